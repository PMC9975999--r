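# Trial-level data handling and derivation of the three differential
# phenotypes: initial development (first third of acquisition), consolidation
# (last third of acquisition) and extinction (first third of extinction).

#' Read trial-level fear-conditioning data and a participant roster
#'
#' The trial file has one row per participant x phase x stimulus x trial with
#' columns `participant_id, phase, stimulus, trial_index, rating, reinforced`;
#' `phase` is `acquisition` or `extinction`, `stimulus` is `CS_plus` or
#' `CS_minus`, `rating` is an integer expectancy rating on the 1 (certain no
#' aversive outcome) to 9 (certain aversive outcome) scale, and `reinforced`
#' (0/1) marks trials on which the aversive stimulus was delivered. The
#' participant file has columns `participant_id, family_id, zygosity, sex,
#' age, excluded_headphones, excluded_volume, excluded_exit`.
#'
#' Records are validated against the task design: ratings in 1..9, acquisition
#' trial indices 1..12 and extinction 1..18 per stimulus, reinforcement only
#' on CS+ acquisition trials, no duplicate (participant, phase, stimulus,
#' trial) rows, and no trials for participants absent from the roster. A
#' participant with a complete set of 12 CS+ acquisition trials is expected
#' to have exactly 9 reinforced ones (75% reinforcement); a deviation raises
#' a warning, since partial uploads are tolerated.
#'
#' @param trial_file path to the trial-level CSV.
#' @param participant_file path to the participant CSV.
#' @return A list with elements `trials` and `roster` (validated data frames).
#' @export
load_trial_data <- function(trial_file, participant_file) {
  if (!file.exists(trial_file)) stop("trial file not found: ", trial_file)
  if (!file.exists(participant_file)) {
    stop("participant file not found: ", participant_file)
  }
  trials <- read.csv(trial_file, stringsAsFactors = FALSE)
  roster <- read.csv(participant_file, stringsAsFactors = FALSE,
                     colClasses = c(sex = "character",
                                    zygosity = "character"))
  validate_roster(roster)
  validate_trials(trials, roster)
  trials$reinforced <- as.logical(trials$reinforced)
  list(trials = trials, roster = roster)
}

validate_roster <- function(roster) {
  need <- c("participant_id", "family_id", "zygosity", "sex", "age",
            "excluded_headphones", "excluded_volume", "excluded_exit")
  miss <- setdiff(need, names(roster))
  if (length(miss)) stop("participant file missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(roster$participant_id)) {
    stop("duplicate participant_id in roster")
  }
  if (!all(roster$zygosity %in% c("MZ", "DZ"))) {
    stop("zygosity must be MZ or DZ")
  }
  if (!all(roster$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (any(!is.finite(roster$age)) || any(roster$age <= 0)) {
    stop("age must be positive")
  }
  zpf <- tapply(roster$zygosity, roster$family_id,
                function(z) length(unique(z)))
  if (any(zpf > 1)) stop("members of a family must share zygosity")
  invisible(TRUE)
}

validate_trials <- function(trials, roster) {
  need <- c("participant_id", "phase", "stimulus", "trial_index",
            "rating", "reinforced")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial file missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(trials$phase %in% c("acquisition", "extinction"))) {
    stop("phase must be acquisition or extinction")
  }
  if (!all(trials$stimulus %in% c("CS_plus", "CS_minus"))) {
    stop("stimulus must be CS_plus or CS_minus")
  }
  bad <- which(!is.finite(trials$rating) | trials$rating < 1 |
                 trials$rating > 9 | trials$rating != round(trials$rating))
  if (length(bad)) {
    stop("rating outside 1-9 at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  max_idx <- ifelse(trials$phase == "acquisition", 12L, 18L)
  bad <- which(trials$trial_index < 1 | trials$trial_index > max_idx |
                 trials$trial_index != round(trials$trial_index))
  if (length(bad)) {
    stop("trial_index out of range at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(trials$participant_id, trials$phase, trials$stimulus,
               trials$trial_index)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, phase, stimulus, trial_index) at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  orphan <- setdiff(unique(trials$participant_id), roster$participant_id)
  if (length(orphan)) {
    stop("trials for participants absent from roster: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  rf <- as.logical(trials$reinforced)
  bad <- which(rf & !(trials$phase == "acquisition" &
                        trials$stimulus == "CS_plus"))
  if (length(bad)) {
    stop("reinforced trials must be CS_plus acquisition; row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  csp <- trials$phase == "acquisition" & trials$stimulus == "CS_plus"
  n_csp <- tapply(csp, trials$participant_id, sum)
  n_rf <- tapply(rf & csp, trials$participant_id, sum)
  complete <- !is.na(n_csp) & n_csp == 12L
  if (any(complete & n_rf != 9L)) {
    warning("complete records with a reinforcement count other than 9/12: ",
            paste(utils::head(names(n_csp)[complete & n_rf != 9L], 5),
                  collapse = ", "))
  }
  invisible(TRUE)
}

#' Remove participants flagged by the task-compliance exclusion rules
#'
#' Participants who removed their headphones, reduced phone volume below 50%
#' or exited the app during the task are removed in full (all their trials).
#' Reasons are not mutually exclusive; the per-reason tallies count each
#' flagged participant under every reason that applies, while the
#' retained/removed totals count each participant once.
#'
#' @param trials trial-level data frame.
#' @param roster participant data frame with the three exclusion flags.
#' @return A list with `trials`, `roster` (both filtered) and `report`
#'   (totals and per-reason counts).
#' @export
apply_exclusions <- function(trials, roster) {
  hp <- as.logical(roster$excluded_headphones)
  vol <- as.logical(roster$excluded_volume)
  ex <- as.logical(roster$excluded_exit)
  flagged <- hp | vol | ex
  keep_ids <- roster$participant_id[!flagged]
  report <- list(
    n_total = nrow(roster),
    n_retained = sum(!flagged),
    n_removed = sum(flagged),
    by_reason = c(headphones = sum(hp), volume = sum(vol), exit = sum(ex))
  )
  list(trials = trials[trials$participant_id %in% keep_ids, , drop = FALSE],
       roster = roster[!flagged, , drop = FALSE],
       report = report)
}

window_trials <- function(phase, window) {
  n <- switch(phase, acquisition = 12L, extinction = 18L,
              stop("unknown phase: ", phase))
  third <- n %/% 3L
  switch(window,
         first_third = seq_len(third),
         last_third = seq.int(n - third + 1L, n),
         stop("unknown window: ", window))
}

#' Differential expectancy score over a phase window
#'
#' Computes, per participant, the mean CS+ expectancy rating minus the mean
#' CS- expectancy rating over the requested third of a phase. Thirds are
#' taken per stimulus: trials 1-4 / 9-12 of acquisition and 1-6 / 13-18 of
#' extinction. A participant whose window has fewer than half its trials
#' rated for either stimulus gets a missing score rather than an error.
#'
#' @param trials trial-level data frame.
#' @param phase `"acquisition"` or `"extinction"`.
#' @param window `"first_third"` or `"last_third"`.
#' @return Data frame with columns `participant_id` and `score`
#'   (range -8..8, NA when insufficient trials).
#' @export
compute_differential <- function(trials, phase, window) {
  idx <- window_trials(phase, window)
  min_n <- ceiling(length(idx) / 2)
  sub <- trials[trials$phase == phase & trials$trial_index %in% idx, ,
                drop = FALSE]
  ids <- sort(unique(trials$participant_id))
  mean_by <- function(stim) {
    s <- sub[sub$stimulus == stim, , drop = FALSE]
    n <- tapply(s$rating, s$participant_id, length)
    m <- tapply(s$rating, s$participant_id, mean)
    m[!is.na(n) & n < min_n] <- NA_real_
    m[match(ids, names(m))]
  }
  score <- unname(mean_by("CS_plus") - mean_by("CS_minus"))
  data.frame(participant_id = ids, score = score,
             stringsAsFactors = FALSE)
}

#' Regress age and sex out of a phenotype
#'
#' Ordinary least squares of the score on intercept, age and a binary sex
#' indicator; the residuals are returned (mean zero by construction). This
#' removes age/sex effects that would otherwise inflate twin correlations,
#' since co-twins share both. Missing scores pass through as missing. With
#' no variation in age and sex the fit collapses to the intercept and
#' residuals are the centered scores; a zero-variance score triggers a
#' warning and returns centered scores.
#'
#' @param scores data frame with `participant_id` and `score` (as returned
#'   by [compute_differential()]).
#' @param roster participant data frame supplying `age` and `sex`.
#' @param sex_reference which sex level codes 0 in the indicator; residuals
#'   are invariant to the choice.
#' @return `scores` with `score` replaced by residuals.
#' @export
residualize_age_sex <- function(scores, roster, sex_reference = "F") {
  m <- match(scores$participant_id, roster$participant_id)
  if (anyNA(m)) stop("scores contain participants absent from roster")
  age <- roster$age[m]
  sex <- as.numeric(roster$sex[m] != sex_reference)
  y <- scores$score
  ok <- !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 non-missing scores to residualize")
  out <- rep(NA_real_, length(y))
  if (var(y[ok]) == 0) {
    warning("score has zero variance; returning centered scores")
    out[ok] <- y[ok] - mean(y[ok])
  } else {
    fit <- lm(y ~ age + sex, na.action = na.exclude)
    out <- as.numeric(residuals(fit))
  }
  scores$score <- out
  scores
}

#' Signed square-root transformation
#'
#' `sign(x) * sqrt(|x|)`: the square-root normalisation extended to the whole
#' real line so that negative residuals keep their sign. Order-preserving;
#' missing values pass through.
#'
#' @param x numeric vector.
#' @return transformed vector.
#' @export
normalize_sqrt <- function(x) sign(x) * sqrt(abs(x))

#' Derive the family-wide phenotype table from trial-level data
#'
#' Runs the full preparation pipeline: compliance exclusions, the three
#' window differentials (initial development = first third of acquisition,
#' consolidation = last third of acquisition, extinction = first third of
#' extinction), age/sex residualization and signed square-root
#' normalisation, then reshapes to one row per family with twin 1/2 columns
#' (twin order is the within-family `participant_id` sort order; all
#' downstream statistics are order-invariant).
#'
#' @param trials trial-level data frame.
#' @param roster participant data frame.
#' @param stage stop the pipeline early: `"raw"` (window differentials),
#'   `"residualized"`, or `"normalized"` (default, analysis-ready).
#' @param exclusions apply the compliance exclusion flags first.
#' @return Data frame with columns `family_id`, `zygosity`,
#'   `t1_initial, t1_consol, t1_extinct, t2_initial, t2_consol, t2_extinct`;
#'   attribute `stage` records the processing stage.
#' @export
derive_phenotypes <- function(trials, roster, stage = "normalized",
                              exclusions = TRUE) {
  stage <- match.arg(stage, c("raw", "residualized", "normalized"))
  if (exclusions) {
    filt <- apply_exclusions(trials, roster)
    trials <- filt$trials
    roster <- filt$roster
  }
  specs <- list(initial = c("acquisition", "first_third"),
                consol = c("acquisition", "last_third"),
                extinct = c("extinction", "first_third"))
  per_trait <- lapply(specs, function(s) {
    sc <- compute_differential(trials, s[1], s[2])
    if (stage != "raw") {
      sc <- residualize_age_sex(sc, roster)
      if (stage == "normalized") sc$score <- normalize_sqrt(sc$score)
    }
    sc
  })
  ids <- per_trait[[1]]$participant_id
  P <- data.frame(participant_id = ids,
                  initial = per_trait$initial$score,
                  consol = per_trait$consol$score,
                  extinct = per_trait$extinct$score,
                  stringsAsFactors = FALSE)
  m <- match(P$participant_id, roster$participant_id)
  P$family_id <- roster$family_id[m]
  P$zygosity <- roster$zygosity[m]
  fam_ids <- unique(roster$family_id[order(roster$family_id)])
  fam_ids <- fam_ids[fam_ids %in% P$family_id]
  rows <- lapply(fam_ids, function(f) {
    sub <- P[P$family_id == f, , drop = FALSE]
    sub <- sub[order(sub$participant_id), , drop = FALSE]
    t1 <- as.numeric(sub[1, TRAITS])
    t2 <- if (nrow(sub) >= 2) as.numeric(sub[2, TRAITS]) else
      rep(NA_real_, 3)
    c(t1, t2)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- PHEN_COLS
  out <- cbind(data.frame(family_id = fam_ids,
                          zygosity = P$zygosity[match(fam_ids, P$family_id)],
                          stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  attr(out, "stage") <- stage
  out
}

#' Write / read a phenotype table CSV
#'
#' One row per family: `family_id, zygosity, t1_initial, t1_consol,
#' t1_extinct, t2_initial, t2_consol, t2_extinct`, empty cells for missing
#' twins or phenotypes.
#'
#' @param phenotypes phenotype table as from [derive_phenotypes()] or
#'   [simulate_twin_phenotypes()].
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.csv(phenotypes[, c("family_id", "zygosity", PHEN_COLS)], path,
            row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("family_id", "zygosity", PHEN_COLS)
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("phenotype file missing columns: ",
                         paste(miss, collapse = ", "))
  for (cc in PHEN_COLS) out[[cc]] <- as.numeric(out[[cc]])
  if (!all(out$zygosity %in% c("MZ", "DZ"))) stop("zygosity must be MZ or DZ")
  if (any(rowSums(!is.na(out[PHEN_COLS])) == 0)) {
    stop("phenotype rows with no observed values")
  }
  out
}
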