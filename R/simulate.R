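# Synthetic twin-family data with known additive-genetic / environmental
# structure, at two levels: phenotype tables drawn directly from the
# model-implied multivariate normal, and trial-level expectancy ratings that
# reproduce each participant's latent phenotypes through the derivation
# pipeline.
#
# Seeding: every family has its own stream, seeded from the master seed and
# a (block, index) counter, so enlarging any part of the sample plan leaves
# earlier families' draws unchanged.

family_seed <- function(master, block, index) {
  k <- block * 1048576 + index
  (1103515245 * (k + 1) + master) %% 2147483647
}

#' Sample plan for a simulated twin study
#'
#' @param n_mz_pairs,n_dz_pairs complete pair counts.
#' @param n_singletons participants whose co-twin did not take part.
#' @param singleton_mz_fraction fraction of singletons from MZ families
#'   (default: the MZ share among complete pairs, 250/538).
#' @return list of class `sample_plan`.
#' @export
sample_plan <- function(n_mz_pairs = 250, n_dz_pairs = 288,
                        n_singletons = 860,
                        singleton_mz_fraction = 250 / 538) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0, n_singletons >= 0,
            singleton_mz_fraction >= 0, singleton_mz_fraction <= 1)
  n_mz_s <- round(n_singletons * singleton_mz_fraction)
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_mz_singletons = as.integer(n_mz_s),
                 n_dz_singletons = as.integer(n_singletons - n_mz_s)),
            class = "sample_plan")
}

check_corr <- function(R, nm) {
  if (!is.matrix(R) || any(dim(R) != 3) || max(abs(R - t(R))) > 1e-10 ||
      any(abs(diag(R) - 1) > 1e-10) || any(abs(R) > 1 + 1e-10)) {
    stop(nm, " must be a symmetric 3x3 correlation matrix")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop(nm, " is not positive semi-definite")
  }
  unname((R + t(R)) / 2)
}

#' Ground-truth generating model for twin simulations
#'
#' Specifies standardized variance components per trait (`a2`, `c2`, `e2`
#' summing to 1), component correlation matrices (`r_a`, `r_c`, `r_e`),
#' trait means and total variances, and a sample plan. Construction checks
#' that every component covariance and the implied 6x6 MZ and DZ
#' covariances are positive semi-definite.
#'
#' @param variant `"AE"` or `"ACE"`.
#' @param a2,c2 standardized variance-component 3-vectors (`e2` is
#'   `1 - a2 - c2`; `c2` must be zero under AE).
#' @param r_a,r_c,r_e 3x3 component correlation matrices.
#' @param means,variances trait means and total variances.
#' @param plan a [sample_plan()].
#' @return object of class `generating_model`.
#' @export
generating_model <- function(variant = c("AE", "ACE"), a2,
                             c2 = rep(0, 3), r_a, r_c = diag(3),
                             r_e, means = rep(0, 3),
                             variances = rep(1, 3),
                             plan = sample_plan()) {
  variant <- match.arg(variant)
  stopifnot(length(a2) == 3, length(c2) == 3, length(means) == 3,
            length(variances) == 3, all(variances > 0),
            all(a2 >= 0), all(c2 >= 0), all(a2 + c2 <= 1 + 1e-10))
  if (variant == "AE" && any(c2 != 0)) stop("AE variant requires c2 = 0")
  e2 <- 1 - a2 - c2
  r_a <- check_corr(r_a, "r_a")
  r_c <- check_corr(r_c, "r_c")
  r_e <- check_corr(r_e, "r_e")
  comp <- function(s2, R) {
    D <- diag(sqrt(s2 * variances), 3)
    D %*% R %*% D
  }
  A <- comp(a2, r_a)
  C <- comp(c2, r_c)
  E <- comp(e2, r_e)
  S <- A + C + E
  sig <- function(alpha) {
    cross <- alpha * A + C
    rbind(cbind(S, cross), cbind(cross, S))
  }
  for (alpha in c(1, 0.5)) {
    ev <- eigen(sig(alpha), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("implied covariance for alpha = ", alpha,
           " is not positive semi-definite")
    }
  }
  structure(list(variant = variant, a2 = a2, c2 = c2, e2 = e2,
                 r_a = r_a, r_c = r_c, r_e = r_e, means = means,
                 variances = variances, plan = plan,
                 A = A, C = C, E = E,
                 sigma_mz = sig(1), sigma_dz = sig(0.5)),
            class = "generating_model")
}

#' @export
print.generating_model <- function(x, digits = 3, ...) {
  cat("Generating model (", x$variant, ")\n", sep = "")
  M <- rbind(a2 = x$a2, c2 = x$c2, e2 = x$e2)
  colnames(M) <- TRAITS
  print(round(if (x$variant == "AE") M[c("a2", "e2"), ] else M, digits))
  cat("rA:\n"); print(round(x$r_a, digits))
  cat("rE:\n"); print(round(x$r_e, digits))
  p <- x$plan
  cat("plan: ", p$n_mz_pairs, " MZ pairs, ", p$n_dz_pairs,
      " DZ pairs, ", p$n_mz_singletons + p$n_dz_singletons,
      " singletons\n", sep = "")
  invisible(x)
}

#' Reference AE generating model for the fear-conditioning phenotypes
#'
#' The package's default ground truth for recovery simulations: an AE model
#' with heritabilities 0.15 (initial development), 0.29 (consolidation) and
#' 0.15 (extinction), genetic correlations 0.99 (initial-consolidation),
#' 0.42 (initial-extinction) and 0.44 (consolidation-extinction),
#' non-shared-environment correlations 0.49 / 0.31 / 0.41, standardized
#' traits, and a sample plan of 250 MZ pairs, 288 DZ pairs and 860
#' singletons. These values mirror large-scale remote fear-conditioning
#' twin estimates, so recovery simulations run at realistic effect sizes
#' and power.
#'
#' @return a [generating_model()].
#' @export
fear_generating_model <- function() {
  generating_model(
    variant = "AE",
    a2 = c(0.15, 0.29, 0.15),
    r_a = matrix(c(1, 0.99, 0.42,
                   0.99, 1, 0.44,
                   0.42, 0.44, 1), 3, 3),
    r_e = matrix(c(1, 0.49, 0.31,
                   0.49, 1, 0.41,
                   0.31, 0.41, 1), 3, 3),
    plan = sample_plan(250, 288, 860)
  )
}

# symmetric square root tolerant of semi-definite matrices (e.g. e2 = 0)
sqrt_factor <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

sim_blocks <- function(plan) {
  list(list(block = 0L, n = plan$n_mz_pairs, zyg = "MZ", pair = TRUE,
            prefix = "MZ"),
       list(block = 1L, n = plan$n_dz_pairs, zyg = "DZ", pair = TRUE,
            prefix = "DZ"),
       list(block = 2L, n = plan$n_mz_singletons, zyg = "MZ", pair = FALSE,
            prefix = "MZS"),
       list(block = 3L, n = plan$n_dz_singletons, zyg = "DZ", pair = FALSE,
            prefix = "DZS"))
}

#' Simulate a twin-family phenotype table from a generating model
#'
#' Complete pairs are drawn from the 6-variate normal with the
#' zygosity-appropriate implied covariance; singletons from the 3-variate
#' within-twin margin. Reproducible under a fixed seed, with per-family
#' streams (see the module notes): growing the plan preserves earlier
#' families.
#'
#' @param model a [generating_model()].
#' @param seed integer master seed.
#' @return phenotype table (one row per family), `stage` attribute
#'   `"normalized"` (the simulated values are on the analysis-ready scale).
#' @export
simulate_twin_phenotypes <- function(model, seed) {
  stopifnot(inherits(model, "generating_model"))
  B6 <- list(MZ = sqrt_factor(model$sigma_mz),
             DZ = sqrt_factor(model$sigma_dz))
  B3 <- sqrt_factor(model$A + model$C + model$E)
  mu6 <- rep(model$means, 2)
  out <- lapply(sim_blocks(model$plan), function(bl) {
    if (bl$n == 0) return(NULL)
    k <- if (bl$pair) 6L else 3L
    B <- if (bl$pair) B6[[bl$zyg]] else B3
    mu <- if (bl$pair) mu6 else model$means
    X <- matrix(NA_real_, bl$n, 6)
    for (i in seq_len(bl$n)) {
      set.seed(family_seed(seed, bl$block, i))
      X[i, seq_len(k)] <- mu + as.numeric(B %*% rnorm(k))
    }
    df <- data.frame(family_id = sprintf("%s%05d", bl$prefix,
                                         seq_len(bl$n)),
                     zygosity = bl$zyg, stringsAsFactors = FALSE)
    colnames(X) <- PHEN_COLS
    cbind(df, as.data.frame(X))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "stage") <- "normalized"
  out
}

#' Fear-conditioning task design parameters
#'
#' Defaults mirror the remote paradigm the package models: 12 acquisition
#' presentations per conditional stimulus with the CS+ reinforced on 9 of
#' 12 (75% reinforcement), 18 extinction presentations per stimulus,
#' expectancy ratings on a 1-9 scale, and a pseudo-randomised presentation
#' order with at most 2 identical stimuli in a row.
#'
#' @param acq_trials,ext_trials presentations per stimulus per phase.
#' @param n_reinforced reinforced CS+ acquisition trials.
#' @param rating_min,rating_max rating scale bounds.
#' @param max_consecutive cap on identical consecutive stimuli.
#' @return list of class `task_design`.
#' @export
task_design <- function(acq_trials = 12L, n_reinforced = 9L,
                        ext_trials = 18L, rating_min = 1L,
                        rating_max = 9L, max_consecutive = 2L) {
  stopifnot(n_reinforced <= acq_trials, rating_min < rating_max,
            max_consecutive >= 1)
  structure(list(acq_trials = as.integer(acq_trials),
                 n_reinforced = as.integer(n_reinforced),
                 ext_trials = as.integer(ext_trials),
                 rating_min = as.integer(rating_min),
                 rating_max = as.integer(rating_max),
                 max_consecutive = as.integer(max_consecutive)),
            class = "task_design")
}

# presentation order of n_plus CS+ and n_minus CS- with a run-length cap
interleave_stimuli <- function(n_plus, n_minus, cap) {
  if (max(n_plus, n_minus) > cap * (min(n_plus, n_minus) + 1)) {
    stop("infeasible presentation order: run cap ", cap,
         " cannot accommodate counts ", n_plus, "/", n_minus)
  }
  pool <- c(rep("CS_plus", n_plus), rep("CS_minus", n_minus))
  for (try in 1:200) {
    s <- sample(pool)
    if (max(rle(s)$lengths) <= cap) return(s)
  }
  # deterministic fallback: strict alternation of the remaining majority
  s <- character(0)
  np <- n_plus; nm <- n_minus
  while (np + nm > 0) {
    nxt <- if (np >= nm) "CS_plus" else "CS_minus"
    run <- utils::tail(rle(s)$lengths, 1)
    last <- utils::tail(s, 1)
    if (length(last) && last == nxt && run >= cap) {
      nxt <- setdiff(c("CS_plus", "CS_minus"), nxt)
    }
    s <- c(s, nxt)
    if (nxt == "CS_plus") np <- np - 1 else nm <- nm - 1
  }
  s
}

#' Simulate trial-level expectancy ratings for a twin sample
#'
#' Draws latent phenotypes with [simulate_twin_phenotypes()] (identical
#' values under the same seed), then builds per-participant rating
#' trajectories: the CS+/CS- differential follows a logistic rise over
#' acquisition and an exponential decay over extinction, scaled so the
#' noiseless window means of the differential equal
#' `baseline + scale * latent` for the three phenotype windows. Ratings are
#' the mid-level trajectory plus/minus half the differential plus Gaussian
#' trial noise, rounded and clipped to the rating scale. The CS+ is
#' reinforced on exactly `n_reinforced` acquisition trials.
#'
#' @param model a [generating_model()].
#' @param design a [task_design()].
#' @param seed integer master seed.
#' @param baseline population-mean window differentials (initial
#'   development, consolidation, extinction) on the rating scale.
#' @param scale rating-scale units per latent standard deviation.
#' @param noise_sd trial-level rating noise standard deviation.
#' @param exclusion_rates named rates for the `headphones`, `volume` and
#'   `exit` compliance flags (independent per participant).
#' @return list with `trials`, `roster` and `latent` (the latent phenotype
#'   table).
#' @export
simulate_trial_level <- function(model, design = task_design(), seed,
                                 baseline = c(2.35, 4.0, 2.0),
                                 scale = 1.5, noise_sd = 0.8,
                                 exclusion_rates = c(headphones = 0,
                                                     volume = 0, exit = 0)) {
  stopifnot(inherits(design, "task_design"), length(baseline) == 3)
  interleave_stimuli(design$acq_trials, design$acq_trials,
                     design$max_consecutive)  # feasibility check
  latent <- simulate_twin_phenotypes(model, seed)

  g <- stats::plogis((seq_len(design$acq_trials) - 4) / 1.5)
  w1 <- seq_len(design$acq_trials %/% 3L)
  w2 <- seq.int(design$acq_trials - length(w1) + 1L, design$acq_trials)
  h <- exp(-(seq_len(design$ext_trials) - 1) / 5)
  w3 <- seq_len(design$ext_trials %/% 3L)
  mid_acq <- rep(4.9, design$acq_trials)
  mid_ext <- 1.2 + 2.3 * exp(-(seq_len(design$ext_trials) - 1) / 6)

  rows_per <- 2L * (design$acq_trials + design$ext_trials)
  blocks <- sim_blocks(model$plan)
  n_participants <- sum(vapply(blocks, function(b)
    b$n * (if (b$pair) 2L else 1L), integer(1)))
  n_rows <- n_participants * rows_per
  col <- list(participant_id = character(n_rows),
              phase = character(n_rows), stimulus = character(n_rows),
              trial_index = integer(n_rows), rating = integer(n_rows),
              reinforced = integer(n_rows))
  roster <- vector("list", n_participants)
  pos <- 0L
  ip <- 0L

  clip <- function(x) pmin(pmax(as.integer(round(x)), design$rating_min),
                           design$rating_max)

  for (bl in blocks) {
    if (bl$n == 0) next
    for (i in seq_len(bl$n)) {
      fam_id <- sprintf("%s%05d", bl$prefix, i)
      lat_row <- latent[latent$family_id == fam_id, ]
      set.seed(family_seed(seed, bl$block + 4L, i))
      fam_age <- runif(1, 22, 25)
      n_mem <- if (bl$pair) 2L else 1L
      if (bl$zyg == "MZ") {
        sexes <- rep(if (runif(1) < 0.72) "F" else "M", n_mem)
      } else if (n_mem == 2L && runif(1) < 107 / 288) {
        sexes <- sample(c("F", "M"))
      } else {
        sexes <- rep(if (runif(1) < 0.72) "F" else "M", n_mem)
      }
      for (mem in seq_len(n_mem)) {
        ip <- ip + 1L
        pid <- paste0(fam_id, "_", mem)
        z <- as.numeric(lat_row[1, PHEN_COLS[(mem - 1) * 3 + 1:3]])
        D <- baseline + scale * z
        b <- (D[2] - D[1]) / (mean(g[w2]) - mean(g[w1]))
        a <- D[1] - b * mean(g[w1])
        diff_acq <- a + b * g
        diff_ext <- D[3] * h / mean(h[w3])
        rs <- sample.int(design$acq_trials, design$n_reinforced)
        acq_plus <- clip(mid_acq + diff_acq / 2 +
                           rnorm(design$acq_trials, sd = noise_sd))
        acq_minus <- clip(mid_acq - diff_acq / 2 +
                            rnorm(design$acq_trials, sd = noise_sd))
        ext_plus <- clip(mid_ext + diff_ext / 2 +
                           rnorm(design$ext_trials, sd = noise_sd))
        ext_minus <- clip(mid_ext - diff_ext / 2 +
                            rnorm(design$ext_trials, sd = noise_sd))
        ord_acq <- interleave_stimuli(design$acq_trials, design$acq_trials,
                                      design$max_consecutive)
        ord_ext <- interleave_stimuli(design$ext_trials, design$ext_trials,
                                      design$max_consecutive)
        ti_acq <- stats::ave(seq_along(ord_acq), ord_acq,
                             FUN = seq_along)
        ti_ext <- stats::ave(seq_along(ord_ext), ord_ext,
                             FUN = seq_along)
        sl <- pos + seq_len(rows_per)
        col$participant_id[sl] <- pid
        col$phase[sl] <- rep(c("acquisition", "extinction"),
                             c(2L * design$acq_trials,
                               2L * design$ext_trials))
        col$stimulus[sl] <- c(ord_acq, ord_ext)
        col$trial_index[sl] <- c(ti_acq, ti_ext)
        col$rating[sl] <- c(ifelse(ord_acq == "CS_plus",
                                   acq_plus[ti_acq], acq_minus[ti_acq]),
                            ifelse(ord_ext == "CS_plus",
                                   ext_plus[ti_ext], ext_minus[ti_ext]))
        col$reinforced[sl] <- c(
          ifelse(ord_acq == "CS_plus" & ti_acq %in% rs, 1L, 0L),
          rep(0L, 2L * design$ext_trials))
        pos <- pos + rows_per
        roster[[ip]] <- data.frame(
          participant_id = pid, family_id = fam_id, zygosity = bl$zyg,
          sex = sexes[mem], age = fam_age,
          excluded_headphones = rbinom(1, 1, exclusion_rates[["headphones"]]),
          excluded_volume = rbinom(1, 1, exclusion_rates[["volume"]]),
          excluded_exit = rbinom(1, 1, exclusion_rates[["exit"]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  trials <- as.data.frame(col, stringsAsFactors = FALSE)
  roster <- do.call(rbind, roster)
  rownames(roster) <- NULL
  list(trials = trials, roster = roster, latent = latent)
}
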