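# Moment-based twin descriptives: intraclass correlations, cross-twin
# cross-trait matrices, phenotypic correlations and bootstrap CIs.

complete_pairs <- function(phenotypes, zygosity = NULL) {
  sub <- phenotypes
  if (!is.null(zygosity)) sub <- sub[sub$zygosity == zygosity, , drop = FALSE]
  has1 <- rowSums(!is.na(sub[, PHEN_COLS[1:3], drop = FALSE])) > 0
  has2 <- rowSums(!is.na(sub[, PHEN_COLS[4:6], drop = FALSE])) > 0
  sub[has1 & has2, , drop = FALSE]
}

#' Twin-pair intraclass correlation (double-entry Pearson)
#'
#' Each complete pair contributes both orderings (twin 1 vs twin 2 and the
#' reverse), and the ICC is the ordinary Pearson correlation of the
#' double-entered data. This estimator is exactly invariant to within-pair
#' ordering and matches the diagonal of the cross-twin cross-trait matrix.
#'
#' @param phenotypes phenotype table.
#' @param trait `"initial"`, `"consol"` or `"extinct"`.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return scalar correlation (NA with a warning when the trait has zero
#'   variance across the double-entered values).
#' @export
twin_icc <- function(phenotypes, trait, zygosity) {
  trait <- match.arg(trait, TRAITS)
  zygosity <- match.arg(zygosity, c("MZ", "DZ"))
  sub <- phenotypes[phenotypes$zygosity == zygosity, , drop = FALSE]
  x1 <- sub[[paste0("t1_", trait)]]
  x2 <- sub[[paste0("t2_", trait)]]
  ok <- !is.na(x1) & !is.na(x2)
  if (sum(ok) < 3) stop("need at least 3 complete pairs for an ICC")
  a <- c(x1[ok], x2[ok])
  b <- c(x2[ok], x1[ok])
  if (var(a) == 0) {
    warning("zero variance; ICC undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Cross-twin cross-trait correlation matrix
#'
#' Entry (i, j) is the correlation between trait i of one twin and trait j
#' of the co-twin, computed on double-entered complete pairs so the matrix
#' is exactly symmetric; its diagonal is the double-entry ICC per trait.
#' For MZ pairs these correlations reflect the full genetic (plus shared
#' environmental) covariance between traits; comparing them with DZ values
#' informs the genetic analysis of trait covariation.
#'
#' @param phenotypes phenotype table.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return 3x3 symmetric matrix (NA cells where fewer than 3 pairs are
#'   available).
#' @export
cross_twin_cross_trait <- function(phenotypes, zygosity) {
  zygosity <- match.arg(zygosity, c("MZ", "DZ"))
  sub <- complete_pairs(phenotypes, zygosity)
  X1 <- as.matrix(sub[, PHEN_COLS[1:3], drop = FALSE])
  X2 <- as.matrix(sub[, PHEN_COLS[4:6], drop = FALSE])
  DE1 <- rbind(X1, X2)
  DE2 <- rbind(X2, X1)
  M <- matrix(NA_real_, 3, 3, dimnames = list(TRAITS, TRAITS))
  for (i in 1:3) for (j in 1:3) {
    ok <- !is.na(DE1[, i]) & !is.na(DE2[, j])
    if (sum(ok) >= 6) M[i, j] <- cor(DE1[ok, i], DE2[ok, j])
  }
  M
}

#' Phenotypic correlations pooled across individuals
#'
#' Pearson correlations between the three phenotypes over all individuals
#' (both twins of each pair plus singletons), pairwise-complete.
#'
#' @param phenotypes phenotype table.
#' @return 3x3 correlation matrix with unit diagonal.
#' @export
phenotypic_correlations <- function(phenotypes) {
  X <- rbind(as.matrix(setNames(phenotypes[, PHEN_COLS[1:3]], TRAITS)),
             as.matrix(setNames(phenotypes[, PHEN_COLS[4:6]], TRAITS)))
  X <- X[rowSums(!is.na(X)) > 0, , drop = FALSE]
  M <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  dimnames(M) <- list(TRAITS, TRAITS)
  diag(M) <- 1
  M
}

#' Family-level stratified bootstrap confidence interval
#'
#' Resamples families (pairs or singletons) with replacement, stratified by
#' zygosity, recomputes `statistic` on each resample and returns the
#' percentile interval. Reproducible under a fixed seed.
#'
#' @param statistic function taking a phenotype table and returning a
#'   numeric vector (possibly named).
#' @param phenotypes phenotype table.
#' @param n_iter number of bootstrap iterations (default 100).
#' @param seed optional integer seed.
#' @param level confidence level (default 0.95).
#' @param max_failure_rate error out when more than this fraction of
#'   resamples fails (default 0.2).
#' @return list with `lower`, `upper` (vectors matching the statistic),
#'   `n_boot`, `n_failed`, `seed`, `level`.
#' @export
bootstrap_ci <- function(statistic, phenotypes, n_iter = 100, seed = NULL,
                         level = 0.95, max_failure_rate = 0.2) {
  stopifnot(n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  strata <- split(seq_len(nrow(phenotypes)), phenotypes$zygosity)
  reps <- vector("list", n_iter)
  failed <- 0L
  for (b in seq_len(n_iter)) {
    idx <- unlist(lapply(strata, function(s)
      s[sample.int(length(s), length(s), replace = TRUE)]), use.names = FALSE)
    r <- tryCatch(statistic(phenotypes[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(r)) failed <- failed + 1L else reps[[b]] <- r
  }
  if (failed > max_failure_rate * n_iter) {
    stop("bootstrap statistic failed on ", failed, " of ", n_iter,
         " resamples")
  }
  M <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  a <- (1 - level) / 2
  list(lower = apply(M, 2, quantile, probs = a, na.rm = TRUE,
                     names = FALSE),
       upper = apply(M, 2, quantile, probs = 1 - a, na.rm = TRUE,
                     names = FALSE),
       n_boot = n_iter, n_failed = failed, seed = seed, level = level)
}

descriptives_statistic <- function(phen) {
  icc <- function(z) vapply(TRAITS, function(tr)
    tryCatch(suppressWarnings(twin_icc(phen, tr, z)),
             error = function(e) NA_real_), numeric(1))
  ctct <- function(z) {
    M <- cross_twin_cross_trait(phen, z)
    c(M[lower.tri(M, diag = FALSE)])
  }
  rp <- phenotypic_correlations(phen)
  c(setNames(icc("MZ"), paste0("icc_MZ_", TRAITS)),
    setNames(icc("DZ"), paste0("icc_DZ_", TRAITS)),
    setNames(ctct("MZ"), c("ctct_MZ_21", "ctct_MZ_31", "ctct_MZ_32")),
    setNames(ctct("DZ"), c("ctct_DZ_21", "ctct_DZ_31", "ctct_DZ_32")),
    rph_21 = rp[2, 1], rph_31 = rp[3, 1], rph_32 = rp[3, 2])
}

#' Twin descriptives report
#'
#' Computes zygosity-specific intraclass correlations, cross-twin
#' cross-trait matrices and pooled phenotypic correlations, with stratified
#' family bootstrap CIs for all of them.
#'
#' @param phenotypes phenotype table.
#' @param n_boot bootstrap iterations (default 100).
#' @param seed optional seed for the bootstrap.
#' @param level CI level.
#' @return An object of class `twin_descriptives`.
#' @export
twin_descriptives <- function(phenotypes, n_boot = 100, seed = NULL,
                              level = 0.95) {
  est <- descriptives_statistic(phenotypes)
  ci <- bootstrap_ci(descriptives_statistic, phenotypes, n_iter = n_boot,
                     seed = seed, level = level)
  counts <- table(factor(phenotypes$zygosity, levels = c("MZ", "DZ")))
  n_pairs <- vapply(c("MZ", "DZ"), function(z)
    nrow(complete_pairs(phenotypes, z)), numeric(1))
  structure(list(estimates = est, lower = setNames(ci$lower, names(est)),
                 upper = setNames(ci$upper, names(est)),
                 icc = list(MZ = est[1:3], DZ = est[4:6]),
                 cross_twin_cross_trait = list(
                   MZ = cross_twin_cross_trait(phenotypes, "MZ"),
                   DZ = cross_twin_cross_trait(phenotypes, "DZ")),
                 phenotypic = phenotypic_correlations(phenotypes),
                 n_families = as.numeric(counts),
                 n_complete_pairs = n_pairs,
                 n_boot = n_boot, seed = seed, level = level),
            class = "twin_descriptives")
}

#' @export
print.twin_descriptives <- function(x, digits = 2, ...) {
  fm <- function(v) formatC(v, digits = digits, format = "f")
  cat("Twin descriptives (", x$n_complete_pairs[1], " MZ / ",
      x$n_complete_pairs[2], " DZ complete pairs; ",
      100 * x$level, "% percentile bootstrap CIs, ", x$n_boot,
      " iterations)\n\n", sep = "")
  cat("Intraclass correlations (CS differential):\n")
  for (z in c("MZ", "DZ")) {
    idx <- paste0("icc_", z, "_", TRAITS)
    for (k in 1:3) {
      cat(sprintf("  %-3s %-20s %s (%s, %s)\n", z, TRAIT_LABELS[k],
                  fm(x$estimates[idx[k]]), fm(x$lower[idx[k]]),
                  fm(x$upper[idx[k]])))
    }
  }
  cat("\nCross-twin cross-trait correlations:\n")
  for (z in c("MZ", "DZ")) {
    cat(" ", z, "\n")
    print(round(x$cross_twin_cross_trait[[z]], digits))
  }
  cat("\nPhenotypic correlations (all individuals):\n")
  print(round(x$phenotypic, digits))
  invisible(x)
}
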