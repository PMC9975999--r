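# Trivariate ACE/AE Cholesky model fitted by full-information maximum
# likelihood over MZ/DZ families (complete pairs, incomplete pairs and
# singletons alike).
#
# Each variance component is parameterized as L %*% t(L) with L lower
# triangular (6 free loadings), which keeps A, C and E positive
# semi-definite for every parameter value. The expected covariance of the
# stacked (twin1, twin2) phenotype 6-vector is
#   within-twin block   S = A + C + E
#   cross-twin block    alpha * A + C,  alpha = 1 (MZ) or 0.5 (DZ),
# reflecting that MZ co-twins share all and DZ co-twins on average half of
# their segregating genes, while both share their rearing environment.

#' Cholesky parameter set for the trivariate twin model
#'
#' @param mu 3-vector of trait means (shared across twin order and
#'   zygosity; the phenotypes are pre-residualized).
#' @param L_A,L_E,L_C lower-triangular 3x3 loading matrices for the
#'   additive-genetic, non-shared-environment and (optionally) shared-
#'   environment components. `L_C = NULL` gives the AE variant.
#' @return object of class `cholesky_params`.
#' @export
cholesky_params <- function(mu, L_A, L_E, L_C = NULL) {
  chk <- function(L, nm) {
    if (!is.matrix(L) || any(dim(L) != 3) ||
        any(abs(L[upper.tri(L)]) > 0)) {
      stop(nm, " must be a 3x3 lower-triangular matrix")
    }
    unname(L)
  }
  stopifnot(length(mu) == 3, all(is.finite(mu)))
  structure(list(mu = as.numeric(mu), L_A = chk(L_A, "L_A"),
                 L_C = if (!is.null(L_C)) chk(L_C, "L_C"),
                 L_E = chk(L_E, "L_E"),
                 variant = if (is.null(L_C)) "AE" else "ACE"),
            class = "cholesky_params")
}

pack_params <- function(p) {
  c(p$mu, p$L_A[VECH_IDX],
    if (!is.null(p$L_C)) p$L_C[VECH_IDX],
    p$L_E[VECH_IDX])
}

unpack_params <- function(theta, variant) {
  has_c <- variant == "ACE"
  mk <- function(v) {
    L <- matrix(0, 3, 3)
    L[VECH_IDX] <- v
    L
  }
  e_off <- if (has_c) 16L else 10L
  cholesky_params(mu = theta[1:3], L_A = mk(theta[4:9]),
                  L_C = if (has_c) mk(theta[10:15]),
                  L_E = mk(theta[e_off:(e_off + 5L)]))
}

component_matrices <- function(p) {
  list(A = tcrossprod(p$L_A),
       C = if (!is.null(p$L_C)) tcrossprod(p$L_C) else matrix(0, 3, 3),
       E = tcrossprod(p$L_E))
}

#' Model-implied covariance and means for a twin pair
#'
#' @param params a `cholesky_params` object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return list with `sigma` (6x6 implied covariance of the stacked
#'   (twin1, twin2) phenotype vector) and `mu` (6-vector of means).
#' @export
implied_covariance <- function(params, zygosity) {
  zygosity <- match.arg(zygosity, c("MZ", "DZ"))
  cm <- component_matrices(params)
  S <- cm$A + cm$C + cm$E
  alpha <- if (zygosity == "MZ") 1 else 0.5
  cross <- alpha * cm$A + cm$C
  list(sigma = rbind(cbind(S, cross), cbind(cross, S)),
       mu = rep(params$mu, 2))
}

# Group families by (zygosity, observed pattern) for the vectorized
# likelihood. Rows with no observed value are dropped.
fiml_prepare <- function(phenotypes) {
  Y <- as.matrix(phenotypes[, PHEN_COLS, drop = FALSE])
  zyg <- phenotypes$zygosity
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]
  zyg <- zyg[keep]
  obs <- obs[keep, , drop = FALSE]
  if (!nrow(Y)) stop("no families with observed phenotypes")
  key <- paste(zyg, apply(obs, 1, function(r)
    paste(which(r), collapse = ",")))
  groups <- lapply(split(seq_len(nrow(Y)), key), function(rows) {
    idx <- which(obs[rows[1], ])
    list(X = Y[rows, idx, drop = FALSE], idx = as.integer(idx),
         alpha = if (zyg[rows[1]] == "MZ") 1.0 else 0.5)
  })
  fingerprint <- paste(nrow(Y), sum(zyg == "MZ"), sum(zyg == "DZ"),
                       signif(sum(Y, na.rm = TRUE), 12), sep = "|")
  list(groups = unname(groups), n_families = nrow(Y),
       n_mz = sum(zyg == "MZ"), n_dz = sum(zyg == "DZ"),
       pattern_counts = table(key), fingerprint = fingerprint)
}

fiml_functions <- function(variant, groups) {
  has_c <- variant == "ACE"
  cache <- new.env(parent = emptyenv())
  eval_at <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) {
      return(cache$res)
    }
    res <- fiml_eval_cpp(theta, has_c, groups, TRUE)
    cache$theta <- theta
    cache$res <- res
    res
  }
  list(objective = function(theta) eval_at(theta)$value,
       gradient = function(theta) eval_at(theta)$gradient)
}

#' FIML deviance (-2 log-likelihood) of a twin dataset
#'
#' Sums, over families, the multivariate-normal deviance of each family's
#' observed phenotype subvector (up to 6 values for a complete pair, up to
#' 3 for a singleton; missing phenotypes are dropped row-wise), evaluated
#' at the zygosity-appropriate implied covariance and means. A numerically
#' singular implied covariance yields a large finite penalty, not an error.
#'
#' @param params a `cholesky_params` object.
#' @param phenotypes phenotype table.
#' @return scalar -2 log-likelihood.
#' @export
neg2_log_likelihood <- function(params, phenotypes) {
  prep <- fiml_prepare(phenotypes)
  fiml_eval_cpp(pack_params(params), params$variant == "ACE",
                prep$groups, FALSE)$value
}

#' Falconer moment estimates from twin correlations
#'
#' `a2 = 2(rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`, `e2 = 1 - rMZ`, applied
#' elementwise. Raw values are returned together with a variant clipped to
#' `[0, 1]` that is used to seed the optimizer.
#'
#' @param r_mz,r_dz vectors of MZ and DZ twin correlations.
#' @return list with `raw` and `clipped` matrices (rows a2, c2, e2).
#' @export
falconer_estimates <- function(r_mz, r_dz) {
  stopifnot(length(r_mz) == length(r_dz),
            all(abs(r_mz) <= 1), all(abs(r_dz) <= 1))
  raw <- rbind(a2 = 2 * (r_mz - r_dz), c2 = 2 * r_dz - r_mz,
               e2 = 1 - r_mz)
  list(raw = raw, clipped = pmin(pmax(raw, 0), 1))
}

auto_start <- function(phenotypes, variant) {
  X <- rbind(as.matrix(phenotypes[, PHEN_COLS[1:3]]),
             as.matrix(phenotypes[, PHEN_COLS[4:6]]))
  colnames(X) <- TRAITS
  X <- X[rowSums(!is.na(X)) > 0, , drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2, var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Rph <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  Rph[!is.finite(Rph)] <- 0
  diag(Rph) <- 1
  ev <- eigen(Rph, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) Rph <- diag(3)
  rr <- vapply(c("MZ", "DZ"), function(z) vapply(TRAITS, function(tr)
    tryCatch(suppressWarnings(twin_icc(phenotypes, tr, z)),
             error = function(e) NA_real_), numeric(1)), numeric(3))
  r_mz <- ifelse(is.na(rr[, "MZ"]), 0.3, rr[, "MZ"])
  r_dz <- ifelse(is.na(rr[, "DZ"]), 0.15, rr[, "DZ"])
  if (variant == "AE") {
    a2 <- pmin(pmax(r_mz, 0.05), 0.9)
    c2 <- rep(0, 3)
  } else {
    fal <- falconer_estimates(r_mz, r_dz)$clipped
    a2 <- pmin(pmax(fal["a2", ], 0.05), 0.85)
    c2 <- pmin(pmax(fal["c2", ], 0.02), 0.5)
  }
  e2 <- pmax(1 - a2 - c2, 0.1)
  tot <- a2 + c2 + e2
  a2 <- a2 / tot; c2 <- c2 / tot; e2 <- e2 / tot
  comp <- function(s2) {
    D <- diag(sqrt(s2 * v))
    t(chol(D %*% Rph %*% D + diag(1e-8, 3)))
  }
  cholesky_params(mu = mu, L_A = comp(a2),
                  L_C = if (variant == "ACE") comp(c2),
                  L_E = comp(e2))
}

fix_signs <- function(L) {
  for (j in 1:3) if (L[j, j] < 0) L[, j] <- -L[, j]
  L
}

fit_once <- function(theta0, fns, control) {
  opt <- nlminb(theta0, fns$objective, fns$gradient,
                control = list(eval.max = control$eval_max,
                               iter.max = control$iter_max,
                               rel.tol = control$rel_tol))
  g <- fns$gradient(opt$par)
  gnorm <- sqrt(sum(g^2))
  list(par = opt$par, value = opt$objective, nlminb_code = opt$convergence,
       iterations = opt$iterations, grad_norm = gnorm,
       converged = is.finite(opt$objective) &&
         gnorm < control$grad_tol * (1 + abs(opt$objective)))
}

default_fit_control <- function(control = list()) {
  utils::modifyList(list(eval_max = 10000, iter_max = 5000,
                         rel_tol = 1e-12, grad_tol = 1e-5,
                         max_restarts = 5, jitter_sd = 0.15,
                         restart_seed = 1L), control)
}

#' Fit the trivariate ACE or AE Cholesky model by FIML
#'
#' Minimizes the FIML deviance over the Cholesky loadings and trait means
#' using a quasi-Newton optimizer with analytic gradients. The default
#' start derives variance shares from Falconer-type estimates on
#' double-entry twin correlations; on non-convergence up to
#' `control$max_restarts` jittered restarts are attempted and the best
#' converged solution is kept. After fitting, each loading matrix has its
#' columns sign-flipped so diagonals are non-negative (the likelihood is
#' invariant to column signs).
#'
#' @param phenotypes phenotype table (must contain at least one MZ and one
#'   DZ family with observed values; A and C are not identified otherwise).
#' @param variant `"AE"` (default) or `"ACE"`.
#' @param start `"auto"`, or a `cholesky_params` object.
#' @param control list overriding optimizer settings: `eval_max`,
#'   `iter_max`, `rel_tol`, `grad_tol` (scaled gradient-norm tolerance),
#'   `max_restarts`, `jitter_sd`, `restart_seed`.
#' @return object of class `twin_fit`: parameters, `minus2LL`, `n_params`,
#'   `AIC`, convergence diagnostics and a data summary.
#' @export
fit_ace <- function(phenotypes, variant = c("AE", "ACE"), start = "auto",
                    control = list()) {
  variant <- match.arg(variant)
  control <- default_fit_control(control)
  prep <- fiml_prepare(phenotypes)
  if (prep$n_mz == 0 || prep$n_dz == 0) {
    stop("both MZ and DZ families are required: ",
         "A and C are not identified from a single zygosity group")
  }
  fns <- fiml_functions(variant, prep$groups)
  start_params <- if (identical(start, "auto")) {
    auto_start(phenotypes, variant)
  } else {
    stopifnot(inherits(start, "cholesky_params"))
    if (start$variant != variant) stop("start has variant ", start$variant,
                                       " but fitting ", variant)
    start
  }
  theta0 <- pack_params(start_params)
  best <- fit_once(theta0, fns, control)
  n_restarts <- 0L
  if (!best$converged && control$max_restarts > 0) {
    scale <- pmax(abs(theta0), 0.1)
    rng_state <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    set.seed(control$restart_seed)
    for (r in seq_len(control$max_restarts)) {
      cand <- fit_once(theta0 + rnorm(length(theta0),
                                      sd = control$jitter_sd) * scale,
                       fns, control)
      n_restarts <- n_restarts + 1L
      if (cand$value < best$value || (cand$converged && !best$converged)) {
        if (cand$converged || cand$value < best$value) best <- cand
      }
      if (best$converged) break
    }
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, globalenv())
  }
  params <- unpack_params(best$par, variant)
  params$L_A <- fix_signs(params$L_A)
  if (!is.null(params$L_C)) params$L_C <- fix_signs(params$L_C)
  params$L_E <- fix_signs(params$L_E)
  n_params <- if (variant == "ACE") 21L else 15L
  structure(list(params = params, variant = variant,
                 minus2LL = best$value, n_params = n_params,
                 AIC = best$value + 2 * n_params,
                 converged = best$converged,
                 iterations = best$iterations,
                 grad_norm = best$grad_norm,
                 nlminb_code = best$nlminb_code,
                 n_restarts = n_restarts,
                 data_summary = list(n_families = prep$n_families,
                                     n_mz = prep$n_mz, n_dz = prep$n_dz,
                                     patterns = prep$pattern_counts),
                 fingerprint = prep$fingerprint),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, digits = 3, ...) {
  cat("Trivariate ", x$variant, " Cholesky model (FIML)\n", sep = "")
  cat("  families: ", x$data_summary$n_families, " (",
      x$data_summary$n_mz, " MZ, ", x$data_summary$n_dz, " DZ)\n",
      sep = "")
  cat("  -2lnL = ", formatC(x$minus2LL, format = "f", digits = digits),
      ", AIC = ", formatC(x$AIC, format = "f", digits = digits),
      " (", x$n_params, " parameters)\n", sep = "")
  cat("  converged: ", x$converged, " (", x$iterations,
      " iterations, |grad| = ", formatC(x$grad_norm, format = "e",
                                        digits = 1), ")\n", sep = "")
  sol <- correlated_factors(x)
  cat("\nStandardized variance components:\n")
  M <- rbind(a2 = sol$a2, c2 = sol$c2, e2 = sol$e2)
  colnames(M) <- TRAITS
  print(round(if (x$variant == "AE") M[c("a2", "e2"), ] else M, digits))
  cat("\nGenetic correlations (rA):\n")
  print(round(sol$rA, digits))
  invisible(x)
}

#' Standardized correlated-factors solution of a Cholesky fit
#'
#' Re-expresses the Cholesky fit as per-trait standardized variance
#' components and component-specific cross-trait correlations:
#' `a2_i = A_ii / S_ii` (likewise c2, e2 with `S = A + C + E`),
#' `rA_ij = A_ij / sqrt(A_ii A_jj)` (likewise rC, rE),
#' `r_phenotypic = cov2cor(S)`, and the share of each phenotypic
#' correlation carried by each component,
#' `contrib_A_ij = A_ij / sqrt(S_ii S_jj) = sqrt(a2_i) rA_ij sqrt(a2_j)`,
#' so that `contrib_A + contrib_C + contrib_E = r_phenotypic` elementwise.
#' Correlations for a component with zero variance in a trait are missing.
#'
#' @param fit a `twin_fit` or a `cholesky_params` object.
#' @return object of class `correlated_factors` with fields `a2`, `c2`,
#'   `e2`, `rA`, `rC`, `rE`, `r_phenotypic`, `contrib_A`, `contrib_C`,
#'   `contrib_E`.
#' @export
correlated_factors <- function(fit) {
  p <- if (inherits(fit, "twin_fit")) fit$params else fit
  stopifnot(inherits(p, "cholesky_params"))
  cm <- component_matrices(p)
  S <- cm$A + cm$C + cm$E
  sv <- diag(S)
  std <- function(M) diag(M) / sv
  comp_cor <- function(M) {
    d <- diag(M)
    out <- M / sqrt(d %o% d)
    out[!is.finite(out)] <- NA_real_
    dimnames(out) <- list(TRAITS, TRAITS)
    out
  }
  denom <- sqrt(sv %o% sv)
  nm <- function(M) {
    dimnames(M) <- list(TRAITS, TRAITS)
    M
  }
  structure(list(
    a2 = setNames(std(cm$A), TRAITS),
    c2 = setNames(std(cm$C), TRAITS),
    e2 = setNames(std(cm$E), TRAITS),
    rA = comp_cor(cm$A), rC = comp_cor(cm$C), rE = comp_cor(cm$E),
    r_phenotypic = nm(S / denom),
    contrib_A = nm(cm$A / denom), contrib_C = nm(cm$C / denom),
    contrib_E = nm(cm$E / denom),
    variant = p$variant), class = "correlated_factors")
}

#' @export
print.correlated_factors <- function(x, digits = 3, ...) {
  cat("Correlated-factors solution (", x$variant, ")\n", sep = "")
  M <- rbind(a2 = x$a2, c2 = x$c2, e2 = x$e2)
  print(round(if (x$variant == "AE") M[c("a2", "e2"), ] else M, digits))
  cat("\nrA:\n"); print(round(x$rA, digits))
  if (x$variant == "ACE") { cat("\nrC:\n"); print(round(x$rC, digits)) }
  cat("\nrE:\n"); print(round(x$rE, digits))
  cat("\nPhenotypic correlations and component contributions:\n")
  cat("  r_phenotypic:\n"); print(round(x$r_phenotypic, digits))
  cat("  from A:\n"); print(round(x$contrib_A, digits))
  cat("  from E:\n"); print(round(x$contrib_E, digits))
  invisible(x)
}

#' Likelihood-ratio and AIC comparison of nested ACE vs AE fits
#'
#' `chi2 = minus2LL(AE) - minus2LL(ACE)` on 6 degrees of freedom (the six
#' shared-environment loadings dropped); no boundary mixture correction is
#' applied to the chi-square reference (a documented simplification).
#'
#' @param fit_full the ACE `twin_fit`.
#' @param fit_reduced the AE `twin_fit` on the same data.
#' @return list with `chi2`, `df`, `p`, `delta_AIC`
#'   (`AIC(AE) - AIC(ACE)`; negative favours AE).
#' @export
compare_models <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "twin_fit"), inherits(fit_reduced, "twin_fit"))
  if (fit_full$variant != "ACE" || fit_reduced$variant != "AE") {
    stop("expected an ACE full model and an AE reduced model")
  }
  if (!identical(fit_full$fingerprint, fit_reduced$fingerprint)) {
    stop("models were fitted to different datasets")
  }
  chi2 <- fit_reduced$minus2LL - fit_full$minus2LL
  df <- fit_full$n_params - fit_reduced$n_params
  list(chi2 = chi2, df = df,
       p = pchisq(max(chi2, 0), df = df, lower.tail = FALSE),
       delta_AIC = fit_reduced$AIC - fit_full$AIC)
}

cf_flatten <- function(sol) {
  pick <- function(M, pre) setNames(M[lower.tri(M)],
                                    paste0(pre, c("_21", "_31", "_32")))
  c(setNames(sol$a2, paste0("a2_", TRAITS)),
    setNames(sol$c2, paste0("c2_", TRAITS)),
    setNames(sol$e2, paste0("e2_", TRAITS)),
    pick(sol$rA, "rA"), pick(sol$rC, "rC"), pick(sol$rE, "rE"),
    pick(sol$r_phenotypic, "rph"),
    pick(sol$contrib_A, "contribA"), pick(sol$contrib_C, "contribC"),
    pick(sol$contrib_E, "contribE"))
}

#' Bootstrap confidence intervals for the correlated-factors solution
#'
#' Resamples families with replacement (stratified by zygosity), refits the
#' model on each resample starting from the point estimate, and attaches
#' percentile intervals to every standardized quantity. Non-converged
#' resamples are dropped and counted; more than `max_failure_rate` failures
#' is an error.
#'
#' @param phenotypes phenotype table.
#' @param variant `"AE"` or `"ACE"`.
#' @param n_iter bootstrap iterations (default 100).
#' @param seed optional integer seed.
#' @param level CI level (default 0.95).
#' @param fit optional pre-computed point-estimate `twin_fit`.
#' @param max_failure_rate tolerated fraction of failed resamples.
#' @param control optimizer control passed to [fit_ace()].
#' @return object of class `cf_ci`: the point `solution`, named vectors
#'   `estimates`, `lower`, `upper`, and bootstrap metadata.
#' @export
bootstrap_model_ci <- function(phenotypes, variant = c("AE", "ACE"),
                               n_iter = 100, seed = NULL, level = 0.95,
                               fit = NULL, max_failure_rate = 0.2,
                               control = list()) {
  variant <- match.arg(variant)
  stopifnot(n_iter >= 1)
  if (is.null(fit)) fit <- fit_ace(phenotypes, variant, control = control)
  point <- cf_flatten(correlated_factors(fit))
  boot_control <- utils::modifyList(list(max_restarts = 1), control)
  if (!is.null(seed)) set.seed(seed)
  strata <- split(seq_len(nrow(phenotypes)), phenotypes$zygosity)
  reps <- vector("list", n_iter)
  failed <- 0L
  for (b in seq_len(n_iter)) {
    idx <- unlist(lapply(strata, function(s)
      s[sample.int(length(s), length(s), replace = TRUE)]), use.names = FALSE)
    r <- tryCatch({
      bfit <- fit_ace(phenotypes[idx, , drop = FALSE], variant,
                      start = fit$params, control = boot_control)
      if (!bfit$converged) NULL else cf_flatten(correlated_factors(bfit))
    }, error = function(e) NULL)
    if (is.null(r)) failed <- failed + 1L else reps[[b]] <- r
  }
  if (failed > max_failure_rate * n_iter) {
    stop("model failed to converge on ", failed, " of ", n_iter,
         " bootstrap resamples")
  }
  M <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  a <- (1 - level) / 2
  structure(list(solution = correlated_factors(fit), fit = fit,
                 estimates = point,
                 lower = apply(M, 2, quantile, probs = a, na.rm = TRUE,
                               names = FALSE),
                 upper = apply(M, 2, quantile, probs = 1 - a, na.rm = TRUE,
                               names = FALSE),
                 n_boot = n_iter, n_failed = failed, seed = seed,
                 level = level), class = "cf_ci")
}

#' @export
print.cf_ci <- function(x, digits = 2, ...) {
  cat("Correlated-factors solution with ", 100 * x$level,
      "% percentile bootstrap CIs (", x$n_boot, " iterations, ",
      x$n_failed, " failed)\n\n", sep = "")
  show <- grep(if (x$solution$variant == "AE") "^(a2|e2|rA|rE|rph)" else
    "^(a2|c2|e2|rA|rC|rE|rph)", names(x$estimates), value = TRUE)
  fm <- function(v) formatC(v, digits = digits, format = "f")
  for (nmq in show) {
    cat(sprintf("  %-12s %s (%s, %s)\n", nmq, fm(x$estimates[nmq]),
                fm(x$lower[nmq]), fm(x$upper[nmq])))
  }
  invisible(x)
}
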