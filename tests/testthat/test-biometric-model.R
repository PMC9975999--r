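test_that("implied covariance has the A/C/E twin block structure", {
  p <- cholesky_params(mu = rep(0, 3), L_A = diag(3), L_C = diag(3),
                       L_E = diag(3))
  mz <- implied_covariance(p, "MZ")
  dz <- implied_covariance(p, "DZ")
  expect_equal(mz$sigma[1:3, 1:3], 3 * diag(3))
  expect_equal(mz$sigma[1:3, 4:6], 2 * diag(3))
  expect_equal(dz$sigma[1:3, 4:6], 1.5 * diag(3))

  p <- cholesky_params(mu = rep(0, 3), L_A = diag(sqrt(0.3), 3),
                       L_E = diag(sqrt(0.7), 3))
  mz <- implied_covariance(p, "MZ")
  dz <- implied_covariance(p, "DZ")
  expect_equal(diag(mz$sigma), rep(1, 6))
  expect_equal(mz$sigma[1:3, 4:6], 0.3 * diag(3))
  expect_equal(dz$sigma[1:3, 4:6], 0.15 * diag(3))

  # random parameters: cross blocks are alpha*A + C, matrix symmetric PSD
  set.seed(51)
  for (i in 1:10) {
    p <- rand_params("ACE")
    A <- tcrossprod(p$L_A); C <- tcrossprod(p$L_C); E <- tcrossprod(p$L_E)
    for (z in c("MZ", "DZ")) {
      alpha <- if (z == "MZ") 1 else 0.5
      sig <- implied_covariance(p, z)$sigma
      expect_equal(sig[1:3, 1:3], A + C + E)
      expect_equal(sig[1:3, 4:6], alpha * A + C)
      expect_equal(sig, t(sig))
      expect_gte(min(eigen(sig, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-10)
    }
  }
})

test_that("FIML deviance has the closed-form values for unit covariance", {
  p <- cholesky_params(mu = rep(0, 3),
                       L_A = diag(sqrt(0.5), 3), L_E = diag(sqrt(0.5), 3))
  # implied within-twin covariance is I3, but cross-twin is not zero;
  # use an E-only parameterization for exactly Sigma = I6
  p <- cholesky_params(mu = rep(0, 3), L_A = matrix(0, 3, 3),
                       L_E = diag(3))
  pair <- data.frame(family_id = "f1", zygosity = "MZ",
                     t1_initial = 0, t1_consol = 0, t1_extinct = 0,
                     t2_initial = 0, t2_consol = 0, t2_extinct = 0)
  expect_equal(neg2_log_likelihood(p, pair), 6 * log(2 * pi))
  single <- pair
  single[, c("t2_initial", "t2_consol", "t2_extinct")] <- NA
  expect_equal(neg2_log_likelihood(p, single), 3 * log(2 * pi))
})

test_that("FIML equals the per-family oracle on random small datasets", {
  set.seed(52)
  for (i in 1:20) {
    variant <- if (i %% 2) "AE" else "ACE"
    p <- rand_params(variant)
    phen <- rand_phen(sample(3:8, 1), sample(3:8, 1),
                      n_single = sample(0:4, 1), miss_rate = 0.2)
    expect_equal(neg2_log_likelihood(p, phen), oracle_neg2ll(p, phen),
                 tolerance = 1e-10)
  }
})

test_that("FIML matches the moment-based closed form on complete data", {
  set.seed(53)
  p <- rand_params("AE")
  phen <- rand_phen(250, 250, miss_rate = 0)
  X <- as.matrix(phen[, c("t1_initial", "t1_consol", "t1_extinct",
                          "t2_initial", "t2_consol", "t2_extinct")])
  val <- 0
  for (z in c("MZ", "DZ")) {
    sig <- implied_covariance(p, z)$sigma
    mu <- implied_covariance(p, z)$mu
    Xz <- X[phen$zygosity == z, ]
    n <- nrow(Xz)
    xb <- colMeans(Xz)
    S_ml <- crossprod(sweep(Xz, 2, xb)) / n
    val <- val + n * (6 * log(2 * pi) +
                        determinant(sig, TRUE)$modulus[1] +
                        sum(diag(solve(sig) %*% S_ml)) +
                        drop(t(xb - mu) %*% solve(sig) %*% (xb - mu)))
  }
  expect_equal(neg2_log_likelihood(p, phen), val, tolerance = 1e-6)
})

test_that("analytic gradients agree with central differences", {
  set.seed(54)
  phen <- rand_phen(30, 30, n_single = 10, miss_rate = 0.15)
  for (variant in c("AE", "ACE")) {
    p <- rand_params(variant)
    prep <- twinfear:::fiml_prepare(phen)
    fns <- twinfear:::fiml_functions(variant, prep$groups)
    theta <- twinfear:::pack_params(p)
    g <- fns$gradient(theta)
    h <- 1e-5
    for (k in seq_along(theta)) {
      up <- dn <- theta
      up[k] <- up[k] + h
      dn[k] <- dn[k] - h
      expect_equal(g[k], (fns$objective(up) - fns$objective(dn)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
})

test_that("the likelihood is invariant to loading-column sign flips", {
  set.seed(55)
  phen <- rand_phen(20, 20, miss_rate = 0.1)
  p <- rand_params("ACE")
  base <- neg2_log_likelihood(p, phen)
  for (comp in c("L_A", "L_C", "L_E")) {
    for (j in 1:3) {
      q <- p
      q[[comp]][, j] <- -q[[comp]][, j]
      expect_equal(neg2_log_likelihood(q, phen), base, tolerance = 1e-10)
    }
  }
})

test_that("standardization reproduces a hand-computed correlated-factors solution", {
  A <- matrix(c(0.30, 0.15, 0.06,
                0.15, 0.30, 0.06,
                0.06, 0.06, 0.15), 3, 3)
  E <- diag(c(0.70, 0.70, 0.85))
  p <- cholesky_params(mu = rep(0, 3), L_A = t(chol(A)), L_E = t(chol(E)))
  sol <- correlated_factors(p)
  expect_equal(unname(sol$a2), c(0.3, 0.3, 0.15), tolerance = 1e-12)
  expect_equal(unname(sol$e2), c(0.7, 0.7, 0.85), tolerance = 1e-12)
  expect_equal(sol$rA[1, 2], 0.15 / 0.30, tolerance = 1e-12)
  expect_equal(sol$rA[1, 3], 0.06 / sqrt(0.30 * 0.15), tolerance = 1e-12)
  expect_equal(sol$rE[1, 2], 0, tolerance = 1e-12)
  expect_equal(sol$r_phenotypic[1, 2], 0.15, tolerance = 1e-12)
  # diagonal components give identity correlations
  p <- cholesky_params(mu = rep(0, 3), L_A = diag(sqrt(0.4), 3),
                       L_E = diag(sqrt(0.6), 3))
  sol <- correlated_factors(p)
  expect_equal(sol$rA, diag(3), ignore_attr = TRUE)
  expect_equal(sol$r_phenotypic, diag(3), ignore_attr = TRUE)
})

test_that("component contributions sum to the phenotypic correlation", {
  set.seed(56)
  for (variant in c("AE", "ACE")) {
    p <- rand_params(variant)
    sol <- correlated_factors(p)
    expect_equal(sol$contrib_A + sol$contrib_C + sol$contrib_E,
                 sol$r_phenotypic, tolerance = 1e-12)
  }
})

test_that("Falconer estimates follow the moment formulas with clipping", {
  f <- falconer_estimates(c(0.30, 0.5, 0.1), c(0.15, 0.4, 0.2))
  expect_equal(unname(f$raw[, 1]), c(0.30, 0.00, 0.70))
  expect_equal(unname(f$raw[, 2]), c(0.2, 0.3, 0.5))
  expect_equal(f$raw["a2", 3], -0.2, ignore_attr = TRUE)
  expect_equal(f$clipped["a2", 3], 0, ignore_attr = TRUE)
})

test_that("model comparison accounts for df and the chi-square reference", {
  fake_fit <- function(variant, m2ll) {
    structure(list(variant = variant, minus2LL = m2ll,
                   n_params = if (variant == "ACE") 21L else 15L,
                   AIC = m2ll + 2 * (if (variant == "ACE") 21 else 15),
                   fingerprint = "x"), class = "twin_fit")
  }
  cmp <- compare_models(fake_fit("ACE", 100), fake_fit("AE", 100))
  expect_equal(cmp$chi2, 0)
  expect_equal(cmp$df, 6)
  expect_equal(cmp$delta_AIC, -12)
  cmp <- compare_models(fake_fit("ACE", 100), fake_fit("AE", 112.59))
  expect_equal(cmp$p, 0.05, tolerance = 0.002)
  expect_error(compare_models(fake_fit("AE", 1), fake_fit("AE", 1)),
               "ACE")
  bad <- fake_fit("AE", 1)
  bad$fingerprint <- "y"
  expect_error(compare_models(fake_fit("ACE", 1), bad), "different")
})

test_that("AE parameters are recovered at very large n and nesting holds", {
  m <- generating_model(variant = "AE", a2 = rep(0.3, 3), r_a = diag(3),
                        r_e = diag(3),
                        plan = sample_plan(20000, 20000, 0))
  phen <- simulate_twin_phenotypes(m, seed = 7)
  fit_ae <- fit_ace(phen, "AE")
  expect_true(fit_ae$converged)
  sol <- correlated_factors(fit_ae)
  expect_lt(max(abs(sol$a2 - 0.3)), 0.02)
  fit_ace_full <- fit_ace(phen, "ACE")
  expect_lte(fit_ace_full$minus2LL, fit_ae$minus2LL + 1e-6)
})

test_that("a single zygosity group is rejected as unidentified", {
  set.seed(57)
  phen <- rand_phen(20, 0)
  expect_error(fit_ace(phen, "AE"), "not identified")
})

test_that("fitted loading diagonals are non-negative by convention", {
  m <- fear_generating_model()
  m$plan <- sample_plan(150, 150, 0)
  fit <- fit_ace(simulate_twin_phenotypes(m, seed = 8), "AE")
  expect_true(all(diag(fit$params$L_A) >= 0))
  expect_true(all(diag(fit$params$L_E) >= 0))
})

test_that("bootstrap model CIs are seed-reproducible and narrow with n", {
  m <- fear_generating_model()
  m$plan <- sample_plan(80, 80, 40)
  phen_small <- simulate_twin_phenotypes(m, seed = 9)
  ci_a <- bootstrap_model_ci(phen_small, "AE", n_iter = 30, seed = 4)
  ci_b <- bootstrap_model_ci(phen_small, "AE", n_iter = 30, seed = 4)
  expect_equal(ci_a$lower, ci_b$lower)
  expect_equal(ci_a$upper, ci_b$upper)

  m$plan <- sample_plan(800, 800, 400)
  phen_big <- simulate_twin_phenotypes(m, seed = 9)
  ci_big <- bootstrap_model_ci(phen_big, "AE", n_iter = 30, seed = 4)
  keep <- grep("^(a2|e2)_", names(ci_a$estimates))
  w_small <- (ci_a$upper - ci_a$lower)[keep]
  w_big <- (ci_big$upper - ci_big$lower)[keep]
  expect_gt(mean(w_big < w_small), 0.9)
})
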