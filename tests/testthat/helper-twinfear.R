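# Shared fixtures and independent oracles, built in code.

# Independent FIML oracle: per-family multivariate-normal deviance computed
# with plain base-R linear algebra, no grouping, no compiled code.
oracle_neg2ll <- function(params, phen) {
  A <- params$L_A %*% t(params$L_A)
  C <- if (is.null(params$L_C)) matrix(0, 3, 3) else
    params$L_C %*% t(params$L_C)
  E <- params$L_E %*% t(params$L_E)
  S <- A + C + E
  mu6 <- rep(params$mu, 2)
  cols <- c("t1_initial", "t1_consol", "t1_extinct",
            "t2_initial", "t2_consol", "t2_extinct")
  total <- 0
  for (i in seq_len(nrow(phen))) {
    alpha <- if (phen$zygosity[i] == "MZ") 1 else 0.5
    cross <- alpha * A + C
    Sig <- rbind(cbind(S, cross), cbind(cross, S))
    x <- as.numeric(phen[i, cols])
    obs <- which(!is.na(x))
    if (!length(obs)) next
    So <- Sig[obs, obs, drop = FALSE]
    r <- x[obs] - mu6[obs]
    total <- total + length(obs) * log(2 * pi) +
      determinant(So, logarithm = TRUE)$modulus[1] +
      drop(crossprod(r, solve(So, r)))
  }
  total
}

# random valid Cholesky parameters with well-conditioned components
rand_params <- function(variant = "AE") {
  rl <- function(scale) {
    L <- matrix(rnorm(9, sd = 0.3), 3, 3)
    L[upper.tri(L)] <- 0
    diag(L) <- abs(diag(L)) + scale
    L
  }
  cholesky_params(mu = rnorm(3, sd = 0.5), L_A = rl(0.4),
                  L_C = if (variant == "ACE") rl(0.2),
                  L_E = rl(0.5))
}

# small random phenotype table with missingness, independent of the
# package's simulator
rand_phen <- function(n_mz, n_dz, n_single = 0, miss_rate = 0.1) {
  n <- n_mz + n_dz + n_single
  Y <- matrix(rnorm(6 * n), n, 6)
  zyg <- c(rep("MZ", n_mz), rep("DZ", n_dz),
           sample(c("MZ", "DZ"), n_single, replace = TRUE))
  if (n_single > 0) Y[(n_mz + n_dz + 1):n, 4:6] <- NA
  if (miss_rate > 0) {
    drop <- matrix(runif(6 * n) < miss_rate, n, 6)
    Y[drop] <- NA
  }
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  out <- data.frame(family_id = sprintf("F%04d", seq_len(nrow(Y))),
                    zygosity = zyg[keep], stringsAsFactors = FALSE)
  Y <- as.data.frame(Y)
  names(Y) <- c("t1_initial", "t1_consol", "t1_extinct",
                "t2_initial", "t2_consol", "t2_extinct")
  cbind(out, Y)
}

# minimal complete trial set for one participant: flat ratings per stimulus
make_trials <- function(pid, csp_acq = rep(6, 12), csm_acq = rep(4, 12),
                        csp_ext = rep(3, 18), csm_ext = rep(2, 18),
                        reinforced_idx = 1:9) {
  rbind(
    data.frame(participant_id = pid, phase = "acquisition",
               stimulus = "CS_plus", trial_index = 1:12, rating = csp_acq,
               reinforced = as.integer(1:12 %in% reinforced_idx)),
    data.frame(participant_id = pid, phase = "acquisition",
               stimulus = "CS_minus", trial_index = 1:12, rating = csm_acq,
               reinforced = 0L),
    data.frame(participant_id = pid, phase = "extinction",
               stimulus = "CS_plus", trial_index = 1:18, rating = csp_ext,
               reinforced = 0L),
    data.frame(participant_id = pid, phase = "extinction",
               stimulus = "CS_minus", trial_index = 1:18, rating = csm_ext,
               reinforced = 0L))
}

make_roster <- function(ids, family_id = ids, zygosity = "MZ", sex = "F",
                        age = 23, headphones = 0, volume = 0, exit = 0) {
  data.frame(participant_id = ids, family_id = family_id,
             zygosity = zygosity, sex = sex, age = age,
             excluded_headphones = headphones, excluded_volume = volume,
             excluded_exit = exit, stringsAsFactors = FALSE)
}
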