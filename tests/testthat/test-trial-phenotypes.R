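test_that("loading validates design size, bounds, duplicates and orphans", {
  trials <- make_trials("p1")
  roster <- make_roster("p1")
  tf <- tempfile(fileext = ".csv")
  pf <- tempfile(fileext = ".csv")
  write.csv(trials, tf, row.names = FALSE)
  write.csv(roster, pf, row.names = FALSE)
  dat <- load_trial_data(tf, pf)
  expect_equal(nrow(dat$trials), 60)  # 2 x 12 + 2 x 18

  bad <- trials
  bad$rating[5] <- 10
  write.csv(bad, tf, row.names = FALSE)
  expect_error(load_trial_data(tf, pf), "rating")

  bad <- rbind(trials, trials[1, ])
  write.csv(bad, tf, row.names = FALSE)
  expect_error(load_trial_data(tf, pf), "duplicate")

  write.csv(trials, tf, row.names = FALSE)
  write.csv(make_roster("other"), pf, row.names = FALSE)
  expect_error(load_trial_data(tf, pf), "absent from roster")

  # reinforcement misplaced on a CS- trial
  bad <- trials
  bad$reinforced[bad$stimulus == "CS_minus"][1] <- 1L
  write.csv(bad, tf, row.names = FALSE)
  write.csv(roster, pf, row.names = FALSE)
  expect_error(load_trial_data(tf, pf), "reinforced")
})

test_that("exclusion filtering removes flagged participants once, tallies per reason", {
  trials <- do.call(rbind, lapply(c("p1", "p2", "p3"), make_trials))
  roster <- make_roster(c("p1", "p2", "p3"), volume = c(0, 1, 0))
  out <- apply_exclusions(trials, roster)
  expect_equal(out$report$n_retained, 2)
  expect_equal(sort(unique(out$trials$participant_id)), c("p1", "p3"))

  roster <- make_roster(c("p1", "p2"), headphones = c(0, 1),
                        volume = c(0, 1), exit = c(0, 1))
  out <- apply_exclusions(trials[trials$participant_id != "p3", ], roster)
  expect_equal(out$report$n_removed, 1)
  expect_equal(unname(out$report$by_reason),
               c(1, 1, 1))

  roster <- make_roster(c("p1", "p2", "p3"))
  out <- apply_exclusions(trials, roster)
  expect_identical(out$trials, trials)
})

test_that("differential scores match hand arithmetic and are order-invariant", {
  tr <- make_trials("p1", csp_acq = c(9, 9, 9, 9, rep(5, 8)),
                    csm_acq = c(1, 1, 1, 1, rep(5, 8)))
  expect_equal(compute_differential(tr, "acquisition", "first_third")$score,
               8)
  tr <- make_trials("p1", csp_acq = c(6, 6, 6, 6, rep(5, 8)),
                    csm_acq = c(4, 4, 3, 3, rep(5, 8)))
  expect_equal(compute_differential(tr, "acquisition", "first_third")$score,
               2.5)  # 6 - 3.5
  tr <- make_trials("p1", csp_acq = rep(7, 12), csm_acq = rep(7, 12))
  expect_equal(compute_differential(tr, "acquisition", "first_third")$score,
               0)
  expect_equal(compute_differential(tr, "acquisition", "last_third")$score,
               0)
  # row order must not matter
  tr <- make_trials("p1", csp_acq = sample(1:9, 12, TRUE),
                    csm_acq = sample(1:9, 12, TRUE))
  shuffled <- tr[sample(nrow(tr)), ]
  expect_equal(compute_differential(shuffled, "extinction", "first_third"),
               compute_differential(tr, "extinction", "first_third"))
  expect_error(compute_differential(tr, "habituation", "first_third"),
               "phase")
  expect_error(compute_differential(tr, "acquisition", "middle"), "window")
})

test_that("window means require at least half the trials per stimulus", {
  tr <- make_trials("p1")
  # drop 3 of the 4 first-third CS+ acquisition trials: below the minimum
  drop <- tr$phase == "acquisition" & tr$stimulus == "CS_plus" &
    tr$trial_index %in% 1:3
  expect_true(is.na(
    compute_differential(tr[!drop, ], "acquisition", "first_third")$score))
  # drop only 2 of 4: still enough
  drop <- tr$phase == "acquisition" & tr$stimulus == "CS_plus" &
    tr$trial_index %in% 1:2
  expect_false(is.na(
    compute_differential(tr[!drop, ], "acquisition", "first_third")$score))
})

test_that("age/sex residualization matches the normal-equations oracle", {
  set.seed(11)
  n <- 50
  roster <- make_roster(sprintf("p%02d", 1:n), age = runif(n, 20, 30),
                        sex = sample(c("F", "M"), n, TRUE))
  scores <- data.frame(participant_id = roster$participant_id,
                       score = rnorm(n))
  res <- residualize_age_sex(scores, roster)
  X <- cbind(1, roster$age, as.numeric(roster$sex != "F"))
  beta <- solve(t(X) %*% X, t(X) %*% scores$score)
  expect_equal(res$score, as.numeric(scores$score - X %*% beta),
               tolerance = 1e-8)
  expect_lt(abs(mean(res$score)), 1e-10)
  expect_lt(abs(cor(res$score, roster$age)), 1e-8)
  expect_lt(abs(cor(res$score, as.numeric(roster$sex != "F"))), 1e-8)
  # residuals invariant to the sex reference level
  res_m <- residualize_age_sex(scores, roster, sex_reference = "M")
  expect_equal(res$score, res_m$score, tolerance = 1e-10)
})

test_that("a known age slope is recovered at large n", {
  set.seed(12)
  n <- 10000
  roster <- make_roster(sprintf("p%05d", 1:n), age = runif(n, 20, 30),
                        sex = sample(c("F", "M"), n, TRUE))
  scores <- data.frame(participant_id = roster$participant_id,
                       score = 2 * roster$age + rnorm(n))
  fit <- lm(scores$score ~ roster$age +
              as.numeric(roster$sex != "F"))
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 0.02)
  # and the package's residuals are orthogonal to age afterwards
  res <- residualize_age_sex(scores, roster)
  expect_lt(abs(cor(res$score, roster$age)), 1e-8)
})

test_that("degenerate designs fall back to centering", {
  roster <- make_roster(c("a", "b", "c", "d"))
  scores <- data.frame(participant_id = roster$participant_id,
                       score = c(1, 2, 3, 10))
  res <- residualize_age_sex(scores, roster)  # same age and sex throughout
  expect_equal(res$score, scores$score - mean(scores$score))
  scores$score <- rep(5, 4)
  expect_warning(res <- residualize_age_sex(scores, roster),
                 "zero variance")
  expect_equal(res$score, rep(0, 4))
  expect_error(residualize_age_sex(
    data.frame(participant_id = c("a", "b"), score = c(NA, 1)),
    roster), "at least 3")
})

test_that("signed square root is odd, exact on squares, and monotone", {
  expect_equal(normalize_sqrt(0), 0)
  expect_equal(normalize_sqrt(c(4, -4)), c(2, -2))
  expect_true(is.na(normalize_sqrt(NA)))
  x <- sort(rnorm(100))
  expect_true(all(diff(normalize_sqrt(x)) > 0))
})

test_that("pipeline without flags and uniform demographics is signed-sqrt centering", {
  set.seed(21)
  ids <- sprintf("p%02d", 1:10)
  trials <- do.call(rbind, lapply(ids, function(p)
    make_trials(p, csp_acq = sample(4:9, 12, TRUE),
                csm_acq = sample(1:6, 12, TRUE),
                csp_ext = sample(1:7, 18, TRUE),
                csm_ext = sample(1:7, 18, TRUE))))
  roster <- make_roster(ids, family_id = rep(sprintf("f%d", 1:5), each = 2))
  raw <- derive_phenotypes(trials, roster, stage = "raw")
  norm <- derive_phenotypes(trials, roster, stage = "normalized")
  cols <- c("t1_initial", "t1_consol", "t1_extinct",
            "t2_initial", "t2_consol", "t2_extinct")
  for (tr in c("initial", "consol", "extinct")) {
    v <- unlist(raw[, paste0(c("t1_", "t2_"), tr)])
    expect_equal(unlist(norm[, paste0(c("t1_", "t2_"), tr)]),
                 normalize_sqrt(v - mean(v)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # raw differentials are bounded by the rating scale
  expect_true(all(abs(raw[, cols]) <= 8, na.rm = TRUE))
})

test_that("phenotype CSV round-trips including missing cells", {
  set.seed(31)
  phen <- rand_phen(5, 5, n_single = 3)
  path <- tempfile(fileext = ".csv")
  write_phenotypes(phen, path)
  back <- read_phenotypes(path)
  expect_equal(back, phen, ignore_attr = TRUE)
})
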