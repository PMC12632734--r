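test_that("omega squared hits its closed-form limits", {
  # zero within-group variance, unequal means -> MSE = 0 -> 100
  expect_equal(as.numeric(omega_squared(c(1, 1, 5, 5), c("a", "a", "b", "b"))),
               100)
  # all observations identical -> degenerate rule returns 0 with flag
  deg <- omega_squared(rep(3, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
  expect_error(omega_squared(1:4, rep("a", 4)), ">= 2 groups")
  expect_error(omega_squared(1:3, c("a", "a", "b")), ">= 2 observations")
})

test_that("omega squared equals a brute-force sums-of-squares oracle", {
  set.seed(14)
  for (rep in 1:100) {
    k <- sample(2:8, 1)
    n_per <- sample(2:6, k, replace = TRUE)
    g <- rep(seq_len(k), n_per)
    y <- rnorm(length(g), mean = g * runif(1, 0, 2))
    # oracle: explicit sum computations, no shared code with the package
    gm <- sum(y) / length(y)
    ssb <- 0; ssw <- 0
    for (j in seq_len(k)) {
      yj <- y[g == j]
      ssb <- ssb + length(yj) * (mean(yj) - gm)^2
      ssw <- ssw + sum((yj - mean(yj))^2)
    }
    sst <- ssb + ssw
    mse <- ssw / (length(y) - k)
    oracle <- (ssb - (k - 1) * mse) / (sst + mse) * 100
    expect_equal(as.numeric(omega_squared(y, g)), oracle, tolerance = 1e-10)
  }
})

test_that("omega squared is centered on zero under the null", {
  set.seed(6)
  vals <- replicate(300, {
    y <- rnorm(8 * 20)
    as.numeric(omega_squared(y, rep(1:8, each = 20)))
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("omega squared is invariant to affine rescaling of rates", {
  set.seed(8)
  y <- rnorm(40, rep(c(0, 1, 2, 4), each = 10))
  g <- rep(letters[1:4], each = 10)
  base <- as.numeric(omega_squared(y, g))
  expect_equal(as.numeric(omega_squared(3.7 * y, g)), base, tolerance = 1e-10)
  expect_equal(as.numeric(omega_squared(y + 11, g)), base, tolerance = 1e-10)
  expect_equal(as.numeric(omega_squared(2 * y - 5, g)), base, tolerance = 1e-10)
})

test_that("trial stratification downsamples to the smallest group", {
  trials <- tibble::tibble(
    trial_id = 1:37,
    cue_location_deg = c(rep(0, 10), rep(90, 12), rep(180, 15)))
  out <- stratify_trials(trials, seed = 2)
  expect_equal(unname(table(out$cue_location_deg)), rep(10L, 3),
               ignore_attr = TRUE)
  expect_identical(stratify_trials(trials, seed = 2),
                   stratify_trials(trials, seed = 2))
  # equal groups -> identity
  eq <- tibble::tibble(trial_id = 1:8, cue_location_deg = rep(c(0, 180), 4))
  expect_setequal(stratify_trials(eq, seed = 1)$trial_id, eq$trial_id)
  expect_error(stratify_trials(tibble::tibble(trial_id = integer(),
                                              cue_location_deg = numeric())))
})

test_that("pev timecourse agrees with direct omega_squared per bin", {
  ds <- poisson_ds(2, 24, rate_hz = c(5, 12), span = c(-1, 4),
                   locations = rep(canonical_angles(), 3), seed = 10)
  pev <- pev_timecourse(ds, width = 0.5, step = 0.5, span = c(0.5, 3.5),
                        seed = 3)
  strat <- attr(pev, "trials_used")
  sub <- wmstates:::filter_dataset(ds, trial_ids = strat)
  br <- bin_rates(sub, width = 0.5, step = 0.5, span = c(0.5, 3.5))
  f <- sub$trials$cue_location_deg
  direct <- as.numeric(omega_squared(unclass(br)[2, , 3], f))
  expect_equal(pev$omega2[pev$unit_id == 2][3], direct)
})

test_that("session summary separates tuned from untuned sessions", {
  cfg_null <- sim_config(n_neurons = 8, n_trials_per_location = 6, gain = 1,
                         seed = 23)
  null_ds <- simulate_tuned_session(cfg_null)
  p_null <- pev_session_summary(pev_timecourse(null_ds, width = 0.25,
                                               step = 0.25,
                                               span = c(0.5, 3.5), seed = 1))
  expect_gt(p_null$delay_test$p_value, 0.01)

  cfg_tuned <- sim_config(n_neurons = 8, n_trials_per_location = 6, gain = 4,
                          kappa = 3, seed = 24)
  tuned_ds <- simulate_tuned_session(cfg_tuned)
  p_tuned <- pev_session_summary(pev_timecourse(tuned_ds, width = 0.25,
                                                step = 0.25,
                                                span = c(0.5, 3.5), seed = 1))
  expect_lt(p_tuned$delay_test$p_value, 0.001)
  expect_gt(p_tuned$delay_test$estimate, 0)
})
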