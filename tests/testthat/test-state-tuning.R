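mk_labels <- function(df) {
  df$mass <- NA_real_
  df$start_bin <- NA_integer_
  df$end_bin <- NA_integer_
  df[, c("trial_id", "state", "start_bin", "end_bin", "start_s", "end_s",
         "mass")]
}

test_that("identical on and off labels give identical curves, reduction 0", {
  cfg <- sim_config(n_neurons = 6, n_trials_per_location = 4, gain = 4,
                    kappa = 3, seed = 81)
  ds <- simulate_tuned_session(cfg)
  lbl <- mk_labels(purrr::map_dfr(ds$trials$trial_id, function(t) {
    tibble::tibble(trial_id = t, state = c("on", "off"),
                   start_s = 0.5, end_s = 3.5)
  }))
  st <- state_tuning(ds, lbl, n_shuffles = 50, seed = 2)
  on <- st$curves$value[st$curves$state == "on"]
  off <- st$curves$value[st$curves$state == "off"]
  expect_equal(on, off, tolerance = 1e-10)
  expect_equal(st$reduction_pct, 0, tolerance = 1e-8)
})

test_that("randomly assigned labels debias to approximately flat curves", {
  cfg <- sim_config(n_neurons = 8, n_trials_per_location = 5, gain = 4,
                    kappa = 3, seed = 83)
  ds <- simulate_tuned_session(cfg)
  set.seed(4)
  # random half of the delay on, other half off, independent of the data
  lbl <- mk_labels(purrr::map_dfr(ds$trials$trial_id, function(t) {
    cut <- runif(1, 1.2, 2.8)
    flip <- runif(1) < 0.5
    tibble::tibble(trial_id = t,
                   state = if (flip) c("on", "off") else c("off", "on"),
                   start_s = c(0.5, cut), end_s = c(cut, 3.5))
  }))
  st <- state_tuning(ds, lbl, n_shuffles = 400, seed = 5)
  agg <- st$curves |>
    dplyr::group_by(state, offset_deg) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  # debiased mean curves are near zero everywhere (no data-label coupling)
  expect_lt(max(abs(agg$value)), 0.25)
})

test_that("ground-truth off gating collapses off-state tuning depth", {
  cfg <- sim_config(n_neurons = 10, n_trials_per_location = 6, gain = 5,
                    kappa = 3, seed = 85)
  ds <- simulate_tuned_session(cfg, locations = c(0, 180))
  g <- impose_off_states(ds, multiplier = 0, rate_hz = 0.5, seed = 3)
  truth <- g$truth_states[g$truth_states$area == "PFC",
                          c("trial_id", "state", "start_s", "end_s")]
  st <- state_tuning(g$ds, mk_labels(truth), n_shuffles = 300, seed = 6)
  expect_gt(st$reduction_pct, 60)
  expect_gt(mean(st$depth$depth_on), mean(st$depth$depth_off))
})

test_that("state counting uses any-overlap membership in the last window", {
  ds <- poisson_ds(2, 4, rate_hz = 5, locations = c(0, 0, 180, 180), seed = 9)
  ds$trials$correct <- c(TRUE, FALSE, TRUE, TRUE)
  lbl <- mk_labels(tibble::tibble(
    trial_id = c(1, 1, 2, 3),
    state = c("on", "off", "off", "on"),
    start_s = c(2.6, 3.3, 0.6, 3.45),   # 2.6-2.95 misses the last 0.5 s
    end_s   = c(2.95, 3.5, 0.9, 3.5)))
  conf <- tibble::tibble(
    trial_id = rep(1:4, each = 2), time = rep(c(1, 2), 4),
    posterior = c(0.9, 0.9, 0.9, 0.9, 0.2, 0.2, 0.2, 0.2))
  res <- state_counts_by_outcome(ds, lbl, conf, window = 0.5)
  expect_equal(res$preferred_deg, 0)
  expect_equal(res$least_preferred_deg, 180)
  pt <- res$per_trial
  # trial 1: on state [2.8,3.1) misses the window, off [3.3,3.5) overlaps
  expect_equal(pt$n_on[pt$trial_id == 1], 0L)
  expect_equal(pt$n_off[pt$trial_id == 1], 1L)
  # trial 2: off state early in delay does not count
  expect_equal(pt$n_off[pt$trial_id == 2], 0L)
  # trial 3: on state straddling the boundary counts once
  expect_equal(pt$n_on[pt$trial_id == 3], 1L)
})

test_that("cross-areal transfer enforces simultaneity and the source gate", {
  cfg <- sim_config(n_neurons = 10, n_trials_per_location = 3,
                    areas = c("PFC", "PPC"), seed = 87)
  ds <- simulate_tuned_session(cfg, locations = c(0, 180))
  lbl <- mk_labels(tibble::tibble(trial_id = ds$trials$trial_id,
                                  state = "off", start_s = 1, end_s = 2))
  expect_error(cross_areal_transfer(ds, lbl, "PFC", "V4"),
               "both areas")
  expect_error(cross_areal_transfer(ds, lbl, "PFC", "PPC"),
               "< 80 required")
  # with the gate lowered the transfer runs and reports the depth contrast
  res <- suppressWarnings(
    cross_areal_transfer(ds, lbl, "PFC", "PPC", min_source_neurons = 2))
  expect_true(is.finite(res$depth_test$p_value))
  expect_named(res$rate_tests, c("comparison", "statistic", "p_value"))
  expect_setequal(unique(res$curves$condition), c("all", "off"))
})

test_that("the three-way ANOVA surfaces an injected outcome interaction", {
  # synthetic cell means: off states abound on error trials at the
  # preferred location; replicated over 6 sessions with small jitter
  set.seed(12)
  cells <- lapply(1:6, function(s) {
    tidyr::expand_grid(correct = c(TRUE, FALSE),
                       preference = c("preferred", "least"),
                       state = c("on", "off")) |>
      dplyr::mutate(mean_count =
        0.5 + 0.8 * (!correct & preference == "preferred" & state == "off") +
        rnorm(8, 0, 0.05))
  })
  tab <- state_counts_anova(cells)
  three_way <- tab[grepl(".*correct.*preference.*state", tab$term), ]
  expect_equal(nrow(three_way), 1)
  expect_lt(three_way$p_value, 0.01)
  # no-error-trial input warns and returns empty
  expect_warning(empty <- state_counts_anova(
    lapply(cells, function(x) x[x$correct, ])), "skipped")
  expect_equal(nrow(empty), 0)
})
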