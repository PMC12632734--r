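test_that("surrogate variants are identical outside silent windows", {
  cfg <- sim_config(seed = 4)
  pop <- simulate_poisson_population(4, 8, cfg = cfg, seed = 4)
  w <- pop$silent_windows
  sp_all <- pop$no_silence$spikes
  in_win <- rep(FALSE, nrow(sp_all))
  for (r in seq_len(nrow(w))) {
    in_win <- in_win | (sp_all$trial_id == w$trial_id[r] &
                          sp_all$time_s >= w$start_s[r] &
                          sp_all$time_s < w$end_s[r])
  }
  expect_equal(sp_all[!in_win, ], pop$silence$spikes)

  # zero silences -> identical datasets
  cfg0 <- sim_config(silences = list(n_range = c(0, 0), duration_s = 0.1,
                                     coordinated = TRUE))
  pop0 <- simulate_poisson_population(3, 5, cfg = cfg0, seed = 2)
  expect_equal(pop0$no_silence$spikes, pop0$silence$spikes)
})

test_that("surrogate spike counts match Poisson and thinning expectations", {
  cfg <- sim_config(baseline_range = c(10, 10))
  pop <- simulate_poisson_population(1, 1000, cfg = cfg, seed = 8)
  counts <- table(factor(pop$no_silence$spikes$trial_id, levels = 1:1000))
  m <- mean(counts)
  expect_lt(abs(m - 30), 3 * sqrt(30 / 1000))

  # with-silence counts match rate x (3 - union of silent windows) per trial
  w <- pop$silent_windows
  union_dur <- vapply(1:1000, function(t) {
    iv <- w[w$trial_id == t, ]
    if (!nrow(iv)) return(0)
    iv <- iv[order(iv$start_s), ]
    tot <- 0; cur_s <- iv$start_s[1]; cur_e <- iv$end_s[1]
    for (r in seq_len(nrow(iv))[-1]) {
      if (iv$start_s[r] <= cur_e) cur_e <- max(cur_e, iv$end_s[r])
      else { tot <- tot + cur_e - cur_s; cur_s <- iv$start_s[r]; cur_e <- iv$end_s[r] }
    }
    tot + cur_e - cur_s
  }, numeric(1))
  counts_sil <- table(factor(pop$silence$spikes$trial_id, levels = 1:1000))
  expected <- 10 * (3 - union_dur)
  expect_lt(abs(mean(counts_sil - expected)), 3 * sqrt(mean(expected) / 1000))
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_poisson_population(3, 6, seed = 99)
  b <- simulate_poisson_population(3, 6, seed = 99)
  expect_identical(a$no_silence$spikes, b$no_silence$spikes)
  expect_identical(a$silent_windows, b$silent_windows)
  c <- simulate_poisson_population(3, 6, seed = 100)
  expect_false(identical(a$no_silence$spikes, c$no_silence$spikes))

  cfg <- sim_config(n_neurons = 5, n_trials_per_location = 2, seed = 13)
  expect_identical(simulate_tuned_session(cfg)$spikes,
                   simulate_tuned_session(cfg)$spikes)
})

test_that("tuned sessions honor their ground truth", {
  cfg <- sim_config(n_neurons = 10, n_trials_per_location = 6,
                    baseline_range = c(10, 10), kappa = 3, gain = 4,
                    seed = 17)
  ds <- simulate_tuned_session(cfg)
  truth <- attr(ds, "truth")
  expect_equal(nrow(truth), 10)
  # fixation rate ~ baseline, cue+delay rate elevated near preferred cue
  fix <- wmstates:::epoch_mean_rates(ds, c(-1, 0))
  expect_lt(abs(mean(fix) - 10), 1.5)
  # spikes stay inside trial bounds; dataset passes validation implicitly
  expect_true(all(ds$spikes$time_s >= -1 & ds$spikes$time_s <= 4.1))
})

test_that("off-state gating flattens tuned spikes inside truth windows only", {
  cfg <- sim_config(n_neurons = 6, n_trials_per_location = 4, gain = 4,
                    kappa = 3, seed = 21)
  ds <- simulate_tuned_session(cfg, locations = c(0, 180))

  g1 <- impose_off_states(ds, multiplier = 1, seed = 5)
  expect_equal(g1$ds$spikes, ds$spikes)  # multiplier 1 is the identity

  g0 <- impose_off_states(ds, multiplier = 0, seed = 5)
  off <- g0$truth_states[g0$truth_states$state == "off", ]
  sp <- g0$ds$spikes
  tuned_in_off <- purrr::map_int(seq_len(nrow(off)), function(r) {
    sum(sp$source == "tuned" & sp$trial_id == off$trial_id[r] &
          sp$time_s >= off$start_s[r] & sp$time_s < off$end_s[r])
  })
  expect_equal(sum(tuned_in_off), 0L)
  # baseline spikes persist during off states
  base_in_off <- purrr::map_int(seq_len(nrow(off)), function(r) {
    sum(sp$source == "baseline" & sp$trial_id == off$trial_id[r] &
          sp$time_s >= off$start_s[r] & sp$time_s < off$end_s[r])
  })
  expect_gt(sum(base_in_off), 0L)
  expect_error(impose_off_states(ds, multiplier = 1.2), "\\[0, 1\\]")
})

test_that("behavior links RT to the go-cue state exactly when noiseless", {
  cfg <- sim_config(n_neurons = 4, n_trials_per_location = 10, seed = 31)
  ds <- simulate_tuned_session(cfg, locations = c(0, 180))
  g <- impose_off_states(ds, multiplier = 0, rate_hz = 1, seed = 2)
  rt_model <- list(base_ms = 200, beta_state_ms = 10, noise_sd_ms = 0,
                   p_error_base = 0.1, p_error_off_slope = 0.3)
  ds2 <- simulate_behavior(g$ds, g$truth_states, rt_model, seed = 3)
  st <- g$truth_states[g$truth_states$area == "PFC", ]
  at_go <- st[st$start_s <= 3.5 - 1e-9 & st$end_s >= 3.5 - 1e-9, ]
  on_ids <- at_go$trial_id[at_go$state == "on"]
  rts <- ds2$trials$rt_ms
  expect_true(all(rts[ds2$trials$trial_id %in% on_ids] == 210))
  expect_true(all(rts[!ds2$trials$trial_id %in% on_ids] == 200))
})
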