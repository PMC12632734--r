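test_that("bin_rates counts spikes into half-open bins and converts to rates", {
  ds <- make_ds(list(c(0.01, 0.02, 0.54)))
  br <- bin_rates(ds, width = 0.5, step = 0.5, span = c(0, 1))
  expect_equal(as.numeric(br[1, 1, ]), c(2, 1) / 0.5)  # counts over width
  expect_equal(as.numeric(br[1, 1, ]), c(4, 2))

  # empty bins are zero
  ds0 <- make_ds(list(c(3.9)))
  br0 <- bin_rates(ds0, width = 0.5, step = 0.5, span = c(0, 1))
  expect_true(all(br0 == 0))
})

test_that("bin_rates conserves total spike count with non-overlapping bins", {
  set.seed(42)
  for (rep in 1:5) {
    ds <- poisson_ds(3, 4, rate_hz = c(5, 10, 15), span = c(-1, 4),
                     seed = rep)
    br <- bin_rates(ds, width = 0.1, step = 0.1, span = c(-1, 4.1))
    expect_equal(sum(br) * 0.1, nrow(ds$spikes))
  }
})

test_that("bin_rates recovers a homogeneous Poisson rate", {
  ds <- poisson_ds(1, 200, rate_hz = 10, span = c(0.5, 3.5), seed = 11)
  br <- bin_rates(ds, width = 0.05, step = 0.05, span = c(0.5, 3.5))
  m <- mean(br)
  se <- sd(br) / sqrt(length(br))
  expect_lt(abs(m - 10), 3 * se + 1e-9)
})

test_that("bin_rates validates its inputs", {
  ds <- make_ds(list(c(0.1)))
  expect_error(bin_rates(ds, width = 0), "positive")
  expect_error(bin_rates(ds, span = c(-5, 10)), "outside")
})

test_that("preferred_location matches the complex-resultant oracle", {
  # all mass at 90 degrees
  pl <- preferred_location(c(0, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(pl$theta_pref_deg, 90)
  expect_equal(pl$modulus, 1)

  # symmetric counts: modulus 0, angle undefined
  pl0 <- preferred_location(rep(2, 8))
  expect_false(pl0$defined)
  expect_equal(pl0$modulus, 0, tolerance = 1e-12)
  expect_true(is.na(pl0$theta_pref_deg))

  # equal mass at 0 and 90: oracle = Mod/Arg of (5 + 5i)/10
  pl45 <- preferred_location(c(5, 0, 5, 0, 0, 0, 0, 0))
  expect_equal(pl45$theta_pref_deg, 45, tolerance = 1e-10)
  expect_equal(pl45$modulus, cos(45 * pi / 180), tolerance = 1e-10)

  expect_error(preferred_location(rep(0, 8)), "undefined")
  expect_error(preferred_location(c(-1, rep(1, 7))), "non-negative")
})

test_that("preferred_location is rotation-equivariant", {
  set.seed(7)
  ang <- canonical_angles()
  for (rep in 1:20) {
    n <- runif(8, 0, 5)
    n[sample(8, 1)] <- n[sample(8, 1)] + 1  # avoid exact symmetry
    delta <- runif(1, 0, 360)
    a <- preferred_location(n, ang)
    b <- preferred_location(n, (ang + delta) %% 360)
    if (a$defined && b$defined) {
      d <- (b$theta_pref_deg - a$theta_pref_deg - delta) %% 360
      expect_lt(min(d, 360 - d), 1e-6)
      expect_equal(a$modulus, b$modulus, tolerance = 1e-10)
    }
  }
})

test_that("laminar classes follow half-open depth boundaries", {
  expect_equal(as.character(laminar_class(c(0, 0.79, 0.8, 1.19, 1.2, 1.9))),
               c("superficial", "superficial", "middle", "middle",
                 "deep", "deep"))
  expect_error(laminar_class(-0.1), "non-negative")
})

test_that("selectivity requires both ANOVA significance and the rate gate", {
  set.seed(3)
  # unit 1: 20 Hz at location 0, 1 Hz elsewhere; unit 2: tuned but peak 1 Hz
  locs <- rep(canonical_angles(), each = 10)
  trials <- tibble::tibble(trial_id = seq_along(locs), cue_location_deg = locs)
  mk <- function(u, peak, base) {
    purrr::map_dfr(seq_along(locs), function(t) {
      r <- if (locs[t] == 0) peak else base
      n <- rpois(1, r * 3)
      if (!n) return(NULL)
      tibble::tibble(unit_id = u, trial_id = t,
                     time_s = runif(n, 0.5, 3.5))
    })
  }
  sp <- dplyr::bind_rows(mk(1, 20, 1), mk(2, 1, 0.05))
  ds <- spike_dataset(sp, trials, tibble::tibble(unit_id = 1:2))
  sel <- classify_selectivity(ds)
  expect_true(sel$selective[sel$unit_id == 1])
  expect_false(sel$selective[sel$unit_id == 2])  # rate gate (peak ~1 Hz)
  expect_lt(sel$p_value[sel$unit_id == 2], 0.05) # tuned, but gated out

  # independent F-statistic oracle on unit 1's epoch-mean rates
  rates <- tapply(sp$time_s[sp$unit_id == 1] >= 0.5 &
                    sp$time_s[sp$unit_id == 1] < 3.5,
                  sp$trial_id[sp$unit_id == 1], sum)
  y <- rep(0, nrow(trials)); y[as.integer(names(rates))] <- rates / 3
  k <- 8; n <- length(y)
  gm <- mean(y); mns <- tapply(y, locs, mean)
  ssb <- sum(10 * (mns - gm)^2)
  ssw <- sum((y - mns[as.character(locs)])^2)
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  p_oracle <- pf(f_oracle, k - 1, n - k, lower.tail = FALSE)
  expect_equal(sel$p_value[sel$unit_id == 1], p_oracle, tolerance = 1e-8)
})

test_that("selectivity p-values are uniform under an untuned Poisson null", {
  ds <- poisson_ds(100, 24, rate_hz = rep(c(4, 8, 12, 16), 25),
                   locations = rep(canonical_angles(), each = 3), seed = 5)
  sel <- classify_selectivity(ds, min_rate = 0)
  ks <- suppressWarnings(ks.test(sel$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("selectivity errors name locations with too few trials", {
  ds <- poisson_ds(2, 9, rate_hz = 5,
                   locations = c(rep(0, 8), 45), seed = 1)
  expect_error(classify_selectivity(ds), "45")
})

test_that("delay elevation test flags doubled delay rates and not null ones", {
  set.seed(9)
  build <- function(delay_rate) {
    sp <- purrr::map_dfr(1:5, function(u) {
      purrr::map_dfr(1:50, function(t) {
        tm <- c(runif(rpois(1, 10 * 1), -1, 0),
                runif(rpois(1, delay_rate * 3), 0.5, 3.5))
        if (!length(tm)) return(NULL)
        tibble::tibble(unit_id = u, trial_id = t, time_s = tm)
      })
    })
    spike_dataset(sp, tibble::tibble(trial_id = 1:50, cue_location_deg = 0),
                  tibble::tibble(unit_id = 1:5))
  }
  elev <- delay_elevation_test(build(20), cue_location = 0)
  expect_equal(nrow(elev), 60)  # 3 s delay / 50 ms bins
  expect_true(all(elev$significant))

  null <- delay_elevation_test(build(10), cue_location = 0)
  expect_lt(mean(null$significant), 0.1)
})

test_that("BH-FDR significance is monotone in q", {
  set.seed(21)
  ds <- poisson_ds(4, 30, rate_hz = 8, span = c(-1, 3.5), seed = 3)
  res <- delay_elevation_test(ds, cue_location = 0, q = 0.05)
  flags_strict <- res$p_adj < 0.01
  flags_loose <- res$p_adj < 0.20
  expect_true(all(flags_loose[flags_strict]))
})

test_that("dataset validation catches orphans, bad times and bad locations", {
  sp <- tibble::tibble(unit_id = 1, trial_id = 1, time_s = 0.2)
  tr <- tibble::tibble(trial_id = 1, cue_location_deg = 0)
  un <- tibble::tibble(unit_id = 1)
  expect_s3_class(spike_dataset(sp, tr, un), "spike_dataset")
  expect_error(spike_dataset(dplyr::mutate(sp, unit_id = 9), tr, un),
               "unknown unit_id")
  expect_error(spike_dataset(dplyr::mutate(sp, trial_id = 9), tr, un),
               "unknown trial_id")
  expect_error(spike_dataset(dplyr::mutate(sp, time_s = 9), tr, un),
               "bounds")
  # 120-location variant is snapped to canonical angles
  ds <- spike_dataset(sp, dplyr::mutate(tr, cue_location_deg = 93), un)
  expect_equal(ds$trials$cue_location_deg, 90)
})
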