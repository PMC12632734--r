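test_that("population ISI counts pooled within-trial intervals", {
  ds <- make_ds(list(c(0.6, 1.4, 3.0)))
  res <- population_isi(ds, unit_ids = 1)
  expect_equal(res$max_isi_s, 1.6)
  expect_equal(res$rate_hz, 3 / 3)

  # two identical trials: same max ISI, rate unchanged
  ds2 <- make_ds(list(c(0.6, 1.4, 3.0), c(0.6, 1.4, 3.0)))
  res2 <- population_isi(ds2, unit_ids = 1)
  expect_equal(res2$max_isi_s, 1.6)
  expect_equal(res2$rate_hz, 6 / 6)

  # no interval ever spans a trial boundary
  ds3 <- make_ds(list(c(0.6), c(3.4, 3.45)))
  expect_equal(population_isi(ds3, 1)$max_isi_s, 0.05, tolerance = 1e-9)

  expect_error(population_isi(make_ds(list(c(1.0))), 1), "no ISI")
})

test_that("max ISI never grows when spikes are added inside the train span", {
  # (a spike beyond the last one creates a new interval and may enlarge it,
  # so monotonicity holds for interior insertions)
  set.seed(31)
  for (rep in 1:10) {
    base <- sort(runif(20, 0.5, 3.5))
    inner <- runif(3, min(base) + 1e-6, max(base) - 1e-6)
    ds_a <- make_ds(list(base))
    ds_b <- make_ds(list(sort(c(base, inner))))
    expect_lte(population_isi(ds_b, 1)$max_isi_s,
               population_isi(ds_a, 1)$max_isi_s)
  }
})

test_that("trial shuffling conserves rate exactly and is seeded", {
  pop <- simulate_poisson_population(4, 6, seed = 33)
  ds <- pop$no_silence
  emp <- population_isi(ds, 1:4)
  nl <- isi_shuffle_null(ds, 1:4, n_iter = 30, seed = 1)
  expect_equal(unique(nl$rate_hz), emp$rate_hz)   # FreqShuffled == FreqEmpirical
  nl2 <- isi_shuffle_null(ds, 1:4, n_iter = 30, seed = 1)
  expect_identical(nl, nl2)
  expect_error(isi_shuffle_null(make_ds(list(c(1, 2))), 1), "single trial")
})

test_that("single-neuron shuffles only relabel trials: null equals empirical", {
  ds <- poisson_ds(1, 5, rate_hz = 8, seed = 35)
  emp <- population_isi(ds, 1)
  nl <- isi_shuffle_null(ds, 1, n_iter = 25, seed = 2)
  expect_true(all(nl$max_isi_s == emp$max_isi_s))
})

test_that("pooled Poisson max ISI matches the extreme-value approximation", {
  # pooled rate lambda over total duration T: E[max ISI] ~ ln(lambda T)/lambda
  # (leading-order extreme-value term; accurate to ~gamma/ln(lambda T))
  set.seed(37)
  lambda <- 30; n_trials <- 15
  pkg <- replicate(300, {
    trains <- lapply(seq_len(n_trials), function(t) {
      tm <- numeric()
      while (length(tm) < 2) tm <- sort(runif(rpois(1, lambda * 3), 0.5, 3.5))
      tm
    })
    population_isi(make_ds(trains), 1)$max_isi_s
  })
  approx <- log(lambda * 3 * n_trials) / lambda
  expect_lt(abs(mean(pkg) - approx) / approx, 0.10)
})

test_that("the log-log regression matches lm and rejects degenerate input", {
  set.seed(39)
  emp <- tibble::tibble(rate_hz = c(2, 5, 11, 19, 40),
                        max_isi_s = c(1.2, 0.5, 0.3, 0.2, 0.1))
  nullm <- matrix(rexp(5 * 200, 5), 5, 200)
  res <- isi_loglog_test(emp, nullm)
  ref <- lm(log10(max_isi_s) ~ log10(rate_hz), data = emp)
  expect_equal(res$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(res$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  # iteration-matched null regressions, checked against lm on one column
  j <- 17
  refj <- lm(log10(nullm[, j]) ~ log10(emp$rate_hz))
  expect_equal(res$null_slopes[j], unname(coef(refj)[2]), tolerance = 1e-10)
  # tails partition the null (no ties generically): p_f + p_s = 1 + 1/(B+1)
  expect_equal(res$p_flatter + res$p_steeper, 1 + 1 / 201, tolerance = 1e-10)

  expect_error(isi_loglog_test(emp[1:2, ], nullm[1:2, ]), ">= 3")
  emp_eq <- dplyr::mutate(emp, rate_hz = 7)
  expect_error(isi_loglog_test(emp_eq, nullm), "slope undefined")
})

test_that("selected populations group delay-selective units by preference", {
  cfg <- sim_config(n_neurons = 12, n_trials_per_location = 5,
                    baseline_range = c(8, 15), kappa = 6, gain = 6, seed = 41)
  ds <- simulate_tuned_session(cfg)
  # force all ground-truth preferences to 0 deg by regenerating: instead,
  # verify grouping consistency against per-unit tables
  sel <- classify_selectivity(ds)
  pl <- unit_preferred_locations(ds)
  pops <- select_populations(ds, min_n = 1, selectivity = sel, prefs = pl)
  for (i in seq_len(nrow(pops))) {
    uids <- pops$unit_ids[[i]]
    expect_true(all(sel$selective[match(uids, sel$unit_id)]))
    expect_true(all(pl$pref_canonical_deg[match(uids, pl$unit_id)] ==
                      pops$location_deg[i]))
  }
  # raising the gate can only shrink the candidate set
  pops5 <- select_populations(ds, min_n = 5, selectivity = sel, prefs = pl)
  expect_true(all(pops5$n_units >= 5))
  expect_lte(nrow(pops5), nrow(pops))
})
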