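# Synthetic spike-train generator: tuned Poisson populations, surrogate
# populations with imposed coordinated silences, off-state gating, behavior.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-session configuration
#'
#' Parameterizes the synthetic spike generator. Defaults emulate the
#' recorded sessions the analyses target: ~100 units per session at
#' baseline rates drawn from a discrete uniform 1-20 Hz, von Mises
#' location tuning during cue and delay, 20 trials per cue location, and
#' (optionally) coordinated off-state gating of the tuned modulation plus a
#' linked reaction-time model.
#'
#' @param n_neurons Units per session (default 100).
#' @param n_trials_per_location Trials at each of the 8 cue locations
#'   (default 20).
#' @param baseline_range Integer range of per-neuron baseline rates in Hz
#'   (default `c(1, 20)`, discrete uniform).
#' @param kappa Von Mises tuning concentration (default 2).
#' @param gain Peak-to-baseline rate multiplier at the preferred location
#'   (default 3; 1 = untuned).
#' @param silences List: `n_range` silences per trial (default `c(1, 3)`),
#'   `duration_s` (default 0.1), `coordinated` (shared across neurons,
#'   default TRUE).
#' @param off_gating List: `enabled` (default FALSE), `rate_hz` full
#'   on+off alternation cycles per second (default 1), `off_fraction`
#'   stationary off-time fraction (default 0.5), `multiplier` for tuned
#'   modulation during off states (0 = complete flattening).
#' @param rt_model List: `base_ms`, `beta_state_ms` (RT_on - RT_off),
#'   `noise_sd_ms`, `p_error_base`, `p_error_off_slope`.
#' @param areas Area label(s); units are split evenly across them.
#' @param seed Integer seed; fully determines the output.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_neurons = 100, n_trials_per_location = 20,
                       baseline_range = c(1, 20), kappa = 2, gain = 3,
                       silences = list(n_range = c(1, 3), duration_s = 0.1,
                                       coordinated = TRUE),
                       off_gating = list(enabled = FALSE, rate_hz = 1,
                                         off_fraction = 0.5, multiplier = 0),
                       rt_model = list(base_ms = 200, beta_state_ms = 0,
                                       noise_sd_ms = 20, p_error_base = 0.08,
                                       p_error_off_slope = 0.3),
                       areas = "PFC", seed = 1) {
  stopifnot(n_neurons >= 1, n_trials_per_location >= 1,
            baseline_range[1] > 0, kappa >= 0, gain >= 1,
            silences$duration_s > 0)
  if (!is.null(off_gating$multiplier) &&
      (off_gating$multiplier < 0 || off_gating$multiplier > 1)) {
    abort("off-gating multiplier must lie in [0, 1]")
  }
  structure(list(n_neurons = n_neurons,
                 n_trials_per_location = n_trials_per_location,
                 baseline_range = baseline_range, kappa = kappa, gain = gain,
                 silences = silences, off_gating = off_gating,
                 rt_model = rt_model, areas = areas, seed = seed),
            class = "sim_config")
}

# discrete uniform draw on lo..hi, safe when lo == hi (unlike sample())
runif_int <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n,
                                                 replace = TRUE) - 1L

# homogeneous Poisson spikes on [a, b): count ~ Poisson(rate * (b - a)),
# times uniform (order statistics construction)
poisson_times <- function(rate, a, b) {
  n <- rpois(1, rate * (b - a))
  sort(runif(n, a, b))
}

#' Simulate surrogate Poisson populations with and without silent periods
#'
#' Builds one homogeneous-Poisson population (3 s delay-period trials,
#' per-neuron rates discrete uniform over `baseline_range`) and a paired
#' copy in which spikes falling inside each trial's silent windows (1-3 per
#' trial, 100 ms each, placed uniformly; shared across all neurons when
#' `coordinated`) are deleted. Outside the silent windows the two variants
#' are identical. Trials are laid on the delay period `[0.5, 3.5)` so the
#' result is a valid [spike_dataset()].
#'
#' @param n_neurons,n_trials Population size and trial count.
#' @param cfg A [sim_config()] supplying rates and silence parameters.
#' @param seed Integer seed (default `cfg$seed`).
#'
#' @return List: `no_silence` and `silence` ([spike_dataset()]s sharing
#'   base spikes), `silent_windows` (tibble `trial_id`, `start_s`, `end_s`),
#'   `rates_hz` (per-neuron).
#' @export
simulate_poisson_population <- function(n_neurons, n_trials,
                                        cfg = sim_config(), seed = cfg$seed) {
  delay <- c(0.5, 3.5)
  with_seed(seed, {
    rates <- runif_int(n_neurons, cfg$baseline_range[1],
                       cfg$baseline_range[2])
    sp <- purrr::map_dfr(seq_len(n_neurons), function(i) {
      counts <- rpois(n_trials, rates[i] * (delay[2] - delay[1]))
      tibble(unit_id = i, trial_id = rep(seq_len(n_trials), counts),
             time_s = runif(sum(counts), delay[1], delay[2]))
    })
    sp <- dplyr::arrange(sp, .data$unit_id, .data$trial_id, .data$time_s)
    n_sil <- runif_int(n_trials, cfg$silences$n_range[1],
                       cfg$silences$n_range[2])
    windows <- purrr::map_dfr(seq_len(n_trials), function(t) {
      on <- runif(n_sil[t], delay[1], delay[2])
      tibble(trial_id = t, start_s = on,
             end_s = pmin(on + cfg$silences$duration_s, delay[2]))
    })
    in_window <- rep(FALSE, nrow(sp))
    for (r in seq_len(nrow(windows))) {
      in_window <- in_window |
        (sp$trial_id == windows$trial_id[r] &
           sp$time_s >= windows$start_s[r] & sp$time_s < windows$end_s[r])
    }
    trials <- tibble(trial_id = seq_len(n_trials), cue_location_deg = 0)
    units <- tibble(unit_id = seq_len(n_neurons), area = "PFC",
                    depth_mm = 0, kind = "single")
    list(
      no_silence = spike_dataset(sp, trials, units),
      silence = spike_dataset(sp[!in_window, ], trials, units),
      silent_windows = windows,
      rates_hz = rates
    )
  })
}

# von Mises-shaped modulation in [0, 1], peak 1 at the preferred angle
vm_modulation <- function(theta_deg, pref_deg, kappa) {
  exp(kappa * (cos((theta_deg - pref_deg) * pi / 180) - 1))
}

#' Simulate a tuned delayed-response session
#'
#' Inhomogeneous-Poisson session: every neuron fires at its baseline rate
#' throughout the trial and superimposes a tuned Poisson process at rate
#' `(gain - 1) * baseline * m(theta)` during cue and delay, where `m` is a
#' von Mises bump (concentration `kappa`) around the neuron's ground-truth
#' preferred angle. Ground truth (per-neuron baseline, preferred angle) is
#' attached as attribute `truth`; spikes carry a `source` column
#' (`"baseline"`/`"tuned"`) used by [impose_off_states()].
#'
#' @param cfg A [sim_config()].
#' @param locations Cue angles used (default all 8 canonical).
#' @param seed Integer seed (default `cfg$seed`).
#' @return A [spike_dataset()] with attribute `truth`.
#' @export
simulate_tuned_session <- function(cfg = sim_config(),
                                   locations = canonical_angles(),
                                   seed = cfg$seed) {
  with_seed(seed, {
    n <- cfg$n_neurons
    baseline <- runif_int(n, cfg$baseline_range[1], cfg$baseline_range[2])
    pref <- runif(n, 0, 360)
    area <- rep(cfg$areas, each = ceiling(n / length(cfg$areas)))[seq_len(n)]

    trials <- tibble(
      trial_id = seq_len(length(locations) * cfg$n_trials_per_location),
      cue_location_deg = rep(locations, each = cfg$n_trials_per_location)
    )
    tuned_span <- c(0, 3.5)  # cue + delay
    full_span <- c(-1, 4.1)

    n_tr <- nrow(trials)
    sp <- purrr::map_dfr(seq_len(n), function(i) {
      nb <- rpois(n_tr, baseline[i] * (full_span[2] - full_span[1]))
      m <- vm_modulation(trials$cue_location_deg, pref[i], cfg$kappa)
      nt <- rpois(n_tr, (cfg$gain - 1) * baseline[i] * m *
                    (tuned_span[2] - tuned_span[1]))
      tibble(
        unit_id = i,
        trial_id = c(rep(trials$trial_id, nb), rep(trials$trial_id, nt)),
        time_s = c(runif(sum(nb), full_span[1], full_span[2]),
                   runif(sum(nt), tuned_span[1], tuned_span[2])),
        source = rep(c("baseline", "tuned"), c(sum(nb), sum(nt))))
    })
    sp <- dplyr::arrange(sp, .data$unit_id, .data$trial_id, .data$time_s)
    units <- tibble(unit_id = seq_len(n), area = area,
                    depth_mm = runif(n, 0, 2), kind = "single")
    ds <- spike_dataset(sp, trials, units)
    attr(ds, "truth") <- tibble(unit_id = seq_len(n),
                                baseline_hz = baseline, pref_deg = pref)
    ds
  })
}

# alternating on/off renewal train on [a, b): exponential holding times
# with mean off_fraction/rate_hz (off) and (1 - off_fraction)/rate_hz (on),
# i.e. rate_hz full on+off cycles per second and a stationary off-time
# fraction of off_fraction; returns tibble(state, start_s, end_s)
state_train <- function(a, b, rate_hz, off_fraction = 0.5) {
  mean_dur <- c(on = (1 - off_fraction) / rate_hz,
                off = off_fraction / rate_hz)
  t <- a
  state <- sample(c("on", "off"), 1,
                  prob = c(1 - off_fraction, off_fraction))
  out <- list()
  while (t < b) {
    d <- rexp(1, 1 / mean_dur[[state]])
    out[[length(out) + 1]] <- tibble(state = state, start_s = t,
                                     end_s = min(t + d, b))
    t <- t + d
    state <- if (state == "on") "off" else "on"
  }
  dplyr::bind_rows(out)
}

#' Impose coordinated off states on a tuned session
#'
#' Generates a ground-truth alternating on/off state train per trial over
#' the delay period (shared across all neurons of an area; optionally one
#' train shared across areas) and, within off intervals, thins the
#' tuned-source spikes so the tuned modulation is multiplied by
#' `multiplier` (0 = complete flattening) while baseline firing persists.
#'
#' @param ds Output of [simulate_tuned_session()] (spikes must carry a
#'   `source` column).
#' @param multiplier Tuning multiplier during off states, in `[0, 1]`.
#' @param rate_hz Full on+off alternation cycles per second (so the mean
#'   off-state duration is `off_fraction/rate_hz`).
#' @param off_fraction Stationary fraction of time spent off (default 0.5;
#'   transient-dip regimes use smaller values).
#' @param shared_across_areas One state train for all areas (`TRUE`,
#'   default) or an independent train per area.
#' @param span Interval gated (default the delay period).
#' @param seed Integer seed.
#'
#' @return List: `ds` (gated dataset, still carrying `truth`), `truth_states`
#'   (tibble `area`, `trial_id`, `state`, `start_s`, `end_s`).
#' @export
impose_off_states <- function(ds, multiplier = 0, rate_hz = 1,
                              off_fraction = 0.5,
                              shared_across_areas = TRUE,
                              span = c(0.5, 3.5), seed = 1) {
  stopifnot(inherits(ds, "spike_dataset"))
  if (multiplier < 0 || multiplier > 1) {
    abort("off-gating multiplier must lie in [0, 1]")
  }
  if (!"source" %in% names(ds$spikes)) {
    abort("dataset lacks spike provenance ('source' column); use simulate_tuned_session()")
  }
  areas <- unique(ds$units$area)
  with_seed(seed, {
    truth <- purrr::map_dfr(ds$trials$trial_id, function(t) {
      if (shared_across_areas) {
        st <- state_train(span[1], span[2], rate_hz, off_fraction)
        purrr::map_dfr(areas, function(a) {
          dplyr::mutate(st, area = a, trial_id = t)
        })
      } else {
        purrr::map_dfr(areas, function(a) {
          dplyr::mutate(state_train(span[1], span[2], rate_hz, off_fraction),
                        area = a, trial_id = t)
        })
      }
    })
    sp <- ds$spikes
    spike_area <- ds$units$area[match(sp$unit_id, ds$units$unit_id)]
    off <- truth[truth$state == "off", ]
    drop <- rep(FALSE, nrow(sp))
    is_tuned <- sp$source == "tuned"
    key_sp <- paste(spike_area, sp$trial_id)
    idx_by_key <- split(which(is_tuned), key_sp[is_tuned])
    for (k in unique(paste(off$area, off$trial_id))) {
      idx <- idx_by_key[[k]]
      if (is.null(idx)) next
      w <- off[paste(off$area, off$trial_id) == k, ]
      hit <- rep(FALSE, length(idx))
      for (r in seq_len(nrow(w))) {
        hit <- hit | (sp$time_s[idx] >= w$start_s[r] &
                        sp$time_s[idx] < w$end_s[r])
      }
      if (any(hit)) {
        drop[idx[hit]] <- runif(sum(hit)) > multiplier
      }
    }
    gated <- ds
    gated$spikes <- sp[!drop, ]
    list(ds = gated,
         truth_states = truth[, c("area", "trial_id", "state",
                                  "start_s", "end_s")])
  })
}

#' Simulate behavior linked to ground-truth states
#'
#' Reaction time per trial is `base + beta_state * 1[state = on at the go
#' cue] + Gaussian noise`; the error probability grows with the fraction of
#' off-labeled time in the last 0.5 s of the delay.
#'
#' @param ds A [spike_dataset()].
#' @param truth_states Ground-truth state tibble from [impose_off_states()]
#'   (one area is used; pass a filtered table for area-specific behavior).
#' @param rt_model List with `base_ms`, `beta_state_ms`, `noise_sd_ms`,
#'   `p_error_base`, `p_error_off_slope` (see [sim_config()]).
#' @param seed Integer seed.
#' @return The dataset with `rt_ms` and `correct` filled in its trial table.
#' @export
simulate_behavior <- function(ds, truth_states,
                              rt_model = sim_config()$rt_model, seed = 1) {
  stopifnot(inherits(ds, "spike_dataset"))
  go <- epoch_interval("delay", ds$epochs)[2]
  st <- truth_states[truth_states$area == truth_states$area[1], ]
  with_seed(seed, {
    trials <- ds$trials
    rt <- numeric(nrow(trials))
    correct <- logical(nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tid <- trials$trial_id[i]
      tr_st <- st[st$trial_id == tid, ]
      at_go <- tr_st[tr_st$start_s <= go - 1e-9 & tr_st$end_s >= go - 1e-9, ]
      on_at_go <- nrow(at_go) > 0 && at_go$state[1] == "on"
      rt[i] <- rt_model$base_ms + rt_model$beta_state_ms * on_at_go +
        rnorm(1, 0, rt_model$noise_sd_ms)
      late <- tr_st[tr_st$end_s > go - 0.5, ]
      off_frac <- if (nrow(late)) {
        sum(pmax(0, pmin(late$end_s, go) - pmax(late$start_s, go - 0.5)) *
              (late$state == "off")) / 0.5
      } else 0
      p_err <- min(0.95, max(0, rt_model$p_error_base +
                               rt_model$p_error_off_slope * off_frac))
      correct[i] <- runif(1) > p_err
    }
    trials$rt_ms <- rt
    trials$correct <- correct
    ds$trials <- trials
    ds
  })
}
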