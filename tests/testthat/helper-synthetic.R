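# Shared fixture builders; everything generated in code at test time.

# minimal dataset from a spike-time list: spikes[[trial]] per single unit, or
# a data.frame; locations default to one cue
make_ds <- function(spikes, trials = NULL, units = NULL) {
  if (!is.data.frame(spikes)) {
    spikes <- purrr::imap_dfr(spikes, function(tm, t) {
      tibble::tibble(unit_id = 1, trial_id = t, time_s = tm)
    })
  }
  trials <- trials %||% tibble::tibble(
    trial_id = sort(unique(spikes$trial_id)), cue_location_deg = 0)
  units <- units %||% tibble::tibble(unit_id = sort(unique(spikes$unit_id)))
  spike_dataset(spikes, trials, units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# homogeneous-Poisson dataset: one rate per unit, uniform spikes over span
poisson_ds <- function(n_units, n_trials, rate_hz, span = c(0.5, 3.5),
                       locations = 0, seed = 1) {
  set.seed(seed)
  trials <- tibble::tibble(
    trial_id = seq_len(n_trials),
    cue_location_deg = rep(locations, length.out = n_trials))
  rate_hz <- rep(rate_hz, length.out = n_units)
  sp <- purrr::map_dfr(seq_len(n_units), function(u) {
    purrr::map_dfr(seq_len(n_trials), function(t) {
      n <- stats::rpois(1, rate_hz[u] * diff(span))
      if (!n) return(NULL)
      tibble::tibble(unit_id = u, trial_id = t,
                     time_s = sort(stats::runif(n, span[1], span[2])))
    })
  })
  units <- tibble::tibble(unit_id = seq_len(n_units))
  spike_dataset(sp, trials, units)
}

# hand-built confidence_null object for state-labeling oracles
fake_confidence_null <- function(posterior, shuffles,
                                 times = NULL, step = 0.05, width = 0.1) {
  stopifnot(length(dim(shuffles)) == 3)
  times <- times %||% (0.55 + (seq_len(ncol(posterior)) - 1) * step)
  structure(list(
    trial_id = seq_len(nrow(posterior)), times = times,
    posterior = posterior,
    null_mean = apply(shuffles, c(1, 2), mean),
    null_sd = apply(shuffles, c(1, 2), sd),
    shuffles = shuffles, bin_width = width, bin_step = step,
    pair = c(0, 180)), class = "confidence_null")
}

# trial x bin logical mask for a label table on a bin grid
label_mask <- function(labels, trial_ids, times, state) {
  m <- matrix(FALSE, length(trial_ids), length(times))
  sel <- labels[labels$state == state, ]
  for (r in seq_len(nrow(sel))) {
    i <- match(sel$trial_id[r], trial_ids)
    if (!is.na(i)) m[i, times >= sel$start_s[r] & times < sel$end_s[r]] <- TRUE
  }
  m
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# truth off mask from an impose_off_states() result
truth_off_mask <- function(truth_states, area, trial_ids, times) {
  tr <- truth_states[truth_states$area == area & truth_states$state == "off", ]
  m <- matrix(FALSE, length(trial_ids), length(times))
  for (r in seq_len(nrow(tr))) {
    i <- match(tr$trial_id[r], trial_ids)
    if (!is.na(i)) m[i, times >= tr$start_s[r] & times < tr$end_s[r]] <- TRUE
  }
  m
}
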