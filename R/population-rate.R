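#' Population firing rate at each neuron's preferred location
#'
#' Averages, per time bin, the firing rate of every neuron over the trials
#' of that neuron's preferred cue location, then across neurons — the
#' population time course of activity for remembered preferred stimuli.
#' Neurons with an undefined preferred location, or with no trials at it,
#' are excluded with a warning. When on/off state labels are supplied,
#' additional traces restricted to on- and off-labeled time are returned.
#'
#' @param ds A [spike_dataset()].
#' @param states Optional state-label tibble (see [label_states()]) with
#'   columns `trial_id`, `state`, `start_s`, `end_s`.
#' @param width Bin width in seconds (default 0.05, non-overlapping).
#' @param prefs Optional precomputed [unit_preferred_locations()] table.
#'
#' @return Tibble: `time`, `state` (`"all"`, and `"on"`/`"off"` when
#'   `states` given), `rate` (spikes/s, mean across neurons), `n_units`.
#' @export
population_rate_preferred <- function(ds, states = NULL, width = 0.05,
                                      prefs = NULL) {
  stopifnot(inherits(ds, "spike_dataset"))
  prefs <- prefs %||% unit_preferred_locations(ds)
  prefs <- prefs[prefs$defined, ]
  br <- bin_rates(ds, width = width, step = width)
  times <- attr(br, "times")
  unit_ids <- attr(br, "unit_id")
  trial_ids <- attr(br, "trial_id")

  trial_loc <- ds$trials$cue_location_deg[match(trial_ids, ds$trials$trial_id)]

  usable <- prefs$unit_id[prefs$pref_canonical_deg %in% trial_loc]
  dropped <- setdiff(prefs$unit_id, usable)
  if (length(dropped)) {
    warn(sprintf("%d neuron(s) with no trials at their preferred location excluded",
                 length(dropped)))
  }
  if (!length(usable)) abort("no neuron has trials at its preferred location")

  per_state <- function(keep_cell) {
    # keep_cell: function(trial_idx, bin) -> logical matrix trials x bins
    mats <- purrr::map(usable, function(u) {
      ui <- match(u, unit_ids)
      pref <- prefs$pref_canonical_deg[prefs$unit_id == u]
      tr <- which(trial_loc == pref)
      m <- matrix(unclass(br)[ui, tr, ], nrow = length(tr))
      keep <- keep_cell(tr)
      m[!keep] <- NA
      colMeans(m, na.rm = TRUE)
    })
    mat <- do.call(rbind, mats)
    tibble(time = times, rate = colMeans(mat, na.rm = TRUE),
           n_units = colSums(!is.na(mat)))
  }

  out <- per_state(function(tr) matrix(TRUE, length(tr), length(times)))
  out$state <- "all"

  if (!is.null(states)) {
    for (s in c("on", "off")) {
      iv <- states[states$state == s, ]
      keep_fun <- function(tr) {
        k <- matrix(FALSE, length(tr), length(times))
        for (r in seq_len(nrow(iv))) {
          ti <- match(iv$trial_id[r], trial_ids[tr])
          if (!is.na(ti)) {
            k[ti, times >= iv$start_s[r] & times < iv$end_s[r]] <- TRUE
          }
        }
        k
      }
      res <- per_state(keep_fun)
      res$state <- s
      res$rate[res$n_units == 0] <- NA
      out <- dplyr::bind_rows(out, res)
    }
  }
  out[, c("time", "state", "rate", "n_units")]
}

#' Test delay-period elevation of the population rate
#'
#' For each delay-period bin, a paired t-test across trials compares the
#' population rate (mean over units) in that bin against the trial's mean
#' fixation-period rate; p-values are Benjamini-Hochberg corrected across
#' the delay bins at level `q`.
#'
#' @param ds A [spike_dataset()].
#' @param cue_location Cue angle (degrees) whose trials are tested.
#' @param width Bin width in seconds (default 0.05).
#' @param q FDR level (default 0.05).
#'
#' @return Tibble: `time`, `statistic`, `p_value`, `p_adj`, `significant`.
#' @export
delay_elevation_test <- function(ds, cue_location, width = 0.05, q = 0.05) {
  stopifnot(inherits(ds, "spike_dataset"))
  tr_ids <- ds$trials$trial_id[ds$trials$cue_location_deg == cue_location]
  if (length(tr_ids) < 2) abort("need >= 2 trials at the cue location")
  sub <- filter_dataset(ds, trial_ids = tr_ids)

  delay <- epoch_interval("delay", ds$epochs)
  fix <- epoch_interval("fixation", ds$epochs)

  br <- bin_rates(sub, width = width, step = width, span = delay)
  pop <- apply(unclass(br), c(2, 3), mean)        # trials x delay bins
  fix_rate <- colMeans(epoch_mean_rates(sub, fix)) # per-trial fixation mean

  res <- purrr::map_dfr(seq_len(ncol(pop)), function(b) {
    d <- pop[, b] - fix_rate
    if (sd(d) < 1e-12) {
      return(tibble(time = attr(br, "times")[b],
                    statistic = NA_real_, p_value = 1))
    }
    tt <- t.test(pop[, b], fix_rate, paired = TRUE)
    tibble(time = attr(br, "times")[b],
           statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_adj < q
  res
}
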