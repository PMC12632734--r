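#' Bin spike counts into firing rates
#'
#' Counts spikes of every unit and trial in (possibly overlapping) time bins
#' and converts counts to rates in spikes/s. Bins are half-open
#' `[start, start + width)` laid on a grid `span[1] + (b-1) * step`; the
#' number of bins is `floor((span_length - width)/step) + 1`.
#'
#' @param ds A [spike_dataset()].
#' @param width Bin width in seconds (default 0.05).
#' @param step Bin step in seconds (default `width`, i.e. non-overlapping).
#' @param span Numeric length-2 interval in trial time, default the full
#'   trial.
#'
#' @return A `binned_rates` object: a 3-d array `unit x trial x bin` of
#'   rates with attributes `times` (bin centers), `starts`, `width`, `step`,
#'   `unit_id`, `trial_id`. Use [generics::tidy()] for a long tibble.
#' @export
bin_rates <- function(ds, width = 0.05, step = width, span = NULL) {
  stopifnot(inherits(ds, "spike_dataset"))
  span <- span %||% c(min(ds$epochs$start), max(ds$epochs$end))
  if (width <= 0 || step <= 0) abort("width and step must be positive")
  if (span[1] < min(ds$epochs$start) - 1e-9 ||
      span[2] > max(ds$epochs$end) + 1e-9) {
    abort("span lies outside the trial bounds")
  }
  if (nrow(ds$units) == 0 || nrow(ds$trials) == 0) abort("empty dataset")

  n_bins <- floor(((span[2] - span[1]) - width) / step + 1e-9) + 1L
  if (n_bins < 1) abort("span shorter than one bin")
  starts <- span[1] + (seq_len(n_bins) - 1L) * step

  unit_ids <- ds$units$unit_id
  trial_ids <- ds$trials$trial_id
  nu <- length(unit_ids)
  nt <- length(trial_ids)

  counts <- array(0L, dim = c(nu, nt, n_bins))
  if (nrow(ds$spikes)) {
    ui <- match(ds$spikes$unit_id, unit_ids)
    ti <- match(ds$spikes$trial_id, trial_ids)
    tm <- ds$spikes$time_s
    ord <- order(tm)
    tm <- tm[ord]; ui <- ui[ord]; ti <- ti[ord]
    cell <- (ti - 1L) * nu + ui
    for (b in seq_len(n_bins)) {
      lo <- findInterval(starts[b] - 1e-12, tm) + 1L
      hi <- findInterval(starts[b] + width - 1e-12, tm)
      if (hi >= lo) {
        tab <- tabulate(cell[lo:hi], nbins = nu * nt)
        counts[, , b] <- counts[, , b] + matrix(tab, nu, nt)
      }
    }
  }
  rates <- counts / width
  dimnames(rates) <- list(as.character(unit_ids), as.character(trial_ids),
                          NULL)
  structure(rates,
            times = starts + width / 2, starts = starts,
            width = width, step = step,
            unit_id = unit_ids, trial_id = trial_ids,
            class = c("binned_rates", "array"))
}

#' @export
tidy.binned_rates <- function(x, ...) {
  times <- attr(x, "times")
  expand_grid_fast <- expand.grid(
    unit_id = attr(x, "unit_id"),
    trial_id = attr(x, "trial_id"),
    time = times,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out <- as_tibble(expand_grid_fast)
  out$rate <- as.vector(unclass(x))
  out
}

#' @export
print.binned_rates <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<binned_rates> %d units x %d trials x %d bins (width %g s, step %g s)\n",
              d[1], d[2], d[3], attr(x, "width"), attr(x, "step")))
  invisible(x)
}

# Mean rate per unit x trial over an epoch interval [a, b): spikes / duration.
epoch_mean_rates <- function(ds, interval) {
  unit_ids <- ds$units$unit_id
  trial_ids <- ds$trials$trial_id
  dur <- interval[2] - interval[1]
  sp <- ds$spikes[ds$spikes$time_s >= interval[1] &
                    ds$spikes$time_s < interval[2], ]
  m <- matrix(0, length(unit_ids), length(trial_ids),
              dimnames = list(as.character(unit_ids), as.character(trial_ids)))
  if (nrow(sp)) {
    ui <- match(sp$unit_id, unit_ids)
    ti <- match(sp$trial_id, trial_ids)
    tab <- tabulate((ti - 1L) * length(unit_ids) + ui,
                    nbins = length(unit_ids) * length(trial_ids))
    m <- m + matrix(tab, length(unit_ids), length(trial_ids))
  }
  m / dur
}
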