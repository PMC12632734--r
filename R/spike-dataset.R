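#' Trial epoch specification for the oculomotor delayed-response task
#'
#' Returns the canonical epoch boundaries used throughout the package, in
#' seconds relative to cue onset, as half-open intervals `[start, end)`:
#' fixation `[-1, 0)`, cue `[0, 0.5)`, delay `[0.5, 3.5)`, response
#' `[3.5, 4.1)`.
#'
#' @return A tibble with columns `epoch`, `start`, `end`.
#' @export
#' @examples
#' odr_epochs()
odr_epochs <- function() {
  tibble(
    epoch = c("fixation", "cue", "delay", "response"),
    start = c(-1.0, 0.0, 0.5, 3.5),
    end   = c(0.0, 0.5, 3.5, 4.1)
  )
}

epoch_interval <- function(epoch, epochs = odr_epochs()) {
  row <- epochs[epochs$epoch == epoch, ]
  if (nrow(row) != 1) abort(paste0("unknown epoch: ", epoch))
  c(row$start, row$end)
}

#' Construct a trial-structured spike dataset
#'
#' Bundles a spike-event table, a trial table and a unit table into a
#' validated `spike_dataset`, the universal input of all analyses. Spike
#' times are seconds relative to cue onset. Cue locations are snapped to the
#' nearest of the 8 canonical angles (0, 45, ..., 315 degrees), which also
#' covers the 120-location task variant by grouping.
#'
#' @param spikes Data frame with columns `unit_id`, `trial_id`, `time_s`.
#' @param trials Data frame with columns `trial_id`, `cue_location_deg`,
#'   and optionally `correct` (logical) and `rt_ms` (numeric, NA allowed).
#' @param units Data frame with columns `unit_id`, and optionally `area`
#'   (`"PFC"` or `"PPC"`), `depth_mm` (>= 0) and `kind` (`"single"` or
#'   `"multi"`).
#' @param epochs Epoch table as returned by [odr_epochs()].
#' @param group_locations Snap cue locations to the canonical 8 angles
#'   (default `TRUE`).
#'
#' @return A `spike_dataset` object: a list of tibbles `spikes`, `trials`,
#'   `units` plus the `epochs` table.
#' @export
#' @examples
#' ds <- spike_dataset(
#'   spikes = data.frame(unit_id = 1, trial_id = 1, time_s = c(0.1, 0.7)),
#'   trials = data.frame(trial_id = 1, cue_location_deg = 90),
#'   units  = data.frame(unit_id = 1)
#' )
#' ds
spike_dataset <- function(spikes, trials, units, epochs = odr_epochs(),
                          group_locations = TRUE) {
  spikes <- as_tibble(spikes)
  trials <- as_tibble(trials)
  units <- as_tibble(units)

  need <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(paste0(name, " table is missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
  }
  need(spikes, c("unit_id", "trial_id", "time_s"), "spikes")
  need(trials, c("trial_id", "cue_location_deg"), "trials")
  need(units, "unit_id", "units")

  if (!"correct" %in% names(trials)) trials$correct <- TRUE
  if (!"rt_ms" %in% names(trials)) trials$rt_ms <- NA_real_
  # normalize column types (CSV round-trips degrade all-NA columns)
  spikes$time_s <- as.numeric(spikes$time_s)
  trials$cue_location_deg <- as.numeric(trials$cue_location_deg)
  trials$rt_ms <- as.numeric(trials$rt_ms)
  trials$correct <- as.logical(trials$correct)
  if (!"area" %in% names(units)) units$area <- "PFC"
  if (!"depth_mm" %in% names(units)) units$depth_mm <- 0
  if (!"kind" %in% names(units)) units$kind <- "single"

  if (group_locations) {
    trials$cue_location_deg <- snap_to_canonical(trials$cue_location_deg)
  }

  ds <- structure(
    list(spikes = spikes, trials = trials, units = units, epochs = epochs),
    class = "spike_dataset"
  )
  validate_spike_dataset(ds)
  ds
}

validate_spike_dataset <- function(ds) {
  sp <- ds$spikes
  if (nrow(ds$units) == 0) abort("dataset has no units")
  if (nrow(ds$trials) == 0) abort("dataset has no trials")
  orphan_u <- setdiff(unique(sp$unit_id), ds$units$unit_id)
  if (length(orphan_u)) {
    abort(paste0("spikes reference unknown unit_id: ",
                 paste(head(orphan_u, 5), collapse = ", ")))
  }
  orphan_t <- setdiff(unique(sp$trial_id), ds$trials$trial_id)
  if (length(orphan_t)) {
    abort(paste0("spikes reference unknown trial_id: ",
                 paste(head(orphan_t, 5), collapse = ", ")))
  }
  lo <- min(ds$epochs$start)
  hi <- max(ds$epochs$end)
  if (nrow(sp) && (min(sp$time_s) < lo || max(sp$time_s) > hi)) {
    abort(sprintf("spike times outside trial bounds [%g, %g]", lo, hi))
  }
  bad_loc <- setdiff(unique(ds$trials$cue_location_deg), canonical_angles())
  if (length(bad_loc)) {
    abort(paste0("non-canonical cue locations: ",
                 paste(bad_loc, collapse = ", "),
                 " (use group_locations = TRUE)"))
  }
  if (any(ds$units$depth_mm < 0)) abort("negative unit depth_mm")
  invisible(ds)
}

#' @export
print.spike_dataset <- function(x, ...) {
  nt <- nrow(x$trials)
  cat(sprintf(
    "<spike_dataset> %d units (%s), %d trials, %d spikes\n",
    nrow(x$units),
    paste(sprintf("%s: %d", names(table(x$units$area)),
                  as.integer(table(x$units$area))), collapse = ", "),
    nt, nrow(x$spikes)
  ))
  cat(sprintf("  cue locations: %s\n",
              paste(sort(unique(x$trials$cue_location_deg)), collapse = " ")))
  invisible(x)
}

# Subset a dataset to given trials and/or units, preserving metadata.
filter_dataset <- function(ds, trial_ids = NULL, unit_ids = NULL) {
  trials <- ds$trials
  units <- ds$units
  if (!is.null(trial_ids)) trials <- trials[trials$trial_id %in% trial_ids, ]
  if (!is.null(unit_ids)) units <- units[units$unit_id %in% unit_ids, ]
  spikes <- ds$spikes[ds$spikes$trial_id %in% trials$trial_id &
                        ds$spikes$unit_id %in% units$unit_id, ]
  structure(list(spikes = spikes, trials = trials, units = units,
                 epochs = ds$epochs), class = "spike_dataset")
}
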