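#' Classify units as spatially selective in a task epoch
#'
#' A unit is selective when a one-way ANOVA of its per-trial epoch-mean
#' firing rate across cue locations is significant at `alpha`, and its mean
#' rate at the best location is at least `min_rate` spikes/s. The rate gate
#' guards against false positives among near-silent units.
#'
#' @param ds A [spike_dataset()].
#' @param epoch Epoch name (default `"delay"`) or a numeric `[start, end)`
#'   interval in seconds.
#' @param alpha ANOVA significance level (default 0.05).
#' @param min_rate Minimum best-location mean rate in spikes/s (default 2).
#' @param kinds Unit kinds to include (default both single and multi).
#'
#' @return A tibble with one row per unit: `unit_id`, `p_value`,
#'   `best_rate`, `best_location_deg`, `selective`.
#' @export
classify_selectivity <- function(ds, epoch = "delay", alpha = 0.05,
                                 min_rate = 2, kinds = c("single", "multi")) {
  stopifnot(inherits(ds, "spike_dataset"))
  interval <- if (is.character(epoch)) epoch_interval(epoch, ds$epochs) else epoch
  units <- ds$units[ds$units$kind %in% kinds, ]
  ds_k <- filter_dataset(ds, unit_ids = units$unit_id)

  loc <- ds_k$trials$cue_location_deg
  tab <- table(loc)
  thin <- names(tab)[tab < 2]
  if (length(thin)) {
    abort(paste0("need >= 2 trials per cue location; too few at: ",
                 paste(thin, collapse = ", "), " deg"))
  }
  rates <- epoch_mean_rates(ds_k, interval)
  f <- factor(loc)

  res <- purrr::map_dfr(seq_len(nrow(rates)), function(i) {
    y <- rates[i, ]
    p <- if (sd(y) == 0) 1 else anova(lm(y ~ f))$`Pr(>F)`[1]
    mean_by_loc <- tapply(y, f, mean)
    best <- which.max(mean_by_loc)
    tibble(
      unit_id = units$unit_id[i],
      p_value = p,
      best_rate = unname(mean_by_loc[best]),
      best_location_deg = as.numeric(names(mean_by_loc)[best])
    )
  })
  res$selective <- res$p_value < alpha & res$best_rate >= min_rate
  res
}

#' Preferred location as spike-count-weighted circular mean
#'
#' The preferred angle is the argument of the complex resultant
#' `sum(n_j * exp(i * theta_j)) / sum(n_j)` over the 8 cue locations, where
#' `n_j` is the mean delay-period spike count at location `theta_j`; its
#' modulus `T` in `[0, 1]` measures tuning concentration. Equal counts at
#' all locations give `T = 0` and an undefined angle.
#'
#' @param counts Non-negative numeric vector of mean spike counts per
#'   location.
#' @param angles_deg Cue angles in degrees, same length as `counts`
#'   (default the 8 canonical angles).
#'
#' @return A tibble with `theta_pref_deg` (NA when undefined), `modulus`,
#'   and `defined`.
#' @export
#' @examples
#' preferred_location(c(0, 0, 1, 0, 0, 0, 0, 0))  # all mass at 90 deg
preferred_location <- function(counts, angles_deg = canonical_angles()) {
  if (length(counts) != length(angles_deg)) {
    abort("counts and angles_deg must have the same length")
  }
  if (any(counts < 0)) abort("spike counts must be non-negative")
  if (all(counts == 0)) abort("no spikes; preferred location undefined")
  z <- sum(counts * exp(1i * angles_deg * pi / 180)) / sum(counts)
  modulus <- Mod(z)
  defined <- modulus > 1e-12
  theta <- if (defined) (Arg(z) * 180 / pi) %% 360 else NA_real_
  tibble(theta_pref_deg = theta, modulus = modulus, defined = defined)
}

#' Per-unit preferred locations for a dataset
#'
#' Applies [preferred_location()] to every unit's mean delay-period spike
#' counts by cue location. Units with no delay spikes, or perfectly
#' symmetric counts (modulus 0), are returned with `defined = FALSE` and
#' are excluded from preferred-location-conditioned analyses downstream.
#'
#' @inheritParams classify_selectivity
#' @return Tibble: `unit_id`, `theta_pref_deg`, `modulus`, `defined`,
#'   `pref_canonical_deg` (nearest canonical angle, NA when undefined).
#' @export
unit_preferred_locations <- function(ds, epoch = "delay") {
  interval <- if (is.character(epoch)) epoch_interval(epoch, ds$epochs) else epoch
  dur <- interval[2] - interval[1]
  counts <- epoch_mean_rates(ds, interval) * dur
  f <- factor(ds$trials$cue_location_deg, levels = canonical_angles())
  present <- levels(f)[table(f) > 0]
  out <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    n_j <- tapply(counts[i, ], f, mean)[present]
    ang <- as.numeric(present)
    if (all(n_j == 0)) {
      return(tibble(unit_id = ds$units$unit_id[i], theta_pref_deg = NA_real_,
                    modulus = 0, defined = FALSE))
    }
    pl <- preferred_location(n_j, ang)
    pl$unit_id <- ds$units$unit_id[i]
    pl[, c("unit_id", "theta_pref_deg", "modulus", "defined")]
  })
  n_undef <- sum(!out$defined)
  if (n_undef > 0) {
    inform(sprintf("%d unit(s) with undefined preferred location excluded from conditioned analyses", n_undef))
  }
  out$pref_canonical_deg <- ifelse(out$defined,
                                   snap_to_canonical(out$theta_pref_deg),
                                   NA_real_)
  out
}

#' Laminar depth class of a recording contact
#'
#' Depths are measured from the shallowest spiking contact (0 mm):
#' `[0, 0.8)` mm is superficial, `[0.8, 1.2)` middle, `[1.2, Inf)` deep.
#'
#' @param depth_mm Non-negative depth(s) in millimetres.
#' @return Factor with levels superficial, middle, deep.
#' @export
#' @examples
#' laminar_class(c(0, 0.79, 0.8, 1.2, 1.9))
laminar_class <- function(depth_mm) {
  if (any(depth_mm < 0, na.rm = TRUE)) abort("depth_mm must be non-negative")
  cut(depth_mm, breaks = c(0, 0.8, 1.2, Inf),
      labels = c("superficial", "middle", "deep"),
      right = FALSE, include.lowest = TRUE)
}

#' Proportion of selective units per laminar depth class
#'
#' @param ds A [spike_dataset()] whose `units` table has `depth_mm`.
#' @inheritParams classify_selectivity
#' @return Tibble: `laminar`, `n_units`, `n_selective`, `proportion`.
#' @export
laminar_selectivity <- function(ds, epoch = "delay", alpha = 0.05,
                                min_rate = 2) {
  sel <- classify_selectivity(ds, epoch = epoch, alpha = alpha,
                              min_rate = min_rate)
  df <- dplyr::left_join(sel, ds$units[, c("unit_id", "depth_mm")],
                         by = "unit_id")
  df$laminar <- laminar_class(df$depth_mm)
  df |>
    dplyr::group_by(.data$laminar) |>
    dplyr::summarise(n_units = dplyr::n(),
                     n_selective = sum(.data$selective),
                     proportion = mean(.data$selective),
                     .groups = "drop")
}
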