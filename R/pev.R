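#' Bias-corrected percentage of explained variance (omega squared)
#'
#' One-way ANOVA effect size measuring the percentage of firing-rate
#' variance attributable to the cue location:
#' `omega^2 = (SS_between - df * MSE) / (SS_total + MSE) * 100`, with
#' `df = k - 1` groups degrees of freedom. The bias correction makes the
#' statistic centered on 0 under the null, so negative values occur and are
#' deliberately retained.
#'
#' @param values Numeric observations (e.g. per-trial rates in one bin).
#' @param groups Group labels, same length as `values` (e.g. cue location).
#' @return Scalar omega-squared in percent, with attribute `components`
#'   (SS_between, SS_total, MSE, df) and attribute `degenerate` set when
#'   all observations are identical (returns 0).
#' @export
#' @examples
#' omega_squared(c(1, 1, 5, 5), c("a", "a", "b", "b"))  # MSE = 0 -> 100
omega_squared <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2) abort("omega_squared needs >= 2 groups")
  if (any(table(groups) < 2)) {
    abort("omega_squared needs >= 2 observations per group")
  }
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  sizes <- tapply(values, groups, length)
  ss_between <- sum(sizes * (means[levels(groups)] - gm)^2, na.rm = TRUE)
  ss_total <- sum((values - gm)^2)
  ss_within <- ss_total - ss_between
  df <- k - 1
  mse <- ss_within / (n - k)
  if (ss_total + mse < 1e-15) {
    return(structure(0, degenerate = TRUE,
                     components = c(ss_between = 0, ss_total = 0,
                                    mse = 0, df = df)))
  }
  structure((ss_between - df * mse) / (ss_total + mse) * 100,
            components = c(ss_between = ss_between, ss_total = ss_total,
                           mse = mse, df = df))
}

#' Balance trial counts across cue locations
#'
#' Downsamples every location's trials, without replacement, to the lowest
#' common trial count, so the ANOVA decomposition is not biased by unequal
#' group sizes. The draw is seeded and made once per analysis run: the same
#' balanced subset enters every time bin.
#'
#' @param trials Trial table with `trial_id` and `cue_location_deg`.
#' @param seed Integer seed.
#' @return The balanced subset of `trials`.
#' @export
stratify_trials <- function(trials, seed = 1) {
  tab <- table(trials$cue_location_deg)
  if (length(tab) == 0 || any(tab == 0)) abort("a cue location has 0 trials")
  m <- min(tab)
  with_seed(seed, {
    trials |>
      dplyr::group_by(.data$cue_location_deg) |>
      dplyr::slice_sample(n = m) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$trial_id)
  })
}

#' Omega-squared information time course
#'
#' Computes [omega_squared()] for every unit in sliding bins (100 ms wide,
#' 50 ms steps by default) over stratified (trial-balanced) trials.
#'
#' @param ds A [spike_dataset()].
#' @param width,step Bin width and step in seconds.
#' @param span Analysis interval (default the full trial).
#' @param seed Seed for the one-off trial stratification.
#' @return A `pev_result` tibble: `unit_id`, `time`, `omega2` (percent),
#'   with the stratified trial ids in attribute `trials_used`.
#' @export
pev_timecourse <- function(ds, width = 0.1, step = 0.05, span = NULL,
                           seed = 1) {
  stopifnot(inherits(ds, "spike_dataset"))
  strat <- stratify_trials(ds$trials, seed = seed)
  sub <- filter_dataset(ds, trial_ids = strat$trial_id)
  br <- bin_rates(sub, width = width, step = step, span = span)
  times <- attr(br, "times")
  f <- factor(sub$trials$cue_location_deg)
  unit_ids <- attr(br, "unit_id")
  arr <- unclass(br)

  out <- purrr::map_dfr(seq_along(unit_ids), function(i) {
    tibble(unit_id = unit_ids[i], time = times,
           omega2 = vapply(seq_along(times), function(b) {
             as.numeric(omega_squared(arr[i, , b], f))
           }, numeric(1)))
  })
  attr(out, "trials_used") <- strat$trial_id
  class(out) <- c("pev_result", class(out))
  out
}

#' Session summary of an omega-squared time course
#'
#' Mean and s.e.m. across units per time bin, plus the delay-period
#' one-sample t-test of per-unit delay-mean omega-squared against 0.
#'
#' @param pev A [pev_timecourse()] result.
#' @param units Optional unit ids to restrict to (e.g. delay-selective).
#' @param delay Delay interval (default `[0.5, 3.5)`).
#' @return List: `timecourse` tibble (`time`, `mean`, `sem`, `n`), `delay_test`
#'   (tibble `estimate`, `statistic`, `p_value`).
#' @export
pev_session_summary <- function(pev, units = NULL, delay = c(0.5, 3.5)) {
  df <- if (is.null(units)) pev else pev[pev$unit_id %in% units, ]
  tc <- df |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(mean = mean(.data$omega2),
                     sem = sd(.data$omega2) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  dm <- df[df$time >= delay[1] & df$time < delay[2], ] |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(m = mean(.data$omega2), .groups = "drop")
  tt <- t.test(dm$m)
  list(timecourse = tc,
       delay_test = tibble(estimate = unname(tt$estimate),
                           statistic = unname(tt$statistic),
                           p_value = tt$p.value))
}

#' @export
autoplot.pev_result <- function(object, ...) {
  tc <- object |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(mean = mean(.data$omega2),
                     sem = sd(.data$omega2) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, 0.5, 3.5), linetype = "dotted") +
    ggplot2::labs(x = "time from cue onset (s)",
                  y = expression(omega^2 ~ "(% explained variance)"))
}
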