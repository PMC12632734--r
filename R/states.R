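#' Label-shuffled null of the decoder confidence
#'
#' Repeats the binary diametric leave-one-out classification `n_shuffles`
#' times, each time permuting the *training* labels, giving each trial a
#' per-bin null distribution of confidence values. The true confidence is
#' computed on the same bin grid.
#'
#' @param ds A [spike_dataset()] (one area; filter first for area-specific
#'   labeling).
#' @param pair Diametric cue-location pair (see
#'   [binary_diametric_decode()]).
#' @param cfg A [decoder_config()].
#' @param span Analysis interval; default the delay period.
#' @param n_shuffles Number of label shuffles (default 50).
#' @param seed Integer seed.
#'
#' @return A `confidence_null` object: list with `trial_id`, `times`,
#'   `posterior` (trial x bin), `null_mean`, `null_sd` (trial x bin),
#'   `shuffles` (trial x bin x shuffle), `bin_step`, `bin_width`.
#' @export
confidence_null <- function(ds, pair = NULL, cfg = decoder_config(),
                            span = c(0.5, 3.5), n_shuffles = 50, seed = 1) {
  stopifnot(inherits(ds, "spike_dataset"))
  if (n_shuffles < 2) abort("n_shuffles must be >= 2")
  locs <- sort(unique(ds$trials$cue_location_deg))
  pair <- pair %||% {
    if (length(locs) != 2) abort("specify `pair`: dataset has != 2 cue locations")
    locs
  }
  sub <- filter_dataset(
    ds, trial_ids = ds$trials$trial_id[ds$trials$cue_location_deg %in% pair])
  if (any(table(sub$trials$cue_location_deg) < 2)) {
    abort("both locations need >= 2 trials")
  }
  br <- bin_rates(sub, width = cfg$width, step = cfg$step, span = span)
  z <- if (cfg$zscore == "full") zscore_rates(br) else br
  zarr <- unclass(z)
  trial_ids <- attr(br, "trial_id")
  y <- as.integer(sub$trials$cue_location_deg[match(trial_ids,
                                                    sub$trials$trial_id)] == pair[1])
  xs <- lapply(seq_len(dim(zarr)[3]), function(b) bin_features(zarr, b))

  post <- binary_conf_matrix(xs, y, cfg$lambda)
  shuf <- with_seed(seed, {
    arr <- array(NA_real_, c(length(y), length(xs), n_shuffles))
    for (s in seq_len(n_shuffles)) {
      perm <- sample.int(length(y))
      arr[, , s] <- binary_conf_matrix(xs, y, cfg$lambda, label_perm = perm)
    }
    arr
  })
  structure(list(trial_id = trial_ids, times = attr(br, "times"),
                 posterior = post,
                 null_mean = apply(shuf, c(1, 2), mean),
                 null_sd = apply(shuf, c(1, 2), sd),
                 shuffles = shuf,
                 bin_width = cfg$width, bin_step = cfg$step, pair = pair),
            class = "confidence_null")
}

#' @export
print.confidence_null <- function(x, ...) {
  cat(sprintf("<confidence_null> %d trials x %d bins, %d label shuffles (pair %s deg)\n",
              nrow(x$posterior), ncol(x$posterior), dim(x$shuffles)[3],
              paste(x$pair, collapse = "/")))
  invisible(x)
}

# cluster masses of supra-threshold runs of a z trace
cluster_masses <- function(z, threshold) {
  runs <- true_runs(z > threshold)
  if (!nrow(runs)) return(runs |> dplyr::mutate(mass = numeric(0)))
  runs$mass <- vapply(seq_len(nrow(runs)),
                      function(r) sum(z[runs$start[r]:runs$end[r]]),
                      numeric(1))
  runs
}

#' Label on and off states from decoder confidence
#'
#' Z-scores each trial's confidence trace by its label-shuffle null and
#' labels: *on states* as maximal runs of `z > z_on` whose cluster mass
#' (sum of z over the run) exceeds the 95th percentile of the null
#' max-cluster-mass distribution (the same clustering applied to each
#' shuffled trace of that trial — the max-statistic correction controlling
#' family-wise error over time); *off states* as maximal runs of
#' `z < z_off` lasting at least `off_len` consecutive bins.
#'
#' @param cn A [confidence_null()] result.
#' @param z_on On-state z threshold (default 1.64).
#' @param z_off Off-state z threshold (default 0.3).
#' @param off_len Minimum off run length in bins (default 3).
#' @param cluster_q Null cluster-mass quantile (default 0.95).
#'
#' @return A `state_labels` tibble: `trial_id`, `state`, `start_bin`,
#'   `end_bin`, `start_s`, `end_s`, `mass` (on states only). Attribute `z`
#'   holds the trial x bin z matrix; attribute `criterion` the per-trial
#'   null cluster-mass criterion.
#' @export
label_states <- function(cn, z_on = 1.64, z_off = 0.3, off_len = 3,
                         cluster_q = 0.95) {
  stopifnot(inherits(cn, "confidence_null"))
  sdm <- cn$null_sd
  pooled <- sd(as.vector(cn$shuffles))
  if (any(sdm == 0)) {
    warn("zero null s.d. at some bins; pooled s.d. substituted")
    sdm[sdm == 0] <- pooled
  }
  zmat <- (cn$posterior - cn$null_mean) / sdm
  n_shuf <- dim(cn$shuffles)[3]
  step <- cn$bin_step

  out <- list()
  criterion <- numeric(nrow(zmat))
  for (t in seq_len(nrow(zmat))) {
    z <- zmat[t, ]
    # null max-cluster-mass distribution from this trial's shuffled traces
    null_max <- vapply(seq_len(n_shuf), function(s) {
      zs <- (cn$shuffles[t, , s] - cn$null_mean[t, ]) / sdm[t, ]
      cm <- cluster_masses(zs, z_on)
      if (nrow(cm)) max(cm$mass) else 0
    }, numeric(1))
    crit <- quantile(null_max, cluster_q, names = FALSE)
    criterion[t] <- crit

    on_runs <- cluster_masses(z, z_on)
    on_runs <- on_runs[on_runs$mass > crit, , drop = FALSE]
    if (nrow(on_runs)) {
      out[[length(out) + 1]] <- tibble(
        trial_id = cn$trial_id[t], state = "on",
        start_bin = on_runs$start, end_bin = on_runs$end,
        mass = on_runs$mass)
    }
    off_runs <- true_runs(z < z_off)
    off_runs <- off_runs[off_runs$end - off_runs$start + 1L >= off_len, ,
                         drop = FALSE]
    if (nrow(off_runs)) {
      out[[length(out) + 1]] <- tibble(
        trial_id = cn$trial_id[t], state = "off",
        start_bin = off_runs$start, end_bin = off_runs$end,
        mass = NA_real_)
    }
  }
  labels <- if (length(out)) dplyr::bind_rows(out) else {
    tibble(trial_id = integer(), state = character(),
           start_bin = integer(), end_bin = integer(), mass = numeric())
  }
  if (nrow(labels)) {
    labels$start_s <- cn$times[labels$start_bin] - step / 2
    labels$end_s <- cn$times[labels$end_bin] + step / 2
  } else {
    labels$start_s <- numeric()
    labels$end_s <- numeric()
  }
  labels <- labels[, c("trial_id", "state", "start_bin", "end_bin",
                       "start_s", "end_s", "mass")]
  class(labels) <- c("state_labels", class(labels))
  attr(labels, "z") <- zmat
  attr(labels, "times") <- cn$times
  attr(labels, "criterion") <- criterion
  attr(labels, "trial_ids") <- cn$trial_id
  labels
}

#' Fraction of delay time labeled on or off
#'
#' @param labels A [label_states()] result.
#' @param state `"on"` or `"off"`.
#' @return Fraction of (trial x bin) cells carrying the state label.
#' @export
state_time_fraction <- function(labels, state = "on") {
  zmat <- attr(labels, "z")
  n_cells <- length(zmat)
  sel <- labels[labels$state == state, ]
  covered <- sum(sel$end_bin - sel$start_bin + 1L)
  covered / n_cells
}

#' @export
autoplot.state_labels <- function(object, trial = NULL, ...) {
  zmat <- attr(object, "z")
  times <- attr(object, "times")
  ids <- attr(object, "trial_ids")
  trial <- trial %||% ids[1]
  zt <- tibble(time = times, z = zmat[match(trial, ids), ])
  iv <- object[object$trial_id == trial, ]
  p <- ggplot2::ggplot(zt, ggplot2::aes(x = .data$time, y = .data$z)) +
    ggplot2::geom_hline(yintercept = c(1.64, 0.3), linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from cue onset (s)", y = "confidence z-score")
  if (nrow(iv)) {
    p <- p + ggplot2::geom_rect(
      data = iv,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$state),
      alpha = 0.2, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(values = c(on = "red", off = "blue"))
  }
  p
}
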