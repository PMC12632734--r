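# State-conditioned tuning curves, cross-areal transfer, outcome analysis.

# per-unit spike rate inside a set of intervals of one trial
interval_rate <- function(times, intervals) {
  if (!nrow(intervals)) return(NA_real_)
  dur <- sum(intervals$end_s - intervals$start_s)
  if (dur <= 0) return(NA_real_)
  n <- 0L
  for (r in seq_len(nrow(intervals))) {
    n <- n + sum(times >= intervals$start_s[r] & times < intervals$end_s[r])
  }
  n / dur
}

#' Shuffle-debiased on/off state tuning curves
#'
#' For every unit, mean z-scored firing rate during on- and off-labeled
#' time is computed per cue location; the unit's preferred location is the
#' one maximizing the sum of the on and off vectors, and both vectors are
#' circularly aligned to it. Because alignment to the empirical peak
#' biases the curve, the same procedure is repeated on `n_shuffles`
#' trial-permuted label assignments and the mean shuffled aligned curve is
#' subtracted, yielding unbiased tuning functions. Tuning depth is the
#' aligned peak (offset 0) minus the curve minimum.
#'
#' @param ds A [spike_dataset()] (restrict units/trials beforehand as
#'   needed).
#' @param labels A [label_states()] result (or any tibble with `trial_id`,
#'   `state`, `start_s`, `end_s`).
#' @param n_shuffles Label shuffles for debiasing (default 1000).
#' @param delay Interval whose mean rate/sd z-scores each unit (default
#'   delay period).
#' @param seed Integer seed.
#'
#' @return A `state_tuning` object: list with `curves` (tibble `unit_id`,
#'   `state`, `offset_deg`, `value`), `depth` (tibble `unit_id`,
#'   `depth_on`, `depth_off`), `n_excluded` (units with no labeled time in
#'   one state), `reduction_pct` (percent reduction of mean off vs on
#'   depth).
#' @export
state_tuning <- function(ds, labels, n_shuffles = 1000,
                         delay = c(0.5, 3.5), seed = 1) {
  stopifnot(inherits(ds, "spike_dataset"))
  trials <- ds$trials
  n_t <- nrow(trials)
  locs <- sort(unique(trials$cue_location_deg))
  loc_of <- trials$cue_location_deg
  unit_ids <- ds$units$unit_id

  iv_by_trial <- function(state) {
    lapply(trials$trial_id, function(tid) {
      labels[labels$trial_id == tid & labels$state == state, , drop = FALSE]
    })
  }
  iv_on <- iv_by_trial("on")
  iv_off <- iv_by_trial("off")
  spikes_by_ut <- split(ds$spikes$time_s,
                        list(factor(ds$spikes$unit_id, levels = unit_ids),
                             factor(ds$spikes$trial_id, levels = trials$trial_id)))
  get_times <- function(u, t) {
    spikes_by_ut[[paste(unit_ids[u], trials$trial_id[t], sep = ".")]] %||% numeric()
  }

  # R_state[t, t2]: rate of trial t's spikes within trial t2's state intervals
  rate_mats <- function(u, ivs) {
    m <- matrix(NA_real_, n_t, n_t)
    for (t2 in seq_len(n_t)) {
      iv <- ivs[[t2]]
      if (!nrow(iv)) next
      for (t in seq_len(n_t)) m[t, t2] <- interval_rate(get_times(u, t), iv)
    }
    m
  }

  perms <- with_seed(seed, {
    lapply(seq_len(n_shuffles), function(s) sample.int(n_t))
  })
  offsets <- angle_diff(locs, 0)  # relative offsets once aligned
  k <- length(locs)

  curve_of <- function(vec_on, vec_off) {
    tot <- vec_on + vec_off
    if (all(is.na(tot))) return(NULL)
    pref <- which.max(tot)
    idx <- ((seq_len(k) - 1 + (pref - 1)) %% k) + 1  # rotate pref to slot 1
    list(on = vec_on[idx], off = vec_off[idx])
  }

  curves <- list()
  depths <- list()
  n_excluded <- 0L
  for (u in seq_along(unit_ids)) {
    r_on <- rate_mats(u, iv_on)
    r_off <- rate_mats(u, iv_off)
    delay_rate <- vapply(seq_len(n_t), function(t) {
      sum(get_times(u, t) >= delay[1] & get_times(u, t) < delay[2]) /
        (delay[2] - delay[1])
    }, numeric(1))
    m_u <- mean(delay_rate); s_u <- sd(delay_rate)
    if (s_u == 0) s_u <- 1
    z_on <- (r_on - m_u) / s_u
    z_off <- (r_off - m_u) / s_u

    vec <- function(zm, assign) {
      v <- vapply(locs, function(l) {
        sel <- loc_of == l
        mean(zm[cbind(which(sel), assign[sel])], na.rm = TRUE)
      }, numeric(1))
      v[is.nan(v)] <- NA
      v
    }
    ident <- seq_len(n_t)
    true_c <- curve_of(vec(z_on, ident), vec(z_off, ident))
    if (is.null(true_c) || all(is.na(true_c$off)) || all(is.na(true_c$on))) {
      n_excluded <- n_excluded + 1L
      next
    }
    acc_on <- rep(0, k); acc_off <- rep(0, k); n_ok <- 0L
    for (p in perms) {
      sc <- curve_of(vec(z_on, p), vec(z_off, p))
      if (is.null(sc)) next
      acc_on <- acc_on + ifelse(is.na(sc$on), 0, sc$on)
      acc_off <- acc_off + ifelse(is.na(sc$off), 0, sc$off)
      n_ok <- n_ok + 1L
    }
    deb_on <- true_c$on - acc_on / n_ok
    deb_off <- true_c$off - acc_off / n_ok
    curves[[length(curves) + 1]] <- tibble(
      unit_id = unit_ids[u],
      state = rep(c("on", "off"), each = k),
      offset_deg = rep(offsets, 2),
      value = c(deb_on, deb_off))
    depths[[length(depths) + 1]] <- tibble(
      unit_id = unit_ids[u],
      depth_on = deb_on[1] - min(deb_on, na.rm = TRUE),
      depth_off = deb_off[1] - min(deb_off, na.rm = TRUE))
  }
  if (!length(depths)) abort("no unit has labeled time in both states")
  depth <- dplyr::bind_rows(depths)
  mean_on <- mean(depth$depth_on); mean_off <- mean(depth$depth_off)
  structure(list(curves = dplyr::bind_rows(curves), depth = depth,
                 n_excluded = n_excluded,
                 reduction_pct = (1 - mean_off / mean_on) * 100),
            class = "state_tuning")
}

#' @export
print.state_tuning <- function(x, ...) {
  cat(sprintf("<state_tuning> %d units (%d excluded); mean depth on %.3f, off %.3f; reduction %.1f%%\n",
              nrow(x$depth), x$n_excluded, mean(x$depth$depth_on),
              mean(x$depth$depth_off), x$reduction_pct))
  invisible(x)
}

#' @export
autoplot.state_tuning <- function(object, ...) {
  df <- object$curves |>
    dplyr::group_by(.data$state, .data$offset_deg) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset_deg, y = .data$value,
                                   color = .data$state)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(on = "red", off = "blue")) +
    ggplot2::labs(x = "offset from preferred location (deg)",
                  y = "debiased z-scored rate")
}

#' Cross-areal transfer of state labels
#'
#' States identified in a source area are applied to the simultaneously
#' recorded target area: the target's tuning and firing rates are computed
#' within source-defined intervals. The depth contrast compares each
#' target unit's tuning depth during source-defined *off* time against its
#' all-delay tuning depth. Both curves are aligned to the unit's preferred
#' location estimated from the *cue period* (spike-count-weighted circular
#' mean) — data disjoint from the delay-period rates entering the curves —
#' and depth is the signed aligned peak minus the mean over the other
#' locations, so the alignment introduces no peak-picking bias in either
#' condition. This replaces the label-shuffle debiasing of
#' [state_tuning()], unusable here because cluster-corrected on states are
#' deliberately conservative and often cover too little time to serve as
#' the reference. The per-unit depth difference (all minus off) is tested
#' with a one-sample t-test (one-sided, reduction > 0). Firing-rate comparisons across target units
#' (on vs. off and on vs. all-trial mean, paired t-tests) are reported
#' when on-labeled time exists.
#'
#' @param ds A [spike_dataset()] containing both areas with a shared trial
#'   clock (simultaneous recording).
#' @param labels State labels derived from the source area's decoder
#'   confidence ([label_states()] output).
#' @param source_area,target_area Area names present in `ds$units$area`.
#' @param min_source_neurons Gate on the source population size (default
#'   80, the inclusion rule for cross-areal analyses).
#' @return List: `curves` tibble (`unit_id`, `condition` in
#'   `{"all", "off"}`, `offset_deg`, `value` in across-trial z-units),
#'   `depth` tibble per unit, `depth_test` tibble (`estimate` = mean
#'   depth_all - depth_off, `statistic`, `p_value`, `n_units`),
#'   `reduction_pct` (off vs. all, from mean depths), `rate_tests` tibble,
#'   `mean_rates` tibble per target unit.
#' @export
cross_areal_transfer <- function(ds, labels, source_area, target_area,
                                 min_source_neurons = 80) {
  stopifnot(inherits(ds, "spike_dataset"))
  areas <- unique(ds$units$area)
  if (!all(c(source_area, target_area) %in% areas)) {
    abort("both areas must be present in the dataset (simultaneous recording)")
  }
  n_src <- sum(ds$units$area == source_area)
  if (n_src < min_source_neurons) {
    abort(sprintf("source area %s has %d neurons (< %d required)",
                  source_area, n_src, min_source_neurons))
  }
  tgt <- filter_dataset(ds,
                        unit_ids = ds$units$unit_id[ds$units$area == target_area])

  delay <- epoch_interval("delay", ds$epochs)
  # preference from the cue period: disjoint from the delay data entering
  # the curves, so the alignment introduces no peak-picking bias in either
  # condition (tuning is present during the cue by task design)
  pl <- suppressMessages(unit_preferred_locations(tgt, epoch = "cue"))
  locs <- sort(unique(tgt$trials$cue_location_deg))
  k <- length(locs)
  loc_of <- tgt$trials$cue_location_deg
  off_iv <- labels[labels$state == "off", , drop = FALSE]
  off_by_trial <- split(off_iv, off_iv$trial_id)

  curves <- list(); depths <- list()
  for (ui in seq_len(nrow(tgt$units))) {
    u <- tgt$units$unit_id[ui]
    if (!pl$defined[pl$unit_id == u]) next
    tm <- tgt$spikes[tgt$spikes$unit_id == u, ]
    tms_by_trial <- split(tm$time_s, factor(tm$trial_id,
                                            levels = tgt$trials$trial_id))
    all_rate <- vapply(tms_by_trial, function(x) {
      sum(x >= delay[1] & x < delay[2]) / (delay[2] - delay[1])
    }, numeric(1))
    off_rate <- vapply(seq_along(tms_by_trial), function(t) {
      iv <- off_by_trial[[as.character(tgt$trials$trial_id[t])]]
      if (is.null(iv) || !nrow(iv)) return(NA_real_)
      interval_rate(tms_by_trial[[t]], iv)
    }, numeric(1))
    m_u <- mean(all_rate); s_u <- sd(all_rate)
    if (s_u == 0) s_u <- 1
    z_all <- (all_rate - m_u) / s_u
    z_off <- (off_rate - m_u) / s_u
    vec <- function(z) {
      v <- vapply(locs, function(l) mean(z[loc_of == l], na.rm = TRUE),
                  numeric(1))
      v[is.nan(v)] <- NA
      v
    }
    v_all <- vec(z_all); v_off <- vec(z_off)
    # align to the unit's circular-mean preferred location
    pref_deg <- pl$theta_pref_deg[pl$unit_id == u]
    d_to <- abs(angle_diff(locs, pref_deg))
    pref_slot <- which.min(d_to)
    idx <- ((seq_len(k) - 1 + (pref_slot - 1)) %% k) + 1
    a_all <- v_all[idx]; a_off <- v_off[idx]
    offsets <- angle_diff(locs, locs[1])
    curves[[length(curves) + 1]] <- tibble(
      unit_id = u, condition = rep(c("all", "off"), each = k),
      offset_deg = rep(offsets, 2), value = c(a_all, a_off))
    # signed depth: aligned peak minus the mean of the other locations —
    # unbiased given the independent alignment (no truncation at zero)
    depths[[length(depths) + 1]] <- tibble(
      unit_id = u,
      depth_all = a_all[1] - mean(a_all[-1], na.rm = TRUE),
      depth_off = if (is.na(a_off[1]) || all(is.na(a_off[-1]))) NA_real_ else
        a_off[1] - mean(a_off[-1], na.rm = TRUE))
  }
  if (!length(depths)) abort("no target unit with a defined preferred location")
  depth <- dplyr::bind_rows(depths)
  dd <- depth$depth_all - depth$depth_off
  dd <- dd[is.finite(dd)]
  if (length(dd) < 3) abort("too few target units with off-labeled time")
  tt3 <- t.test(dd, alternative = "greater")

  delay <- epoch_interval("delay", ds$epochs)
  unit_ids <- tgt$units$unit_id
  rates <- purrr::map_dfr(unit_ids, function(u) {
    tm_all <- tgt$spikes[tgt$spikes$unit_id == u, ]
    per_state <- vapply(c("on", "off"), function(s) {
      iv <- labels[labels$state == s, ]
      num <- 0; den <- 0
      for (r in seq_len(nrow(iv))) {
        tms <- tm_all$time_s[tm_all$trial_id == iv$trial_id[r]]
        num <- num + sum(tms >= iv$start_s[r] & tms < iv$end_s[r])
        den <- den + (iv$end_s[r] - iv$start_s[r])
      }
      if (den > 0) num / den else NA_real_
    }, numeric(1))
    all_rate <- sum(tm_all$time_s >= delay[1] & tm_all$time_s < delay[2]) /
      ((delay[2] - delay[1]) * nrow(tgt$trials))
    tibble(unit_id = u, rate_on = per_state[["on"]],
           rate_off = per_state[["off"]], rate_all = all_rate)
  })
  ok <- complete.cases(rates)
  rate_tests <- if (sum(ok) >= 3) {
    tt1 <- t.test(rates$rate_on[ok], rates$rate_off[ok], paired = TRUE)
    tt2 <- t.test(rates$rate_on[ok], rates$rate_all[ok], paired = TRUE)
    tibble(comparison = c("on_vs_off", "on_vs_mean"),
           statistic = c(unname(tt1$statistic), unname(tt2$statistic)),
           p_value = c(tt1$p.value, tt2$p.value))
  } else {
    warn("too little on-labeled time for rate comparisons")
    tibble(comparison = c("on_vs_off", "on_vs_mean"),
           statistic = NA_real_, p_value = NA_real_)
  }
  list(
    curves = dplyr::bind_rows(curves),
    depth = depth,
    depth_test = tibble(estimate = mean(dd),
                        statistic = unname(tt3$statistic),
                        p_value = tt3$p.value, n_units = length(dd)),
    reduction_pct = (1 - mean(depth$depth_off, na.rm = TRUE) /
                       mean(depth$depth_all, na.rm = TRUE)) * 100,
    rate_tests = rate_tests,
    mean_rates = rates
  )
}

#' Count on/off states near the end of the delay by trial outcome
#'
#' Counts, per trial, the on and off states overlapping the last `window`
#' seconds of the delay period (membership by any overlap), restricted to
#' the site's overall preferred and least-preferred cue locations (largest
#' and smallest mean delay-period classification confidence), and
#' summarizes mean states/trial per (outcome x preference x state) cell.
#'
#' @param ds A [spike_dataset()] with `correct` filled in its trial table.
#' @param labels A [label_states()] result.
#' @param conf A `confidence_series` tibble (or the `posterior` of a
#'   [confidence_null()] converted to one) with `trial_id`, `time`,
#'   `posterior`.
#' @param window Seconds before delay end (default 0.5).
#' @return List: `per_trial` tibble, `cells` tibble (`correct`,
#'   `preference`, `state`, `mean_count`), `preferred_deg`,
#'   `least_preferred_deg`. Warns when no error trials are present.
#' @export
state_counts_by_outcome <- function(ds, labels, conf, window = 0.5) {
  stopifnot(inherits(ds, "spike_dataset"))
  delay_end <- epoch_interval("delay", ds$epochs)[2]
  w0 <- delay_end - window

  loc_of <- setNames(ds$trials$cue_location_deg, ds$trials$trial_id)
  conf$loc <- unname(loc_of[as.character(conf$trial_id)])
  by_loc <- conf |>
    dplyr::group_by(.data$loc) |>
    dplyr::summarise(m = mean(.data$posterior), .groups = "drop")
  pref <- by_loc$loc[which.max(by_loc$m)]
  least <- by_loc$loc[which.min(by_loc$m)]

  keep <- ds$trials[ds$trials$cue_location_deg %in% c(pref, least), ]
  per_trial <- purrr::map_dfr(seq_len(nrow(keep)), function(i) {
    tid <- keep$trial_id[i]
    lv <- labels[labels$trial_id == tid, ]
    overlap <- lv$end_s > w0 & lv$start_s < delay_end
    tibble(trial_id = tid,
           correct = keep$correct[i],
           preference = ifelse(keep$cue_location_deg[i] == pref,
                               "preferred", "least"),
           n_on = sum(overlap & lv$state == "on"),
           n_off = sum(overlap & lv$state == "off"))
  })
  if (all(per_trial$correct)) {
    warn("no error trials present; outcome contrasts unavailable")
  }
  cells <- per_trial |>
    tidyr::pivot_longer(c("n_on", "n_off"), names_to = "state",
                        values_to = "count") |>
    dplyr::mutate(state = sub("^n_", "", .data$state)) |>
    dplyr::group_by(.data$correct, .data$preference, .data$state) |>
    dplyr::summarise(mean_count = mean(.data$count), n_trials = dplyr::n(),
                     .groups = "drop")
  list(per_trial = per_trial, cells = cells,
       preferred_deg = pref, least_preferred_deg = least)
}

#' Three-way ANOVA on state counts across sessions
#'
#' Fits `mean_count ~ correct * preference * state` on per-session cell
#' means (sessions are the replicates) and returns the full ANOVA table.
#'
#' @param cells_by_session List of `cells` tibbles from
#'   [state_counts_by_outcome()], one per session.
#' @return Tidy ANOVA tibble: `term`, `df`, `statistic`, `p_value`.
#' @export
state_counts_anova <- function(cells_by_session) {
  df <- purrr::imap_dfr(cells_by_session, function(cl, i) {
    dplyr::mutate(cl, session = i)
  })
  if (length(unique(df$correct)) < 2) {
    warn("no error trials in any session; ANOVA skipped")
    return(tibble(term = character(), df = integer(),
                  statistic = numeric(), p_value = numeric()))
  }
  fit <- aov(mean_count ~ factor(correct) * factor(preference) *
               factor(state), data = df)
  tab <- summary(fit)[[1]]
  tibble(term = trimws(rownames(tab)), df = tab$Df,
         statistic = tab$`F value`, p_value = tab$`Pr(>F)`)
}
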