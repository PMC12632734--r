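#' Build pseudo-populations by trial shuffling within stimulus conditions
#'
#' Each pseudo-population permutes, independently for every neuron, the
#' trial identities within each cue-location stratum: stimulus labels are
#' preserved, per-neuron per-location rate distributions are exactly
#' preserved, but within-trial co-fluctuations across neurons are
#' destroyed. Stored compactly as per-neuron trial permutation maps; use
#' [pseudo_dataset()] to materialize one as a [spike_dataset()].
#'
#' @param ds A [spike_dataset()].
#' @param n Number of pseudo-populations (default 100).
#' @param seed Integer seed.
#' @return A `pseudo_population_set`: list with `perms` (list of
#'   unit x trial matrices of source-trial indices), `trial_id`, `unit_id`.
#' @export
build_pseudopopulations <- function(ds, n = 100, seed = 1) {
  stopifnot(inherits(ds, "spike_dataset"))
  if (any(table(ds$trials$cue_location_deg) < 2)) {
    abort("need >= 2 trials per cue location")
  }
  trial_ids <- ds$trials$trial_id
  loc <- ds$trials$cue_location_deg
  n_units <- nrow(ds$units)
  strata <- split(seq_along(trial_ids), loc)
  with_seed(seed, {
    perms <- lapply(seq_len(n), function(p) {
      m <- matrix(0L, n_units, length(trial_ids))
      for (u in seq_len(n_units)) {
        idx <- seq_along(trial_ids)
        for (s in strata) idx[s] <- s[sample.int(length(s))]
        m[u, ] <- idx
      }
      m
    })
    structure(list(perms = perms, trial_id = trial_ids,
                   unit_id = ds$units$unit_id),
              class = "pseudo_population_set")
  })
}

#' Materialize one pseudo-population as a spike dataset
#'
#' @param ds The source [spike_dataset()].
#' @param set A [build_pseudopopulations()] result.
#' @param k Which pseudo-population to materialize.
#' @return A [spike_dataset()] with spliced trials.
#' @export
pseudo_dataset <- function(ds, set, k = 1) {
  perm <- set$perms[[k]]
  sp <- ds$spikes
  ui <- match(sp$unit_id, set$unit_id)
  ti <- match(sp$trial_id, set$trial_id)
  # spikes of (unit u, source trial perm[u, t]) are assigned to trial t
  inv <- t(apply(perm, 1, order))  # inv[u, source] = destination slot
  sp$trial_id <- set$trial_id[inv[cbind(ui, ti)]]
  out <- ds
  out$spikes <- sp
  out
}

# permute a z-scored (or raw) binned_rates array according to one pseudo map
permute_binned <- function(arr, perm) {
  out <- arr
  for (u in seq_len(dim(arr)[1])) out[u, , ] <- arr[u, perm[u, ], ]
  out
}

#' Compare simultaneous and pseudo-population decoding
#'
#' Decodes the session as recorded and each pseudo-population on the same
#' bin grid (diagonal leave-one-out 8-way accuracy), then reports per bin:
#' the simultaneous accuracy, the pseudo-population mean/sd, the empirical
#' percentile of the simultaneous accuracy within the pseudo distribution,
#' and a Bonferroni-corrected exact two-sided permutation test (rank of the
#' simultaneous accuracy among the pseudo draws; with 100 draws the minimum
#' two-sided p is ~0.02, so Bonferroni flags are only attainable over a
#' handful of bins). Across bins, a
#' Wilcoxon signed-rank test compares the simultaneous series to the
#' pseudo-population mean, and mean accuracy differences are summarized per
#' task epoch (cue, delay, response).
#'
#' @param ds A [spike_dataset()].
#' @param set A [build_pseudopopulations()] result.
#' @param cfg A [decoder_config()].
#' @param span,bins Bin grid restriction as in [crosstemporal_decode()].
#' @param alpha Family-wise error level for the Bonferroni flags.
#' @return List: `per_bin` tibble (`time`, `accuracy_sim`, `pseudo_mean`,
#'   `pseudo_sd`, `percentile`, `p_value`, `significant`), `wilcoxon`
#'   (tibble `statistic`, `p_value`), `epoch_summary` tibble.
#' @export
compare_simul_vs_pseudo <- function(ds, set, cfg = decoder_config(),
                                    span = NULL, bins = NULL, alpha = 0.05) {
  stopifnot(inherits(ds, "spike_dataset"),
            inherits(set, "pseudo_population_set"))
  br <- bin_rates(ds, width = cfg$width, step = cfg$step, span = span)
  z <- if (cfg$zscore == "full") zscore_rates(br) else br
  zarr <- unclass(z)
  n_bins_all <- dim(zarr)[3]
  bins <- bins %||% seq_len(n_bins_all)
  y <- ds$trials$cue_location_deg[match(attr(br, "trial_id"),
                                        ds$trials$trial_id)]
  classes <- sort(unique(y))
  times <- attr(br, "times")[bins]

  binary <- cfg$scheme == "binary-diametric"
  if (binary && length(classes) != 2) {
    abort("binary-diametric comparison needs exactly 2 cue locations")
  }
  y01 <- as.integer(y == classes[1])
  acc_of <- function(arr) {
    vapply(seq_along(bins), function(bi) {
      x <- bin_features(arr, bins[bi])
      ok <- logical(length(y))
      for (i in seq_along(y)) {
        if (binary) {
          cf <- fit_binary_lasso(x[-i, , drop = FALSE], y01[-i], cfg$lambda)
          s <- cf[1] + sum(x[i, ] * cf[-1])
          ok[i] <- (s > 0) == (y01[i] == 1)
        } else {
          scorer <- fit_onevsall(x[-i, , drop = FALSE], y[-i], classes,
                                 cfg$lambda)
          sc <- scorer(x[i, , drop = FALSE])
          ok[i] <- classes[which.max(sc)] == y[i]
        }
      }
      mean(ok)
    }, numeric(1))
  }

  acc_sim <- acc_of(zarr)
  acc_pseudo <- vapply(set$perms, function(p) acc_of(permute_binned(zarr, p)),
                       numeric(length(bins)))
  if (is.null(dim(acc_pseudo))) acc_pseudo <- matrix(acc_pseudo, nrow = 1)

  ps_mean <- rowMeans(acc_pseudo)
  ps_sd <- apply(acc_pseudo, 1, sd)
  n_ps <- ncol(acc_pseudo)
  pct <- vapply(seq_along(bins), function(b) {
    mean(acc_pseudo[b, ] < acc_sim[b]) +
      0.5 * mean(acc_pseudo[b, ] == acc_sim[b])
  }, numeric(1))
  # exact two-sided permutation p from the pseudo-population rank
  p_lo <- vapply(seq_along(bins), function(b) {
    (1 + sum(acc_pseudo[b, ] <= acc_sim[b])) / (n_ps + 1)
  }, numeric(1))
  p_hi <- vapply(seq_along(bins), function(b) {
    (1 + sum(acc_pseudo[b, ] >= acc_sim[b])) / (n_ps + 1)
  }, numeric(1))
  p <- pmin(1, 2 * pmin(p_lo, p_hi))
  per_bin <- tibble(time = times, accuracy_sim = acc_sim,
                    pseudo_mean = ps_mean, pseudo_sd = ps_sd,
                    percentile = pct, p_value = p,
                    significant = p < alpha / length(bins))

  d <- acc_sim - ps_mean
  wx <- if (all(d == 0)) {
    tibble(statistic = NA_real_, p_value = 1)
  } else {
    w <- suppressWarnings(wilcox.test(acc_sim, ps_mean, paired = TRUE))
    tibble(statistic = unname(w$statistic), p_value = w$p.value)
  }

  ep <- odr_epochs()
  ep$epoch[ep$epoch == "response"] <- "saccade"
  epoch_summary <- purrr::map_dfr(seq_len(nrow(ep)), function(i) {
    sel <- times >= ep$start[i] & times < ep$end[i]
    if (!any(sel)) return(NULL)
    tibble(epoch = ep$epoch[i], mean_difference = mean(d[sel]),
           n_bins = sum(sel))
  })

  list(per_bin = per_bin, wilcoxon = wx, epoch_summary = epoch_summary,
       pseudo_accuracy = acc_pseudo)
}
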