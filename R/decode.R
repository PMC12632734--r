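#' Decoder configuration
#'
#' Leave-one-trial-out lasso-regularized logistic decoding of cue location
#' from z-scored population rates, either 8-way (one classifier per
#' location versus all others) or binary between a location and its
#' diametric opposite.
#'
#' @param lambda Lasso penalty (default 0.01).
#' @param width,step Rate bin width and step in seconds (defaults 0.1 and
#'   0.05).
#' @param scheme `"onevsall-8way"` or `"binary-diametric"`.
#' @param zscore `"full"` (z-score the whole rate matrix across trials, the
#'   default) or `"fold"` (fold-safe: statistics from the training trials
#'   only).
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(lambda = 0.01, width = 0.1, step = 0.05,
                           scheme = c("onevsall-8way", "binary-diametric"),
                           zscore = c("full", "fold")) {
  if (lambda <= 0) abort("lambda must be positive")
  structure(list(lambda = lambda, width = width, step = step,
                 scheme = match.arg(scheme), zscore = match.arg(zscore)),
            class = "decoder_config")
}

#' Z-score binned rates across trials
#'
#' Per (unit, bin): subtract the across-trial mean and divide by the
#' across-trial standard deviation. Zero-variance features are set to 0
#' (rather than dropped) so feature indices stay stable across folds; their
#' count is recorded in attribute `n_zero_variance`.
#'
#' @param binned A [bin_rates()] result.
#' @return A `binned_rates` array of z-scores with attributes `center` and
#'   `scale` (unit x bin matrices) for inversion.
#' @export
zscore_rates <- function(binned) {
  stopifnot(inherits(binned, "binned_rates"))
  arr <- unclass(binned)
  mu <- apply(arr, c(1, 3), mean)
  sg <- apply(arr, c(1, 3), sd)
  z <- sweep(arr, c(1, 3), mu, "-")
  z <- sweep(z, c(1, 3), ifelse(sg > 0, sg, 1), "/")
  zero <- sg == 0
  if (any(zero)) {
    # degenerate features: constant across trials -> exact 0 after centering
    for (b in which(apply(zero, 2, any))) z[zero[, b], , b] <- 0
  }
  out <- binned
  out[] <- z
  attr(out, "center") <- mu
  attr(out, "scale") <- sg
  attr(out, "n_zero_variance") <- sum(zero)
  out
}

# trials x units feature matrix for one bin; pads a second all-zero column
# for single-unit sessions (glmnet needs >= 2 columns)
bin_features <- function(zarr, b) {
  x <- t(zarr[, , b, drop = TRUE])
  if (is.null(dim(x))) x <- matrix(x, ncol = dim(zarr)[1])
  if (ncol(x) == 1) x <- cbind(x, 0)
  x
}

# one binary lasso-logistic fit at the target lambda; returns
# c(intercept, coefs). glmnet needs a warm-started lambda path to converge
# reliably at a single small penalty, so a short decreasing path ending at
# `lambda` is fit and its last solution extracted.
fit_binary_lasso <- function(x_train, yy, lambda) {
  if (length(unique(yy)) < 2) {
    abort("a class is absent from a training fold")
  }
  path <- lambda * 4^(4:0)
  # suppress glmnet's small-class advisory warning at desk-scale n
  f <- suppressWarnings(
    glmnet::glmnet(x_train, yy, family = "binomial", alpha = 1,
                   lambda = path, standardize = FALSE, thresh = 1e-6))
  k <- ncol(f$beta)
  c(as.numeric(f$a0)[k], as.numeric(f$beta[, k]))
}

# one-vs-all margin scores for all classes at a fixed train bin and fold.
# Returns function(newx) -> matrix n_new x n_classes of margins.
fit_onevsall <- function(x_train, y_train, classes, lambda) {
  coefs <- vapply(classes, function(cl) {
    yy <- as.integer(y_train == cl)
    if (length(unique(yy)) < 2) {
      abort(paste0("class ", cl, " absent from a training fold"))
    }
    fit_binary_lasso(x_train, yy, lambda)
  }, numeric(ncol(x_train) + 1))
  function(newx) {
    cbind(1, newx) %*% coefs
  }
}

#' Cross-temporal leave-one-out decoding of cue location
#'
#' For every train bin, an 8-way one-vs-all lasso-logistic decoder is fit on
#' all trials but one and tested on the held-out trial at every test bin; a
#' fresh model is fit per train bin, and within a fold one model serves all
#' test bins. Accuracy is the proportion of correctly classified held-out
#' trials.
#'
#' @param ds A [spike_dataset()].
#' @param cfg A [decoder_config()].
#' @param span Analysis interval (default full trial).
#' @param train_bins,test_bins Integer bin indices into the bin grid
#'   (default all bins). `diagonal = TRUE` restricts testing to the train
#'   bin, giving the accuracy time course.
#' @param diagonal Only decode train-time = test-time (default FALSE).
#'
#' @return A `ct_decode` object: list with `accuracy` (train x test
#'   matrix), `per_cue` (named list of accuracy matrices over trials of
#'   each cue), `train_times`, `test_times`, `n_trials`.
#' @export
crosstemporal_decode <- function(ds, cfg = decoder_config(), span = NULL,
                                 train_bins = NULL, test_bins = NULL,
                                 diagonal = FALSE) {
  stopifnot(inherits(ds, "spike_dataset"))
  br <- bin_rates(ds, width = cfg$width, step = cfg$step, span = span)
  z <- if (cfg$zscore == "full") zscore_rates(br) else br
  zarr <- unclass(z)
  y <- ds$trials$cue_location_deg[match(attr(br, "trial_id"),
                                        ds$trials$trial_id)]
  classes <- sort(unique(y))
  if (any(table(y) < 2)) abort("need >= 2 trials per cue location")
  n_bins <- dim(zarr)[3]
  train_bins <- train_bins %||% seq_len(n_bins)
  test_bins <- test_bins %||% if (diagonal) NULL else seq_len(n_bins)
  n_tr <- length(attr(br, "trial_id"))

  correct <- array(NA, c(length(train_bins),
                         if (diagonal) 1L else length(test_bins), n_tr))
  xs <- lapply(seq_len(n_bins), function(b) bin_features(zarr, b))

  for (i in seq_len(n_tr)) {
    for (bi in seq_along(train_bins)) {
      b <- train_bins[bi]
      x_tr <- xs[[b]][-i, , drop = FALSE]
      y_tr <- y[-i]
      if (cfg$zscore == "fold") {
        mu <- colMeans(x_tr); sg <- apply(x_tr, 2, sd); sg[sg == 0] <- 1
        x_tr <- scale(x_tr, mu, sg)
      }
      scorer <- fit_onevsall(x_tr, y_tr, classes, cfg$lambda)
      tb <- if (diagonal) b else test_bins
      newx <- do.call(rbind, lapply(tb, function(t2) xs[[t2]][i, , drop = FALSE]))
      if (cfg$zscore == "fold") newx <- scale(newx, mu, sg)
      sc <- scorer(newx)
      pred <- classes[max.col(matrix(sc, nrow = length(tb)))]
      correct[bi, , i] <- pred == y[i]
    }
  }
  test_times <- attr(br, "times")[if (diagonal) train_bins else test_bins]
  res <- list(
    accuracy = apply(correct, c(1, 2), mean),
    per_cue = setNames(lapply(classes, function(cl) {
      apply(correct[, , y == cl, drop = FALSE], c(1, 2), mean)
    }), classes),
    train_times = attr(br, "times")[train_bins],
    test_times = test_times,
    diagonal = diagonal,
    n_trials = n_tr
  )
  class(res) <- "ct_decode"
  res
}

#' Diagonal decoding accuracy time course
#'
#' Convenience wrapper for [crosstemporal_decode()] with train time = test
#' time, returning a tibble.
#'
#' @inheritParams crosstemporal_decode
#' @param bins Bin indices to decode (default all).
#' @return Tibble: `time`, `accuracy`.
#' @export
decode_timecourse <- function(ds, cfg = decoder_config(), span = NULL,
                              bins = NULL) {
  res <- crosstemporal_decode(ds, cfg, span = span, train_bins = bins,
                              diagonal = TRUE)
  tibble(time = res$train_times, accuracy = as.numeric(res$accuracy))
}

#' Two-class softmax posterior from margin scores
#'
#' `posterior_i = exp(score_i) / sum_j exp(score_j)` over the two classes.
#'
#' @param scores Numeric vector (or 2-column matrix) of class margins.
#' @return Posterior probabilities, same shape.
#' @export
#' @examples
#' softmax_posterior(c(log(3), 0))  # 0.75, 0.25
softmax_posterior <- function(scores) {
  if (is.matrix(scores)) {
    e <- exp(scores - apply(scores, 1, max))
    e / rowSums(e)
  } else {
    e <- exp(scores - max(scores))
    e / sum(e)
  }
}

# Leave-one-out binary confidence core. xs: list (per bin) of trials x
# units feature matrices; y: 0/1 truth; label_perm permutes *training*
# labels only. Returns trials x bins matrix of posterior of the true class.
binary_conf_matrix <- function(xs, y, lambda, label_perm = NULL) {
  n_tr <- length(y)
  y_train_all <- if (is.null(label_perm)) y else y[label_perm]
  post <- matrix(NA_real_, n_tr, length(xs))
  for (bi in seq_along(xs)) {
    x <- xs[[bi]]
    for (i in seq_len(n_tr)) {
      cf <- fit_binary_lasso(x[-i, , drop = FALSE], y_train_all[-i], lambda)
      s <- cf[1] + sum(x[i, ] * cf[-1])
      # margins (s, -s) for the two classes; softmax -> posterior of truth
      p1 <- softmax_posterior(c(s, -s))[1]
      post[i, bi] <- if (y[i] == 1) p1 else 1 - p1
    }
  }
  post
}

#' Binary diametric decoding with posterior confidence
#'
#' Leave-one-trial-out lasso-logistic classification of one cue location
#' against its diametric (180 deg) opposite. For each held-out trial and
#' time bin the two class margins (s, -s from the single binary fit) pass
#' through the two-class softmax, and the posterior probability of the
#' trial's *true* class is recorded — the decoder-confidence series that
#' downstream state labeling consumes.
#'
#' @param ds A [spike_dataset()].
#' @param pair Length-2 cue angles (degrees); defaults to the two locations
#'   present when the dataset has exactly two.
#' @param cfg A [decoder_config()].
#' @param span Analysis interval (default the full trial).
#' @param bins Bin indices (default all bins in `span`).
#' @param label_perm Optional permutation of the trial labels used for
#'   *training* only (label-shuffle null); confidence is still evaluated
#'   for the held-out trial's true class.
#'
#' @return A `confidence_series` tibble: `trial_id`, `time`, `posterior`.
#' @export
binary_diametric_decode <- function(ds, pair = NULL, cfg = decoder_config(),
                                    span = NULL, bins = NULL,
                                    label_perm = NULL) {
  stopifnot(inherits(ds, "spike_dataset"))
  locs <- sort(unique(ds$trials$cue_location_deg))
  pair <- pair %||% {
    if (length(locs) != 2) abort("specify `pair`: dataset has != 2 cue locations")
    locs
  }
  if ((pair[2] - pair[1]) %% 360 != 180 && length(locs) > 2) {
    warn("decoding a non-diametric location pair")
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
  n_tr <- length(y)
  n_bins <- dim(zarr)[3]
  bins <- bins %||% seq_len(n_bins)
  xs <- lapply(bins, function(b) bin_features(zarr, b))
  post <- binary_conf_matrix(xs, y, cfg$lambda, label_perm)
  out <- tibble(
    trial_id = rep(trial_ids, times = length(bins)),
    time = rep(attr(br, "times")[bins], each = n_tr),
    posterior = as.vector(post)
  )
  class(out) <- c("confidence_series", class(out))
  attr(out, "pair") <- pair
  attr(out, "bin_width") <- cfg$width
  attr(out, "bin_step") <- cfg$step
  out
}
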