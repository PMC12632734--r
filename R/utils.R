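# internal helpers shared across modules

#' @importFrom rlang .data abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats sd var median quantile rnorm runif rpois rexp rbinom
#'   p.adjust t.test wilcox.test lm aov anova coef predict fft dbeta rbeta
#'   optim complete.cases setNames na.omit
#' @importFrom utils head tail
NULL

# Deterministic sub-seed for a named random stage, derived from a global seed.
# Keeps stage streams independent: adding a stage never perturbs another.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # double arithmetic: sub-seeds compose (seed may already be ~2^31)
  as.integer((as.numeric(seed) * 1103 + h * 12289) %% 2147483647)
}

# Maximal runs of TRUE in a logical vector -> tibble(start, end) of indices
# (inclusive). Empty tibble when no runs.
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

#' Canonical cue angles of the 8-location delayed-response task
#'
#' @return Numeric vector `c(0, 45, ..., 315)` in degrees.
#' @export
canonical_angles <- function() seq(0, 315, by = 45)

# Snap arbitrary cue angles (e.g. the 120-location task variant) to the
# nearest of the 8 canonical angles.
snap_to_canonical <- function(deg) {
  (round((deg %% 360) / 45) * 45) %% 360
}

# Shortest signed angular difference a - b in degrees, in (-180, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

`%||%` <- rlang::`%||%`
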