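#' Welch power spectral density
#'
#' One-sided Welch estimate: the series is split into `window_s`-second
#' segments with fractional `overlap`, each segment is Hamming-windowed and
#' zero-padded to `nfft` points, and periodograms (normalized by
#' `fs * sum(w^2)`) are averaged. Mean-center the input first; a constant
#' series then has (numerically) zero power at all frequencies.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 2).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param nfft FFT length, zero-padded (default 1024).
#' @return Tibble: `freq` (Hz, 0 to fs/2), `power`.
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5, nfft = 1024) {
  L <- round(window_s * fs)
  if (length(x) < L) abort("series shorter than one Welch window")
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  nhalf <- nfft %/% 2
  acc <- numeric(nhalf + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    Y <- fft(c(seg, numeric(nfft - L)))
    P <- Mod(Y[1:(nhalf + 1)])^2 / (fs * sum(w^2))
    P[2:nhalf] <- 2 * P[2:nhalf]  # one-sided (DC and Nyquist unscaled)
    acc <- acc + P
  }
  tibble(freq = (0:nhalf) * fs / nfft, power = acc / length(starts))
}

#' Power spectrum of on/off state time series
#'
#' For each trial and state, builds a binary series marking time points
#' carrying that state label on a `bin_s` grid over `span`, mean-centers
#' it, computes the Welch PSD, and averages across trials per frequency.
#' Trials shorter than one Welch window are skipped and counted.
#'
#' @param labels A [label_states()] result (or tibble with `trial_id`,
#'   `state`, `start_s`, `end_s`).
#' @param state `"on"` or `"off"`.
#' @param bin_s State-series bin in seconds: 0.05 matches the decoder
#'   grid; 0.01 (100 Hz sampling) extends estimates to 50 Hz.
#' @param span Interval covered (default the delay period).
#' @param trial_ids Trials to include (default all labeled trials).
#' @inheritParams welch_psd
#' @return Tibble: `freq`, `power` (trial-averaged), with attribute
#'   `n_trials_used` and `n_trials_skipped`.
#' @export
state_psd <- function(labels, state = "off", bin_s = 0.01,
                      span = c(0.5, 3.5), trial_ids = NULL,
                      window_s = 2, overlap = 0.5, nfft = 1024) {
  fs <- 1 / bin_s
  centers <- seq(span[1] + bin_s / 2, span[2] - bin_s / 2 + 1e-12, by = bin_s)
  trial_ids <- trial_ids %||%
    (attr(labels, "trial_ids") %||% unique(labels$trial_id))
  used <- 0L; skipped <- 0L
  acc <- NULL
  for (tid in trial_ids) {
    iv <- labels[labels$trial_id == tid & labels$state == state, ]
    series <- rep(0, length(centers))
    for (r in seq_len(nrow(iv))) {
      series[centers >= iv$start_s[r] & centers < iv$end_s[r]] <- 1
    }
    if (length(series) < round(window_s * fs)) { skipped <- skipped + 1L; next }
    psd <- welch_psd(series - mean(series), fs, window_s, overlap, nfft)
    acc <- if (is.null(acc)) psd$power else acc + psd$power
    used <- used + 1L
  }
  if (skipped) inform(sprintf("%d trial(s) shorter than one window skipped", skipped))
  if (used == 0L) abort("no trial long enough for one Welch window")
  freq <- (0:(nfft %/% 2)) / (bin_s * nfft)
  structure(tibble(freq = freq, power = acc / used),
            n_trials_used = used, n_trials_skipped = skipped)
}
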