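#' Per-trial state at the go cue
#'
#' The neural state at fixation offset (the go cue for the saccade) is the
#' label of the state interval containing the end of the delay period;
#' trials whose go-cue bin is labeled neither on nor off are missing and
#' excluded downstream.
#'
#' @param ds A [spike_dataset()] with `rt_ms` in its trial table.
#' @param labels A [label_states()] result.
#' @param go_s Go-cue time (default the delay end, 3.5 s).
#' @return Tibble: `trial_id`, `rt_ms`, `state` (1 on, 0 off, NA missing).
#' @export
rt_state_table <- function(ds, labels, go_s = NULL) {
  go_s <- go_s %||% epoch_interval("delay", ds$epochs)[2]
  eps <- 1e-9
  st <- vapply(ds$trials$trial_id, function(tid) {
    iv <- labels[labels$trial_id == tid &
                   labels$start_s <= go_s - eps & labels$end_s >= go_s - eps, ]
    if (!nrow(iv)) NA_real_ else as.numeric(iv$state[1] == "on")
  }, numeric(1))
  tibble(trial_id = ds$trials$trial_id, rt_ms = ds$trials$rt_ms, state = st)
}

#' Session-bootstrapped reaction-time/state effect
#'
#' Within each session a linear model `RT ~ State` estimates `beta_state`,
#' the difference in mean RT between on and off states (RT_on - RT_off).
#' Sessions are then resampled with replacement `B` times; each draw's
#' mean `beta_state` forms the bootstrap distribution of the across-session
#' mean effect. The one-sided p-value is the proportion of bootstrap means
#' `>= 0`; the opposite tail is also reported, since the sign convention of
#' interest depends on the hypothesis.
#'
#' @param sessions List of per-session tibbles with columns `rt_ms` and
#'   `state` (1 = on, 0 = off, NA = missing; missing-state trials are
#'   excluded).
#' @param B Bootstrap draws (default 10000).
#' @param seed Integer seed.
#' @return An `rt_state_effect`: list with `beta_by_session`,
#'   `bootstrap_means`, `mean_beta`, `p_ge_0`, `p_le_0`, `n_sessions`.
#' @export
rt_state_bootstrap <- function(sessions, B = 10000, seed = 1) {
  betas <- purrr::imap_dbl(sessions, function(df, i) {
    df <- df[!is.na(df$state) & !is.na(df$rt_ms), ]
    if (length(unique(df$state)) < 2) return(NA_real_)
    unname(coef(lm(rt_ms ~ state, data = df))["state"])
  })
  dropped <- sum(is.na(betas))
  if (dropped) {
    warn(sprintf("%d session(s) with a single state at the go cue dropped", dropped))
  }
  betas <- betas[!is.na(betas)]
  if (length(betas) < 2) abort("need >= 2 usable sessions")
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      mean(betas[sample.int(length(betas), replace = TRUE)])
    }, numeric(1))
  })
  structure(list(beta_by_session = betas, bootstrap_means = boot,
                 mean_beta = mean(betas),
                 p_ge_0 = mean(boot >= 0), p_le_0 = mean(boot <= 0),
                 n_sessions = length(betas)),
            class = "rt_state_effect")
}

#' @export
print.rt_state_effect <- function(x, ...) {
  cat(sprintf("<rt_state_effect> %d sessions; mean beta_state = %.1f ms (RT_on - RT_off)\n",
              x$n_sessions, x$mean_beta))
  cat(sprintf("  one-sided p (bootstrap means >= 0): %.4f; (<= 0): %.4f\n",
              x$p_ge_0, x$p_le_0))
  invisible(x)
}

#' @export
glance.rt_state_effect <- function(x, ...) {
  tibble(n_sessions = x$n_sessions, mean_beta = x$mean_beta,
         p_ge_0 = x$p_ge_0, p_le_0 = x$p_le_0)
}
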