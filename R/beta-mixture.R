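#' Fit one- and two-component beta models to decoder confidence
#'
#' Fits (i) a single beta distribution by maximum likelihood and (ii) a
#' two-component beta mixture `w*Beta(a,b) + (1-w)*Beta(a',b')` by EM with
#' multiple restarts, to delay-period confidence values. Model comparison
#' uses `dAIC = AIC_2 - AIC_1` and `dBIC = BIC_2 - BIC_1` (k = 2 and 5
#' parameters): negative values favor the two-state model.
#'
#' @param x Confidence values; clamped to `[eps, 1 - eps]` since saturated
#'   classifiers produce exact 0/1.
#' @param n_restarts EM restarts (default 10): a moment-based quantile
#'   split, a degenerate start at the single-beta fit (guaranteeing the
#'   nested likelihood ordering), and random perturbations.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param eps Clamping epsilon (default 1e-6).
#' @param seed Integer seed for the random restarts.
#'
#' @return A `beta_mixture_fit`: list with `one` (a, b, loglik), `two`
#'   (w, a, b, a2, b2, loglik), `n`, `delta_aic`, `delta_bic`,
#'   `converged`.
#' @export
fit_beta_mixture <- function(x, n_restarts = 10, max_iter = 500,
                             tol = 1e-8, eps = 1e-6, seed = 1) {
  x <- pmin(pmax(x, eps), 1 - eps)
  n <- length(x)
  if (n < 20) abort("need >= 20 confidence values")

  lx <- log(x); l1x <- log1p(-x)
  # weighted MLE through sufficient statistics (O(1) per objective eval)
  beta_mle <- function(wts = NULL, start = NULL) {
    if (is.null(wts)) { sw <- n; slx <- sum(lx); sl1x <- sum(l1x) }
    else { sw <- sum(wts); slx <- sum(wts * lx); sl1x <- sum(wts * l1x) }
    m <- if (is.null(wts)) mean(x) else sum(wts * x) / sw
    v <- if (is.null(wts)) var(x) else sum(wts * (x - m)^2) / sw
    v <- max(v, 1e-8)
    common <- max(m * (1 - m) / v - 1, 1e-2)
    start <- start %||% log(pmax(c(m * common, (1 - m) * common), 1e-2))
    nll <- function(p) {
      a <- exp(p[1]); b <- exp(p[2])
      -((a - 1) * slx + (b - 1) * sl1x -
          sw * (lgamma(a) + lgamma(b) - lgamma(a + b)))
    }
    fit <- optim(start, nll, method = "BFGS",
                 control = list(reltol = 1e-10, maxit = 200))
    list(a = exp(fit$par[1]), b = exp(fit$par[2]), nll = fit$value)
  }

  one <- beta_mle()
  ll1 <- -one$nll

  em <- function(w, a, b, a2, b2) {
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- w * dbeta(x, a, b)
      d2 <- (1 - w) * dbeta(x, a2, b2)
      tot <- d1 + d2
      tot[tot < 1e-300] <- 1e-300
      r <- d1 / tot
      ll <- sum(log(tot))
      if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      w <- mean(r)
      w <- min(max(w, 1e-6), 1 - 1e-6)
      f1 <- beta_mle(r, start = log(c(a, b)))          # warm-started M-steps
      f2 <- beta_mle(1 - r, start = log(c(a2, b2)))
      a <- f1$a; b <- f1$b; a2 <- f2$a; b2 <- f2$b
    }
    list(w = w, a = a, b = b, a2 = a2, b2 = b2, loglik = ll,
         converged = converged)
  }

  starts <- with_seed(seed, {
    qs <- quantile(x, c(0.25, 0.75))
    mom <- function(m) {
      m <- min(max(m, 0.05), 0.95)
      c(a = m * 10, b = (1 - m) * 10)
    }
    lo <- mom(mean(x[x <= median(x)]))
    hi <- mom(mean(x[x > median(x)]))
    base <- list(
      c(0.5, lo[1], lo[2], hi[1], hi[2]),
      c(0.5, one$a, one$b, one$a, one$b)  # nested start: ll2 >= ll1
    )
    extra <- lapply(seq_len(max(0, n_restarts - 2)), function(i) {
      c(runif(1, 0.2, 0.8),
        exp(log(c(lo[1], lo[2], hi[1], hi[2])) + rnorm(4, 0, 0.5)))
    })
    c(base, extra)
  })
  fits <- lapply(starts, function(s) {
    tryCatch(em(s[1], s[2], s[3], s[4], s[5]), error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits) || !any(vapply(fits, function(f) f$converged, logical(1)))) {
    abort("beta-mixture EM failed to converge in all restarts")
  }
  two <- fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
  ll2 <- two$loglik

  aic1 <- 2 * 2 - 2 * ll1; aic2 <- 2 * 5 - 2 * ll2
  bic1 <- 2 * log(n) - 2 * ll1; bic2 <- 5 * log(n) - 2 * ll2
  structure(list(one = list(a = one$a, b = one$b, loglik = ll1),
                 two = two[c("w", "a", "b", "a2", "b2", "loglik")],
                 n = n, delta_aic = aic2 - aic1, delta_bic = bic2 - bic1,
                 converged = two$converged),
            class = "beta_mixture_fit")
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat(sprintf("<beta_mixture_fit> n = %d\n", x$n))
  cat(sprintf("  one-state: Beta(%.2f, %.2f), loglik %.2f\n",
              x$one$a, x$one$b, x$one$loglik))
  cat(sprintf("  two-state: w = %.2f, Beta(%.2f, %.2f) + Beta(%.2f, %.2f), loglik %.2f\n",
              x$two$w, x$two$a, x$two$b, x$two$a2, x$two$b2, x$two$loglik))
  cat(sprintf("  dAIC = %.2f, dBIC = %.2f (%s)\n", x$delta_aic, x$delta_bic,
              if (x$delta_bic < 0) "two-state preferred" else "one-state preferred"))
  invisible(x)
}

#' @export
tidy.beta_mixture_fit <- function(x, ...) {
  tibble(
    model = c(rep("one_state", 2), rep("two_state", 5)),
    term = c("a", "b", "w", "a", "b", "a2", "b2"),
    estimate = c(x$one$a, x$one$b, x$two$w, x$two$a, x$two$b,
                 x$two$a2, x$two$b2))
}

#' @export
glance.beta_mixture_fit <- function(x, ...) {
  tibble(n = x$n, loglik_one = x$one$loglik, loglik_two = x$two$loglik,
         delta_aic = x$delta_aic, delta_bic = x$delta_bic,
         preferred = ifelse(x$delta_bic < 0, "two_state", "one_state"))
}
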