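## Cumulative-Gaussian psychometric functions: construction, evaluation,
## maximum-likelihood fitting, threshold computation, observer simulation.

#' Construct a cumulative-Gaussian psychometric function
#'
#' The model is `psi(s) = guess + (1 - guess - lapse) * Phi((s - mu)/sigma)`
#' where `Phi` is the standard normal CDF. `guess` is the lower asymptote
#' (0.5 for a two-alternative near/far judgment), `lapse` the deficit of the
#' upper asymptote from 1. With `axis = "log"` the stimulus is transformed to
#' `log10` before evaluation, and `mu`/`sigma` live on the log axis.
#'
#' @param mu Location on the stimulus axis (e.g. % signal or arcsec).
#' @param sigma Slope scale, same units as `mu`; must be positive.
#' @param guess Lower asymptote in `[0, 1)`.
#' @param lapse Upper-asymptote deficit in `[0, 1)`; `guess + lapse < 1`.
#' @param axis `"linear"` or `"log"`.
#' @return A `psychometric_function` object.
#' @export
psychometric_function <- function(mu, sigma, guess = 0.5, lapse = 0,
                                  axis = c("linear", "log")) {
  axis <- match.arg(axis)
  abort_if(sigma <= 0, "sigma must be positive")
  abort_if(guess < 0 || guess >= 1 || lapse < 0 || lapse >= 1 ||
             guess + lapse >= 1, "need 0 <= guess, lapse and guess + lapse < 1")
  structure(list(mu = mu, sigma = sigma, guess = guess, lapse = lapse,
                 axis = axis),
            class = "psychometric_function")
}

#' Evaluate a psychometric function
#'
#' @param object A `psychometric_function`.
#' @param newdata Stimulus magnitudes. On a log axis these must be positive.
#' @param ... Unused.
#' @return Predicted proportion correct, in `[guess, 1 - lapse]`.
#' @export
predict.psychometric_function <- function(object, newdata, ...) {
  s <- newdata
  if (object$axis == "log") {
    abort_if(any(s <= 0), "log-axis evaluation requires positive levels")
    s <- log10(s)
  }
  object$guess + (1 - object$guess - object$lapse) *
    stats::pnorm((s - object$mu) / object$sigma)
}

#' @export
print.psychometric_function <- function(x, ...) {
  cat(sprintf(
    "psychometric_function (%s axis): mu = %.4g, sigma = %.4g, guess = %.3g, lapse = %.3g\n",
    x$axis, x$mu, x$sigma, x$guess, x$lapse))
  if (!is.null(attr(x, "logLik")))
    cat(sprintf("  logLik = %.4f%s\n", attr(x, "logLik"),
                if (isTRUE(attr(x, "degenerate"))) "  [degenerate fit]" else ""))
  invisible(x)
}

#' Behavioral data container
#'
#' Per-level correct/total counts for a forced-choice task.
#'
#' @param levels Distinct, non-negative stimulus magnitudes.
#' @param n_correct,n_total Counts per level, `0 <= n_correct <= n_total`.
#' @return A `behavioral_data` data.frame.
#' @export
behavioral_data <- function(levels, n_correct, n_total) {
  abort_if(anyDuplicated(levels) > 0, "levels must be distinct")
  abort_if(any(levels < 0), "levels must be non-negative")
  abort_if(any(n_correct < 0) || any(n_correct > n_total),
           "need 0 <= n_correct <= n_total")
  structure(data.frame(level = levels, n_correct = n_correct,
                       n_total = n_total),
            class = c("behavioral_data", "data.frame"))
}

#' Fit a psychometric function by binomial maximum likelihood
#'
#' Maximizes the binomial log-likelihood of per-level correct counts under
#' the cumulative-Gaussian model, within a parameter box, using bounded
#' quasi-Newton (L-BFGS-B) started from a deterministic 5 x 5 grid over
#' `(mu, sigma)`; the best likelihood wins, ties going to the first start.
#' The guess rate is fixed (default 0.5 for two-alternative judgments); the
#' lapse rate is free within `lapse_range` (default `[0, 0.06]`).
#'
#' All-correct or all-chance data still return a fit, flagged via the
#' `degenerate` attribute (parameters at the box boundary).
#'
#' @param data A `behavioral_data` (or data.frame with columns `level`,
#'   `n_correct`, `n_total`).
#' @param guess Fixed lower asymptote.
#' @param lapse_range Bounds for the lapse rate.
#' @param mu_range,sigma_range Optional bounds for location and slope;
#'   defaults span the sampled level range generously.
#' @param axis `"linear"` or `"log"` fitting axis.
#' @return A `psychometric_function` with attributes `logLik`, `degenerate`,
#'   and `data`.
#' @examples
#' pf <- psychometric_function(40, 20, guess = 0.5)
#' bd <- simulate_observer(pf, c(0, 20, 40, 60, 100), 200, seed = 1)
#' fit <- fit_psychometric(bd)
#' threshold(fit, 0.75)
#' @export
fit_psychometric <- function(data, guess = 0.5, lapse_range = c(0, 0.06),
                             mu_range = NULL, sigma_range = NULL,
                             axis = c("linear", "log")) {
  axis <- match.arg(axis)
  abort_if(!all(c("level", "n_correct", "n_total") %in% names(data)),
           "data needs columns level, n_correct, n_total")
  keep <- data$n_total > 0
  lev <- data$level[keep]; k <- data$n_correct[keep]; n <- data$n_total[keep]
  abort_if(length(lev) < 3, "need >= 3 levels with observations")
  s <- if (axis == "log") {
    abort_if(any(lev <= 0), "log-axis fitting requires positive levels")
    log10(lev)
  } else lev
  rng <- range(s); span <- max(diff(rng), .Machine$double.eps)
  if (is.null(mu_range)) mu_range <- c(rng[1] - span, rng[2] + 2 * span)
  if (is.null(sigma_range)) sigma_range <- c(span * 5e-3, span * 10)

  fixed_lapse <- diff(range(lapse_range)) == 0
  nll <- function(par) {
    lam <- if (fixed_lapse) lapse_range[1] else par[3]
    psi <- guess + (1 - guess - lam) * stats::pnorm((s - par[1]) / par[2])
    psi <- pmin(pmax(psi, 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(k, n, psi, log = TRUE))
  }
  starts <- expand.grid(
    mu = seq(rng[1], rng[2], length.out = 5),
    sigma = exp(seq(log(sigma_range[1] * 2), log(sigma_range[2] / 2),
                    length.out = 5))
  )
  lower <- c(mu_range[1], sigma_range[1], lapse_range[1])
  upper <- c(mu_range[2], sigma_range[2], lapse_range[2])
  np <- if (fixed_lapse) 2L else 3L
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    start <- c(starts$mu[i], starts$sigma[i], mean(lapse_range))[1:np]
    o <- tryCatch(
      stats::optim(start, nll, method = "L-BFGS-B",
                   lower = lower[1:np], upper = upper[1:np]),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value - 1e-12))
      best <- o
  }
  abort_if(is.null(best), "optimization failed from every start")
  par <- pmin(pmax(c(best$par, lapse_range[1])[1:3], lower), upper)
  tol <- 1e-6
  degenerate <- any(abs(par[1:2] - lower[1:2]) < tol * pmax(1, abs(lower[1:2]))) ||
    any(abs(par[1:2] - upper[1:2]) < tol * pmax(1, abs(upper[1:2])))
  pf <- psychometric_function(par[1], par[2], guess = guess, lapse = par[3],
                              axis = axis)
  attr(pf, "logLik") <- -best$value
  attr(pf, "degenerate") <- degenerate
  attr(pf, "data") <- data
  pf
}

#' Stimulus magnitude at a criterion accuracy
#'
#' Inverts the psychometric function analytically via the inverse normal:
#' the unique `s` with `psi(s) = criterion`.
#'
#' @param pf A `psychometric_function`.
#' @param criterion Probability strictly between `guess` and `1 - lapse`.
#' @return Stimulus magnitude on the original axis (back-transformed from
#'   log10 when the function lives on a log axis).
#' @export
threshold <- function(pf, criterion = 0.75) {
  stopifnot(inherits(pf, "psychometric_function"))
  abort_if(criterion <= pf$guess || criterion >= 1 - pf$lapse,
           "criterion %.3g outside attainable range (%.3g, %.3g)",
           criterion, pf$guess, 1 - pf$lapse)
  z <- stats::qnorm((criterion - pf$guess) / (1 - pf$guess - pf$lapse))
  s <- pf$mu + pf$sigma * z
  if (pf$axis == "log") 10^s else s
}

#' Simulate a binomial observer
#'
#' Draws per-level binomial counts with success probability `psi(level)`.
#'
#' @param pf A `psychometric_function`.
#' @param levels Stimulus magnitudes.
#' @param n_per_level Trials per level (scalar or vector).
#' @param seed Integer seed.
#' @return A `behavioral_data` data.frame.
#' @export
simulate_observer <- function(pf, levels, n_per_level, seed) {
  stopifnot(inherits(pf, "psychometric_function"))
  abort_if(any(n_per_level < 1), "n_per_level must be >= 1")
  n <- rep_len(n_per_level, length(levels))
  p <- predict(pf, levels)
  k <- with_seed(seed, stats::rbinom(length(levels), n, p))
  behavioral_data(levels, k, n)
}
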