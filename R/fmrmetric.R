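## fMR-metric functions: cumulative-Gaussian fits to decoding accuracies,
## the psychophysically scaled model, goodness of fit, and the saturation
## regression control.

#' Fit an fMR-metric function to decoding accuracies
#'
#' Least-squares cumulative-Gaussian fit of accuracy vs signal level,
#' `a(s) = low + (up - low) * Phi((s - mu)/sigma)`, with the lower asymptote
#' constrained to the chance band of the permutation null and the upper
#' asymptote free in `(low, 1]`. Optimization is bounded quasi-Newton from a
#' deterministic start grid; best residual wins.
#'
#' Accuracies flat at chance give a degenerate fit (flagged; threshold
#' undefined in any practical sense because the curve carries no signal).
#'
#' @param levels Signal magnitudes (>= 3).
#' @param accuracies Mean decoding accuracy per level.
#' @param band Numeric `c(low, high)` chance band within `[0, 1]`.
#' @param axis `"linear"` or `"log"` stimulus axis.
#' @return A `psychometric_function` (guess = fitted lower asymptote, lapse
#'   = 1 - upper) with attributes `rss`, `fitted`, `degenerate`, `band`.
#' @export
fit_fmrmetric <- function(levels, accuracies, band, axis = c("linear", "log")) {
  axis <- match.arg(axis)
  abort_if(length(levels) < 3, "need >= 3 levels")
  abort_if(length(levels) != length(accuracies), "levels/accuracies mismatch")
  abort_if(any(!is.finite(accuracies)), "non-finite accuracies")
  abort_if(band[1] < 0 || band[2] > 1 || band[1] > band[2],
           "band must be an interval within [0, 1]")
  s <- if (axis == "log") log10(pmax(levels, min(levels[levels > 0]) / 10))
       else levels
  rng <- range(s); span <- max(diff(rng), .Machine$double.eps)

  # parameters: mu, log sigma, low (in band; fixed if the band is a point),
  # up (in (low, 1])
  fixed_low <- diff(range(band)) == 0
  rss_fun <- function(par) {
    low <- if (fixed_low) band[1] else par[3]
    up <- par[length(par)]
    pred <- low + (up - low) * stats::pnorm((s - par[1]) / exp(par[2]))
    sum((accuracies - pred)^2)
  }
  lower <- c(rng[1] - span, log(span * 5e-3),
             if (!fixed_low) band[1], band[1])
  upper <- c(rng[2] + 2 * span, log(span * 10),
             if (!fixed_low) band[2], 1)
  best <- NULL
  mid <- mean(band)
  for (m0 in seq(rng[1], rng[2], length.out = 5)) {
    for (ls0 in seq(log(span * 0.05), log(span * 2), length.out = 4)) {
      for (u0 in c(max(mid + 0.05, 0.6), 0.8, 1)) {
        start <- c(m0, ls0, if (!fixed_low) mid, min(u0, 1))
        o <- tryCatch(
          stats::optim(start, rss_fun, method = "L-BFGS-B",
                       lower = lower, upper = upper),
          error = function(e) NULL)
        if (!is.null(o) && (is.null(best) || o$value < best$value - 1e-15))
          best <- o
      }
    }
  }
  abort_if(is.null(best), "optimization failed from every start")
  par <- pmin(pmax(best$par, lower), upper) # L-BFGS-B can exceed bounds by eps
  if (fixed_low) par <- c(par[1:2], band[1], par[3])
  low <- par[3]; up <- par[4]
  degenerate <- (up - low) < 1e-3
  pf <- psychometric_function(par[1], exp(par[2]), guess = low,
                              lapse = max(0, min(1 - up, 1 - low - 1e-12)),
                              axis = axis)
  attr(pf, "rss") <- best$value
  attr(pf, "fitted") <- low + (up - low) * stats::pnorm((s - par[1]) / exp(par[2]))
  attr(pf, "degenerate") <- degenerate
  attr(pf, "band") <- band
  pf
}

#' Scaled behavioral fit of decoding accuracies
#'
#' Carries the behavioral psychometric function's location and slope over
#' unchanged and rescales the curve vertically: the lower asymptote is fixed
#' near chance (default: the null-distribution median clamped into the
#' 32nd-68th centile band) and the upper asymptote is the single free
#' parameter, solved by closed-form one-dimensional least squares
#' (`up = low + sum(phi*(a - low)) / sum(phi^2)` with
#' `phi = Phi((s - mu)/sigma)`), then clamped to `(low, 1]`. An upper
#' asymptote driven to the lower boundary is flagged (no signal to scale).
#'
#' @param pf_behavior Behavioral `psychometric_function` on the same
#'   stimulus axis as `levels`.
#' @param levels Signal magnitudes.
#' @param accuracies Mean decoding accuracy per level.
#' @param band Chance band `c(low, high)` from [chance_band].
#' @param lower Optional fixed lower asymptote; default clamps
#'   `lower_hint` into the band.
#' @param lower_hint Value clamped into the band when `lower` is missing
#'   (default 0.5; pass the null median for data-driven anchoring).
#' @return An `fmrmetric_result`: list with `free_fit` (NULL until
#'   [fit_fmrmetric] output is attached by the caller), `scaled_fit`
#'   (mu, sigma, lower, upper, axis), `fitted`, `rss`, `band`, `flagged`.
#' @export
scaled_behavioral_fit <- function(pf_behavior, levels, accuracies, band,
                                  lower = NULL, lower_hint = 0.5) {
  stopifnot(inherits(pf_behavior, "psychometric_function"))
  abort_if(band[1] > band[2], "empty band")
  abort_if(length(levels) != length(accuracies), "levels/accuracies mismatch")
  if (is.null(lower)) lower <- min(max(lower_hint, band[1]), band[2])
  s <- if (pf_behavior$axis == "log")
    log10(pmax(levels, min(levels[levels > 0]) / 10)) else levels
  phi <- stats::pnorm((s - pf_behavior$mu) / pf_behavior$sigma)
  abort_if(sum(phi^2) == 0, "behavioral curve is flat over these levels")
  up_ls <- lower + sum(phi * (accuracies - lower)) / sum(phi^2)
  flagged <- up_ls <= lower
  up <- min(max(up_ls, lower), 1)
  fitted <- lower + (up - lower) * phi
  structure(list(
    scaled_fit = list(mu = pf_behavior$mu, sigma = pf_behavior$sigma,
                      lower = lower, upper = up, upper_unclamped = up_ls,
                      axis = pf_behavior$axis),
    fitted = fitted, rss = sum((accuracies - fitted)^2),
    levels = levels, accuracies = accuracies, band = band,
    flagged = flagged),
    class = "fmrmetric_result")
}

#' @export
print.fmrmetric_result <- function(x, ...) {
  cat(sprintf("fmrmetric_result: scaled fit upper = %.3f (lower fixed at %.3f)%s\n",
              x$scaled_fit$upper, x$scaled_fit$lower,
              if (x$flagged) " [flagged: driven to lower bound]" else ""))
  if (!is.null(x$gof))
    cat(sprintf("  goodness of fit: r = %.3f, p = %.4g, R^2 = %.3f\n",
                x$gof$r, x$gof$p, x$gof$r_squared))
  invisible(x)
}

#' Goodness of fit of accuracies to a scaled curve
#'
#' Pearson correlation between observed accuracies and model predictions at
#' the sampled levels, with a two-sided p-value from the t transform on
#' `n - 2` degrees of freedom; the coefficient of determination `R^2 = r^2`
#' is reported alongside. With only a handful of levels and one free
#' parameter these p-values are fragile; `warning_low_n` flags `n < 5`.
#'
#' @param observed Observed accuracies.
#' @param predicted Model predictions at the same levels.
#' @return List with `r`, `p`, `r_squared`, `df`, `warning_low_n`.
#' @export
goodness_of_fit <- function(observed, predicted) {
  abort_if(length(observed) != length(predicted), "length mismatch")
  n <- length(observed)
  abort_if(n < 3, "need >= 3 paired points")
  abort_if(stats::sd(predicted) == 0,
           "constant predictions: correlation undefined")
  r <- stats::cor(observed, predicted)
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  list(r = r, p = p, r_squared = r^2, df = df, warning_low_n = n < 5)
}

#' Saturation regression of accuracy on stimulus magnitude
#'
#' Ordinary least-squares regression of decoding accuracy on disparity
#' magnitude with a t-based 95% confidence interval on the slope. A CI
#' covering zero supports the verdict that accuracies have saturated (no
#' residual dependence on magnitude).
#'
#' @param levels Stimulus magnitudes (>= 3).
#' @param accuracies Decoding accuracies.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `slope`, `ci` (low, high), `saturated` (CI covers 0),
#'   `exact_fit` (TRUE when residuals are numerically zero, where the CI
#'   degenerates).
#' @export
saturation_regression <- function(levels, accuracies, conf_level = 0.95) {
  abort_if(length(levels) < 3, "need >= 3 points")
  fit <- stats::lm(accuracies ~ levels)
  slope <- unname(stats::coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  exact <- rss < .Machine$double.eps * 100 * max(1, sum(accuracies^2))
  ci <- unname(stats::confint(fit, "levels", level = conf_level))
  list(slope = slope, ci = c(ci[1], ci[2]),
       saturated = ci[1] <= 0 && ci[2] >= 0, exact_fit = exact)
}
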