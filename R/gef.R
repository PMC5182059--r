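#' Fit a single-exponential fluorescence rise
#'
#' Least-squares fit of \eqn{F(t) = baseline + \Delta F_{max}(1-e^{-kt})}
#' to a GTPgammaS-uptake fluorescence time course. Starting values:
#' baseline from the first point, amplitude from last minus first, and k
#' from a log-linear regression of \eqn{\log(plateau - F)} against time.
#' The fit is refined with Levenberg-Marquardt least squares.
#'
#' A flat or non-increasing trace, an optimizer failure or a non-positive
#' fitted rate yields \code{converged = FALSE}. A converged fit whose
#' sampled span covers fewer than two half-lives of the fitted rate is
#' additionally flagged \code{reliable = FALSE}: the plateau is then an
#' extrapolation and the amplitude (not the rate) is poorly determined.
#'
#' @param trace data.frame with columns \code{time_min} (strictly
#'   increasing, >= 6 points) and \code{intensity}.
#' @param conc0 optional initial concentration of the fluorescent
#'   substrate complex in uM; when given, the molar exchange rate
#'   \eqn{k \cdot conc_0} is reported.
#' @return object of class \code{gef_fit}: list with \code{k} (1/min),
#'   \code{dFmax}, \code{baseline} (AU), \code{v0_fluor} = k * dFmax
#'   (AU/min), \code{molar_rate} (uM/min or NA), \code{fit_rmse},
#'   \code{converged}, \code{reason}, \code{n}, \code{trace}.
#' @examples
#' tr <- simulate_fluorescence(k = 1.92, dFmax = 100, noise_sd = 1)
#' fit <- fit_single_exponential(tr, conc0 = 2)
#' coef(fit)
#' @export
fit_single_exponential <- function(trace, conc0 = NULL) {
  t <- trace$time_min; y <- trace$intensity
  if (length(t) < 6L) stop("trace needs at least 6 points")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")

  failed <- function(reason) {
    structure(list(k = NA_real_, dFmax = NA_real_, baseline = NA_real_,
                   v0_fluor = NA_real_, molar_rate = NA_real_,
                   fit_rmse = NA_real_, converged = FALSE, reliable = FALSE,
                   reason = reason, n = length(t), conc0 = conc0,
                   trace = trace),
              class = "gef_fit")
  }
  if (stats::sd(y) < .Machine$double.eps^0.5 * (abs(mean(y)) + 1)) {
    return(failed("flat trace"))
  }
  b0 <- y[1]
  a0 <- y[length(y)] - y[1]
  if (a0 <= 0) return(failed("non-increasing trace"))
  # log-linear start for k: log(plateau - F) ~ -k t
  plateau <- max(y) + 0.05 * abs(a0)
  pos <- plateau - y > 0
  k0 <- tryCatch({
    fitl <- stats::lm(log(plateau - y[pos]) ~ t[pos])
    max(-stats::coef(fitl)[[2]], 1e-3)
  }, error = function(e) 1)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ baseline + dFmax * (1 - exp(-k * t)),
      start = list(baseline = b0, dFmax = a0, k = k0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed("optimizer failure"))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["k"]]) || cf[["k"]] <= 0) {
    return(failed("non-positive fitted rate"))
  }
  half_lives <- (max(t) - min(t)) * cf[["k"]] / log(2)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  structure(list(
    k = cf[["k"]], dFmax = cf[["dFmax"]], baseline = cf[["baseline"]],
    v0_fluor = cf[["k"]] * cf[["dFmax"]],
    molar_rate = if (is.null(conc0)) NA_real_ else cf[["k"]] * conc0,
    fit_rmse = rmse,
    converged = TRUE,
    reliable = half_lives >= 2,
    reason = if (half_lives >= 2) "ok" else
      sprintf("trace spans only %.2f half-lives; plateau extrapolated",
              half_lives),
    n = length(t), conc0 = conc0, trace = trace),
    class = "gef_fit")
}

#' @export
print.gef_fit <- function(x, ...) {
  cat("Single-exponential fluorescence fit\n")
  if (!x$converged) {
    cat(sprintf("  NOT converged: %s\n", x$reason))
  }
  cat(sprintf("  k        = %.4g /min\n", x$k))
  cat(sprintf("  dFmax    = %.4g AU\n", x$dFmax))
  cat(sprintf("  baseline = %.4g AU\n", x$baseline))
  cat(sprintf("  v0       = %.4g AU/min\n", x$v0_fluor))
  if (is.finite(x$molar_rate)) {
    cat(sprintf("  molar rate = %.4g uM/min ([S]0 = %.3g uM)\n",
                x$molar_rate, x$conc0))
  }
  cat(sprintf("  RMSE     = %.4g AU over %d points\n", x$fit_rmse, x$n))
  invisible(x)
}

#' @export
coef.gef_fit <- function(object, ...) {
  c(k = object$k, dFmax = object$dFmax, baseline = object$baseline)
}

#' @export
predict.gef_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$trace$time_min
  object$baseline + object$dFmax * (1 - exp(-object$k * times))
}

#' @export
residuals.gef_fit <- function(object, ...) {
  object$trace$intensity - predict(object)
}

#' @export
plot.gef_fit <- function(x, ...) {
  graphics::plot(x$trace$time_min, x$trace$intensity,
                 xlab = "time (min)", ylab = "fluorescence (AU)", ...)
  tt <- seq(min(x$trace$time_min), max(x$trace$time_min), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = 2)
  invisible(x)
}

#' Initial velocity and molar exchange rate
#'
#' The fitted exponential has derivative \eqn{k \Delta F_{max} e^{-kt}},
#' hence initial velocity \eqn{v_0 = k \Delta F_{max}} in fluorescence
#' units. Calibrating fluorescence to concentration with the ratio
#' \eqn{\Delta F_{max} / [S]_0} (one amplitude corresponds to complete
#' exchange of the initial substrate pool) gives the molar rate
#' \eqn{v_0 / (\Delta F_{max}/[S]_0) = k [S]_0} in uM/min.
#'
#' @param fit a converged \code{gef_fit}.
#' @param conc0 initial substrate concentration in uM (> 0).
#' @return list with \code{v0_fluor} (AU/min) and \code{molar_rate}
#'   (uM/min).
#' @export
initial_velocity <- function(fit, conc0) {
  stopifnot(inherits(fit, "gef_fit"))
  if (!fit$converged) stop("fit did not converge; no velocity")
  if (conc0 <= 0) stop("'conc0' must be positive")
  list(v0_fluor = fit$k * fit$dFmax, molar_rate = fit$k * conc0)
}

#' Relative activity of mutants versus wild type
#'
#' Per-sample ratios of mutant exchange rates to a wild-type rate, with
#' their mean and sample standard deviation.
#'
#' @param mutant_rates numeric vector of mutant molar rates (uM/min).
#' @param wt_rate wild-type molar rate (> 0), uM/min.
#' @return list with \code{ratios}, \code{ratio_mean}, \code{ratio_sd}.
#' @export
relative_activity <- function(mutant_rates, wt_rate) {
  if (wt_rate <= 0) stop("'wt_rate' must be positive")
  r <- mutant_rates / wt_rate
  list(ratios = r, ratio_mean = mean(r),
       ratio_sd = if (length(r) > 1L) stats::sd(r) else 0)
}

#' Two-sample t test from summary statistics
#'
#' Two-tailed Student's t test on two groups given their means, standard
#' deviations and sizes. The default pools the variances
#' (df = n1 + n2 - 2); \code{welch = TRUE} uses the Welch-Satterthwaite
#' approximation instead. When both SDs are zero the p-value is 1 for
#' equal means and 0 otherwise, by convention.
#'
#' @param mean1,sd1,n1 first group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 second group summary.
#' @param welch use Welch's unequal-variance test.
#' @return list with \code{t}, \code{df}, \code{p_value}.
#' @export
compare_activities <- function(mean1, sd1, n1, mean2, sd2, n2,
                               welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    return(list(t = if (mean1 == mean2) 0 else Inf * sign(mean1 - mean2),
                df = n1 + n2 - 2,
                p_value = if (mean1 == mean2) 1 else 0))
  }
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    tstat <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / (sd1^4 / (n1^2 * (n1 - 1)) + sd2^4 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tstat, df = df, p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Significance stars for activity comparisons
#'
#' Conventional annotation: \code{***} for p < 0.001, \code{**} for
#' p < 0.005, \code{*} for p < 0.01, empty otherwise.
#'
#' @param p p-value(s).
#' @return character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.005, "**", ifelse(p < 0.01, "*", "")))
}
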