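#' Modified Gompertz (Zwietering) model value
#'
#' \deqn{y(t) = A \exp\{-\exp[\mu e / A (\lambda - t) + 1]\}}
#' where `A` is the asymptote of the log-relative growth, `mu` the maximum
#' specific growth rate (the steepest slope of the log curve) and `lam` the
#' lag time (the time-axis intercept of the tangent at the steepest point).
#'
#' @param t Time (hr), vectorised.
#' @param A Asymptote, `A > 0`.
#' @param mu Maximum specific growth rate (hr^-1).
#' @param lam Lag time (hr).
#' @return Model value(s), dimensionless log-ratio.
#' @examples
#' gompertz_value(2 + 3 / (0.8 * exp(1)), A = 3, mu = 0.8, lam = 2)  # = 3/e
#' @export
gompertz_value <- function(t, A, mu, lam) {
  if (any(A <= 0)) stop("A must be > 0", call. = FALSE)
  A * exp(-exp(mu * exp(1) / A * (lam - t) + 1))
}

#' Fit the modified Gompertz model to a growth curve
#'
#' Fits `gompertz_value()` to the logarithm of a growth curve by nonlinear
#' least squares (Levenberg-Marquardt trust region). The input may already
#' be a log-ratio curve (`input = "logratio"`), or a raw curve of cell
#' counts / OD values (`input = "raw"`) in which case the log-ratio
#' `log(v / v[1])` is formed internally and `od_ceiling` truncates the data
#' to values at or below the ceiling before the ratio is formed -- the
#' standard device for fitting only the low-OD regime where the OD-cell
#' number relation is close to linear.
#'
#' Starting values follow the Zwietering geometry: `A` from the maximum
#' log-ratio, `mu` from the steepest forward-difference slope, `lam` from
#' the time-axis intercept of the tangent at the steepest point.
#'
#' @param curve A [new_curve()] object (or anything with `times`/`values`).
#' @param od_ceiling Optional ceiling applied to raw values before the
#'   log-ratio is formed; ignored for `input = "logratio"`.
#' @param input `"logratio"` (default) or `"raw"`.
#' @param log_base Base of the logarithm for `input = "raw"`: `"e"`
#'   (natural, the convention the Zwietering formula with its factor of
#'   Euler's number presumes; default) or `"10"`. `A` and `mu` are
#'   reinterpreted consistently on the chosen scale.
#' @return A `gompertz_fit`: list with `A`, `mu`, `lam`, standard errors
#'   `se_A`, `se_mu`, `se_lam`, the fitted time `window`, `n_points` and a
#'   `converged` flag (on failure the estimates are `NA` and `converged` is
#'   `FALSE`).
#' @examples
#' tt <- seq(0, 16, 1/6)
#' y <- gompertz_value(tt, A = 3, mu = 0.8, lam = 2.5)
#' fit_gompertz(new_curve(tt, y))
#' @export
fit_gompertz <- function(curve, od_ceiling = NULL,
                         input = c("logratio", "raw"),
                         log_base = c("e", "10")) {
  stopifnot(inherits(curve, "gc_curve"))
  input <- match.arg(input)
  log_base <- match.arg(log_base)
  tt <- curve$times; vv <- curve$values
  if (input == "raw") {
    if (vv[1] <= 0) {
      stop("first value must be positive to form the log-ratio", call. = FALSE)
    }
    if (!is.null(od_ceiling)) {
      keep <- vv <= od_ceiling
      tt <- tt[keep]; vv <- vv[keep]
    }
    if (any(vv <= 0)) stop("raw values must be positive", call. = FALSE)
    y <- if (log_base == "e") log(vv / vv[1]) else log10(vv / vv[1])
  } else {
    y <- vv
  }
  if (length(y) < 8L) {
    stop("too few points for a Gompertz fit (need >= 8 after truncation)",
         call. = FALSE)
  }

  A0 <- max(y)
  if (A0 <= 0) stop("log-ratio curve never rises above its start",
                    call. = FALSE)
  slopes <- diff(y) / diff(tt)
  i_s <- which.max(slopes)
  mu0 <- max(slopes[i_s], 1e-6)
  lam0 <- tt[i_s] - y[i_s] / mu0

  fail <- structure(list(A = NA_real_, mu = NA_real_, lam = NA_real_,
                         se_A = NA_real_, se_mu = NA_real_, se_lam = NA_real_,
                         window = range(tt), n_points = length(y),
                         converged = FALSE, message = "optimizer failed"),
                    class = "gompertz_fit")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-exp(mu * exp(1) / A * (lam - t) + 1)),
      data = list(y = y, t = tt),
      start = list(A = A0, mu = mu0, lam = lam0),
      lower = c(A = 1e-12, mu = 1e-12, lam = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 2000,
                                           ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA, mu = NA, lam = NA))
  structure(list(A = unname(cf[["A"]]), mu = unname(cf[["mu"]]),
                 lam = unname(cf[["lam"]]),
                 se_A = unname(se[["A"]]), se_mu = unname(se[["mu"]]),
                 se_lam = unname(se[["lam"]]),
                 window = range(tt), n_points = length(y),
                 converged = TRUE, message = ""),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Gompertz fit: NOT converged (", x$message, ")\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Gompertz fit: A = %.4g +/- %.2g, mu = %.4g +/- %.2g /hr, lam = %.4g +/- %.2g hr\n",
    x$A, x$se_A, x$mu, x$se_mu, x$lam, x$se_lam))
  cat(sprintf("  (%d points, t in [%.3g, %.3g] hr)\n",
              x$n_points, x$window[1], x$window[2]))
  invisible(x)
}
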