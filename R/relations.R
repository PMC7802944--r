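#' Fit a dependency relation between a swept parameter and a peak summary
#'
#' Fits one of four relation families used to summarise how derivative-peak
#' locations and heights depend on model parameters:
#' \describe{
#'   \item{linear}{`y = slope * x + intercept`, ordinary least squares.}
#'   \item{power}{`y = prefactor * x^exponent`, ordinary least squares on
#'     `(log x, log y)`; the exponent is the log-log slope.}
#'   \item{exponential}{`y = prefactor * exp(rate * x)`, ordinary least
#'     squares on `(x, log y)`.}
#'   \item{michaelis_menten}{`y = VM * x / (x + KM) + b`, nonlinear least
#'     squares.}
#' }
#'
#' @param x,y Numeric vectors (>= 3 points); `x` and `y` must be positive
#'   for log-transformed families.
#' @param model One of `"linear"`, `"power"`, `"exponential"`,
#'   `"michaelis_menten"`.
#' @return A `relation_fit`: list with `model`, named `coefficients`, named
#'   `se` (standard errors, delta-method for back-transformed prefactors)
#'   and `r_squared` (on the fitting scale).
#' @examples
#' fit_relation(1:10, 3 * (1:10) + 1, "linear")
#' fit_relation(1:10, 2 * (1:10)^0.84, "power")
#' @export
fit_relation <- function(x, y, model = c("linear", "power", "exponential",
                                         "michaelis_menten")) {
  model <- match.arg(model)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite points", call. = FALSE)

  if (model == "linear") {
    fit <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(fit))
    cf <- stats::coef(fit)
    out <- list(coefficients = c(slope = unname(cf[2]),
                                 intercept = unname(cf[1])),
                se = c(slope = sm$coefficients[2, 2],
                       intercept = sm$coefficients[1, 2]),
                r_squared = sm$r.squared)
  } else if (model == "power") {
    if (any(x <= 0) || any(y <= 0)) {
      stop("power-law fits require positive x and y", call. = FALSE)
    }
    fit <- stats::lm(log(y) ~ log(x))
    sm <- suppressWarnings(summary(fit))
    cf <- stats::coef(fit)
    out <- list(coefficients = c(exponent = unname(cf[2]),
                                 prefactor = exp(unname(cf[1]))),
                se = c(exponent = sm$coefficients[2, 2],
                       prefactor = exp(unname(cf[1])) * sm$coefficients[1, 2]),
                r_squared = sm$r.squared)
  } else if (model == "exponential") {
    if (any(y <= 0)) {
      stop("exponential fits require positive y", call. = FALSE)
    }
    fit <- stats::lm(log(y) ~ x)
    sm <- suppressWarnings(summary(fit))
    cf <- stats::coef(fit)
    out <- list(coefficients = c(rate = unname(cf[2]),
                                 prefactor = exp(unname(cf[1]))),
                se = c(rate = sm$coefficients[2, 2],
                       prefactor = exp(unname(cf[1])) * sm$coefficients[1, 2]),
                r_squared = sm$r.squared)
  } else {
    b0 <- min(y)
    VM0 <- max(y) - b0
    half <- b0 + VM0 / 2
    KM0 <- x[which.min(abs(y - half))]
    if (!is.finite(KM0) || KM0 <= 0) KM0 <- stats::median(x)
    fit <- minpack.lm::nlsLM(
      y ~ VM * x / (x + KM) + b,
      data = list(x = x, y = y),
      start = list(VM = VM0, KM = KM0, b = b0),
      control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 5000))
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) stats::setNames(rep(NA_real_, 3),
                                                       names(cf)))
    res <- y - stats::predict(fit)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    out <- list(coefficients = c(VM = unname(cf[["VM"]]),
                                 KM = unname(cf[["KM"]]),
                                 b = unname(cf[["b"]])),
                se = c(VM = unname(se[["VM"]]), KM = unname(se[["KM"]]),
                       b = unname(se[["b"]])),
                r_squared = r2)
  }
  structure(c(list(model = model, n = length(x)), out),
            class = "relation_fit")
}

#' @export
print.relation_fit <- function(x, ...) {
  cat(sprintf("<relation_fit %s> R^2 = %.5f (n = %d)\n",
              x$model, x$r_squared, x$n))
  print(signif(x$coefficients, 5))
  invisible(x)
}
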