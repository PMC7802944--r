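#' Uniformly sampled scalar time series
#'
#' The basic container passed between the analysis stages: a time grid with
#' one scalar value per time point (cell count, OD, FL, or a derivative
#' thereof). Times must be strictly increasing with constant spacing.
#'
#' @param times Numeric vector of times (hr), uniform spacing.
#' @param values Numeric vector of the same length, all finite.
#' @param label Short label carried through derived curves.
#' @param deriv_order Derivative order of the values (0 for raw data).
#'
#' @return An object of class `gc_curve`: a list with elements `times`,
#'   `values`, `label`, `deriv_order`.
#' @examples
#' new_curve(seq(0, 16, by = 1/6), sin(seq(0, 16, by = 1/6)), label = "demo")
#' @export
new_curve <- function(times, values, label = "", deriv_order = 0L) {
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 1L) stop("curve must be non-empty", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(values))) {
    stop("curve times and values must be finite", call. = FALSE)
  }
  if (length(times) > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) {
      stop("times must be strictly increasing", call. = FALSE)
    }
    if (diff(range(dts)) > 1e-9 * max(abs(dts))) {
      stop("times must be uniformly spaced", call. = FALSE)
    }
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label, deriv_order = as.integer(deriv_order)),
            class = "gc_curve")
}

#' @export
print.gc_curve <- function(x, ...) {
  cat(sprintf("<gc_curve '%s'> %d points, t in [%.4g, %.4g] hr, order %d\n",
              x$label, length(x$times), min(x$times), max(x$times),
              x$deriv_order))
  invisible(x)
}

#' @export
as.data.frame.gc_curve <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

curve_spacing <- function(curve) {
  if (length(curve$times) < 2L) stop("curve has fewer than 2 points",
                                     call. = FALSE)
  mean(diff(curve$times))
}

#' Forward-difference time derivative of a curve
#'
#' Computes the discrete derivative
#' \eqn{(v_{i+1} - v_i) / (t_{i+1} - t_i)}, reported at \eqn{t_i}, the exact
#' estimator used on plate-reader exports; the result has one fewer point
#' than the input. A second-order derivative is obtained by applying the
#' function twice.
#'
#' @param curve A [new_curve()] object with at least 2 points.
#' @return A `gc_curve` of length `length(curve) - 1` with `deriv_order`
#'   incremented.
#' @examples
#' cv <- new_curve(0:10, (0:10)^2)
#' forward_diff(cv)$values        # 2*t + 1: forward-difference bias h
#' @export
forward_diff <- function(curve) {
  stopifnot(inherits(curve, "gc_curve"))
  if (length(curve$times) < 2L) {
    stop("forward_diff requires at least 2 points", call. = FALSE)
  }
  n <- length(curve$times)
  new_curve(curve$times[-n],
            diff(curve$values) / diff(curve$times),
            label = paste0("d", curve$label, "/dt"),
            deriv_order = curve$deriv_order + 1L)
}

#' Hanning (raised-cosine) smoothing of a curve
#'
#' Convolves the values with a Hann window
#' \eqn{w_j = 0.5 (1 - \cos(2\pi j/(K-1)))}, \eqn{j = 0 \dots K-1},
#' normalised to unit sum, so a constant curve passes through unchanged.
#' Edges are handled by reflection padding by default; the alternative
#' `"truncate"` policy renormalises the part of the kernel that overlaps the
#' data near each edge.
#'
#' @param curve A [new_curve()] object.
#' @param window Odd integer window length in points, `3 <= window <=`
#'   curve length. The default 11 is the shortest window of the 11-15 point
#'   range typical for 10-min sampled overnight runs.
#' @param edge Edge policy, `"reflect"` (default) or `"truncate"`.
#' @return A smoothed `gc_curve` of the same length.
#' @examples
#' set.seed(1)
#' noisy <- new_curve(seq(0, 16, 1/6), rnorm(97))
#' var(hanning_smooth(noisy, 11)$values) < var(noisy$values)
#' @export
hanning_smooth <- function(curve, window = 11L,
                           edge = c("reflect", "truncate")) {
  stopifnot(inherits(curve, "gc_curve"))
  edge <- match.arg(edge)
  n <- length(curve$values)
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  if (window < 3L || window > n) {
    stop("window must satisfy 3 <= window <= length(curve)", call. = FALSE)
  }
  kern <- as.numeric(signal::hanning(window))
  kern <- kern / sum(kern)
  m <- (window - 1L) %/% 2L
  v <- curve$values
  if (edge == "reflect") {
    padded <- c(v[(m + 1L):2L], v, v[(n - 1L):(n - m)])
    sm <- stats::filter(padded, kern, method = "convolution", sides = 2L)
    sm <- as.numeric(sm)[(m + 1L):(m + n)]
  } else {
    sm <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - m); hi <- min(n, i + m)
      kk <- kern[(lo - i + m + 1L):(hi - i + m + 1L)]
      sum(v[lo:hi] * kk) / sum(kk)
    }, numeric(1))
  }
  new_curve(curve$times, sm, label = curve$label,
            deriv_order = curve$deriv_order)
}
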