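#' Plate-reader time-series dataset
#'
#' Container for multimode plate-reader exports: per-well OD600 and FL
#' readings on a shared uniform time grid. The canonical storage is a tidy
#' long-form data frame with columns `well`, `condition`, `channel`
#' (`"OD600"` or `"FL"`), `time_hr` and `value`.
#'
#' @param data Tidy data frame as above.
#' @param pathlength_factor Path-length correction factor already applied to
#'   the OD values (`NA` if none).
#' @return An object of class `plate_dataset` with attributes `interval`
#'   (sampling period, hr) and `pathlength_factor`.
#' @export
plate_dataset <- function(data, pathlength_factor = NA_real_) {
  req <- c("well", "condition", "channel", "time_hr", "value")
  if (!all(req %in% names(data))) {
    stop("plate data must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(data$channel %in% c("OD600", "FL"))) {
    stop("channel must be 'OD600' or 'FL'", call. = FALSE)
  }
  if (any(!is.finite(data$value))) {
    bad <- which(!is.finite(data$value))[1]
    stop("non-finite value at row ", bad, call. = FALSE)
  }
  key <- paste(data$well, data$channel, data$time_hr)
  if (anyDuplicated(key)) {
    stop("duplicate well/channel/time triple: ", key[duplicated(key)][1],
         call. = FALSE)
  }
  # all wells of a channel must share one complete uniform grid
  grid <- sort(unique(data$time_hr))
  if (length(grid) < 2L) stop("need at least 2 time points", call. = FALSE)
  dts <- diff(grid)
  if (diff(range(dts)) > 1e-9 * max(dts)) {
    stop("time grid is not uniform", call. = FALSE)
  }
  counts <- table(paste(data$well, data$channel))
  if (length(unique(counts)) != 1L || unique(counts) != length(grid)) {
    short <- names(counts)[counts != length(grid)][1]
    stop("well/channel '", short, "' is missing time points", call. = FALSE)
  }
  data <- data[order(data$channel, data$well, data$time_hr), , drop = FALSE]
  rownames(data) <- NULL
  structure(data, class = c("plate_dataset", "data.frame"),
            interval = mean(dts), pathlength_factor = pathlength_factor)
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat(sprintf(
    "<plate_dataset> %d wells, channels: %s, %d time points every %.3g hr\n",
    length(unique(x$well)), paste(unique(x$channel), collapse = "/"),
    length(unique(x$time_hr)), attr(x, "interval")))
  cat(sprintf("  conditions: %s; path-length factor: %s\n",
              paste(unique(x$condition), collapse = ", "),
              format(attr(x, "pathlength_factor"))))
  invisible(x)
}

#' Read a plate-reader CSV export
#'
#' Two dialects are supported. The long form (default) has the columns
#' `well,condition,channel,time_hr,value`. The wide form, common in reader
#' exports, has a `time_hr` column followed by one column per well and holds
#' a single channel per file; a layout map (data frame or CSV with columns
#' `well,condition`) assigns wells to conditions, and unmapped wells are
#' dropped with a warning.
#'
#' @param path CSV file path.
#' @param format `"long"` or `"wide"`.
#' @param channel Channel of a wide file, `"OD600"` or `"FL"`.
#' @param layout Layout map for wide files: data frame or CSV path with
#'   columns `well`, `condition`. Ignored for long files.
#' @return A [plate_dataset()].
#' @export
read_plate_csv <- function(path, format = c("long", "wide"),
                           channel = "OD600", layout = NULL) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "long") {
    return(plate_dataset(df))
  }
  if (!"time_hr" %in% names(df)) {
    stop("wide plate file must have a 'time_hr' column", call. = FALSE)
  }
  if (is.character(layout) && length(layout) == 1L) {
    layout <- utils::read.csv(layout, stringsAsFactors = FALSE)
  }
  if (is.null(layout) || !all(c("well", "condition") %in% names(layout))) {
    stop("wide format needs a layout map with columns well, condition",
         call. = FALSE)
  }
  wells <- setdiff(names(df), "time_hr")
  unmapped <- setdiff(wells, layout$well)
  if (length(unmapped)) {
    warning("excluding unmapped wells: ", paste(unmapped, collapse = ", "))
    wells <- setdiff(wells, unmapped)
  }
  long <- do.call(rbind, lapply(wells, function(w) {
    data.frame(well = w,
               condition = layout$condition[match(w, layout$well)],
               channel = channel, time_hr = df$time_hr, value = df[[w]])
  }))
  plate_dataset(long)
}

#' Write a plate dataset as long-form CSV
#'
#' @param dataset A [plate_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "plate_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Path-length correction of OD readings
#'
#' Microplate beam paths differ from the standard 1-cm cuvette; raw OD
#' values are rescaled by a pre-calibrated multiplicative factor (2.39 for
#' the reference instrument). FL values are untouched. Negative corrected
#' values (e.g. from blank over-subtraction) are retained with a warning,
#' never clipped.
#'
#' @param dataset A [plate_dataset()].
#' @param factor Positive multiplicative factor.
#' @return The corrected `plate_dataset`; the applied factor accumulates in
#'   the `pathlength_factor` attribute.
#' @examples
#' # raw OD 0.1 becomes 0.239 under the default factor
#' @export
correct_od <- function(dataset, factor = 2.39) {
  stopifnot(inherits(dataset, "plate_dataset"))
  if (!is.numeric(factor) || factor <= 0) {
    stop("path-length factor must be > 0", call. = FALSE)
  }
  od <- dataset$channel == "OD600"
  if (!any(od)) stop("dataset has no OD600 channel", call. = FALSE)
  dataset$value[od] <- dataset$value[od] * factor
  if (any(dataset$value[od] < 0)) {
    warning("negative corrected OD values retained (not clipped)")
  }
  prev <- attr(dataset, "pathlength_factor")
  attr(dataset, "pathlength_factor") <- if (is.na(prev)) factor else
    prev * factor
  dataset
}

#' Aggregate replicate wells of one condition
#'
#' Pointwise mean and standard error of the mean (SEM = sample SD / sqrt(n))
#' across the replicate wells of a condition/channel. With a single
#' replicate the SEM is zero and the result is flagged.
#'
#' @param dataset A [plate_dataset()].
#' @param condition Condition label.
#' @param channel `"OD600"` or `"FL"`.
#' @return A `condition_curve`: list with `condition`, `channel`, `times`,
#'   `mean`, `sem`, `n_replicates`, `single_replicate` flag.
#' @examples
#' # replicates (1, 2, 3) at one time point give mean 2, SEM 1/sqrt(3)
#' @export
aggregate_condition <- function(dataset, condition, channel = "OD600") {
  stopifnot(inherits(dataset, "plate_dataset"))
  sub <- dataset[dataset$condition == condition &
                   dataset$channel == channel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no wells for condition '", condition, "' channel '", channel, "'",
         call. = FALSE)
  }
  wells <- unique(sub$well)
  n <- length(wells)
  times <- sort(unique(sub$time_hr))
  mat <- vapply(wells, function(w) {
    ws <- sub[sub$well == w, ]
    ws$value[order(ws$time_hr)]
  }, numeric(length(times)))
  mat <- matrix(mat, nrow = length(times))
  means <- rowMeans(mat)
  sems <- if (n > 1L) apply(mat, 1, stats::sd) / sqrt(n) else
    rep(0, length(times))
  structure(list(condition = condition, channel = channel, times = times,
                 mean = means, sem = sems, n_replicates = n,
                 single_replicate = n == 1L),
            class = "condition_curve")
}

#' @export
print.condition_curve <- function(x, ...) {
  cat(sprintf("<condition_curve '%s' %s> n = %d replicates, %d time points\n",
              x$condition, x$channel, x$n_replicates, length(x$times)))
  invisible(x)
}

#' Convert an aggregated condition curve to a plain curve of the means
#'
#' @param cc A `condition_curve` from [aggregate_condition()].
#' @return A [new_curve()] of the replicate means.
#' @export
as_curve <- function(cc) {
  stopifnot(inherits(cc, "condition_curve"))
  new_curve(cc$times, cc$mean,
            label = paste(cc$condition, cc$channel, sep = "/"))
}

#' Full derivative analysis of one aggregated condition
#'
#' Applies the standard processing order -- replicate mean, Hanning
#' smoothing, forward differencing -- and extracts the derivative peak. For
#' the OD channel the first derivative is analysed and the Gompertz model is
#' additionally fitted to `ln(OD/OD0)` truncated at `od_ceiling`; for the FL
#' channel the second derivative is analysed (optionally re-smoothing
#' between the two differencing passes).
#'
#' @param cc A `condition_curve` from [aggregate_condition()].
#' @param smooth_window Hanning window (points), see [hanning_smooth()].
#' @param od_ceiling OD ceiling for the Gompertz fit (default 1.0); `NULL`
#'   fits the full curve.
#' @param blank Scalar baseline subtracted from the mean curve before
#'   analysis (e.g. a blank-well level); default 0.
#' @param search_window Optional `c(t0, t1)` peak search window, useful to
#'   exclude short-time artifact peaks.
#' @param resmooth Re-apply smoothing between first and second differencing
#'   of FL curves (default `FALSE`: smooth once).
#' @return A `condition_analysis` list: `smoothed` curve, `derivative`
#'   curve, `peak` ([find_peak()] summary), and for OD `gompertz`
#'   ([fit_gompertz()]).
#' @export
analyze_condition <- function(cc, smooth_window = 11L, od_ceiling = 1.0,
                              blank = 0, search_window = NULL,
                              resmooth = FALSE) {
  stopifnot(inherits(cc, "condition_curve"))
  cv <- as_curve(cc)
  if (blank != 0) cv <- new_curve(cv$times, cv$values - blank,
                                  label = cv$label)
  sm <- hanning_smooth(cv, smooth_window)
  res <- list(condition = cc$condition, channel = cc$channel, smoothed = sm)
  with_label <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("condition '", cc$condition, "' (", cc$channel, "): ",
           conditionMessage(e), call. = FALSE)
    })
  }
  if (cc$channel == "OD600") {
    d1 <- forward_diff(sm)
    res$derivative <- d1
    res$peak <- with_label(find_peak(d1, window = search_window))
    res$gompertz <- with_label(
      fit_gompertz(cv, od_ceiling = od_ceiling, input = "raw"))
  } else {
    d1 <- forward_diff(sm)
    if (resmooth) d1 <- hanning_smooth(d1, smooth_window)
    d2 <- forward_diff(d1)
    res$derivative <- d2
    res$peak <- with_label(find_peak(d2, window = search_window))
  }
  structure(res, class = "condition_analysis")
}

#' @export
print.condition_analysis <- function(x, ...) {
  cat(sprintf("<condition_analysis '%s' %s>\n", x$condition, x$channel))
  print(x$peak)
  if (!is.null(x$gompertz)) print(x$gompertz)
  invisible(x)
}
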