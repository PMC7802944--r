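#' Measurement model for synthetic plate-reader data
#'
#' Maps simulated cell and fluorescent-protein counts to raw instrument
#' readings. OD uses a monotone saturating map,
#' `OD_raw = S (1 - exp(-od_scale n / S)) + baseline_od`, linear at low
#' density and flattening at high density -- a simple stand-in for the
#' multiple-scattering saturation of real microplate OD readings (the true
#' OD-cell number relation is instrument-specific and is deliberately not
#' modelled). FL is linear in the fluorescent-protein count. Noise is
#' multiplicative lognormal per reading, independent across wells and time
#' points, with unit mean and the stated coefficient of variation. An
#' optional Gaussian-shaped early-time OD bump emulates nanoparticle
#' interference artifacts.
#'
#' Default scales put the synthetic culture in a realistic raw-instrument
#' range: inoculum raw OD 0.05, linear-map maximum 1.0, saturation scale
#' 1.3, so the path-length-corrected curve spans roughly 0.1-1.7.
#'
#' @param od_scale Raw OD per cell (default 5e-10).
#' @param od_saturation Saturation scale `S` of the OD map, raw OD units
#'   (default 1.3); `Inf` gives a purely linear map.
#' @param fl_scale Raw FL per fluorescent protein (default 1e-9).
#' @param baseline_od,baseline_fl Additive offsets (defaults 0.04 and 100).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.02).
#' @param artifact Optional list `(amplitude, center, width)` for the
#'   early-time OD bump; `NULL` for none.
#' @param seed Integer RNG seed for reproducible noise.
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(od_scale = 5e-10, od_saturation = 1.3,
                              fl_scale = 1e-9, baseline_od = 0.04,
                              baseline_fl = 100, noise_cv = 0.02,
                              artifact = NULL, seed = 1L) {
  if (od_scale <= 0 || fl_scale <= 0) {
    stop("scales must be > 0", call. = FALSE)
  }
  if (od_saturation <= 0) stop("od_saturation must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (!is.null(artifact)) {
    if (!all(c("amplitude", "center", "width") %in% names(artifact)) ||
        artifact$width <= 0) {
      stop("artifact needs amplitude, center and width > 0", call. = FALSE)
    }
  }
  structure(list(od_scale = od_scale, od_saturation = od_saturation,
                 fl_scale = fl_scale, baseline_od = baseline_od,
                 baseline_fl = baseline_fl, noise_cv = noise_cv,
                 artifact = artifact, seed = as.integer(seed)),
            class = "measurement_model")
}

od_map <- function(n, meas) {
  S <- meas$od_saturation
  if (is.infinite(S)) meas$od_scale * n + meas$baseline_od
  else S * (1 - exp(-meas$od_scale * n / S)) + meas$baseline_od
}

#' Generate a synthetic plate-reader dataset with known ground truth
#'
#' Simulates the coupled growth/GFP model, maps the noiseless kinetics to
#' raw OD600 and FL readings through a [measurement_model()], applies seeded
#' multiplicative noise per replicate well, and returns both the dataset and
#' the ground-truth derivative-peak and Gompertz summaries of the noiseless
#' kinetics (computed on the same sampling grid with the same
#' forward-difference estimators the analysis pipeline uses).
#'
#' @param growth,gfp,init Model specification as for [simulate_growth()].
#' @param meas A [measurement_model()].
#' @param n_replicates Replicate wells per channel (default 3).
#' @param interval Sampling period (hr), default 10 min.
#' @param duration Run length (hr), default 16 (97 time points).
#' @param condition Condition label for all generated wells.
#' @return A `synthetic_plate` list: `dataset` (a [plate_dataset()] of raw
#'   readings) and `truth` (list with `tau_p`, `eta_p`, `tau_pf`, `eta_pf`,
#'   `lam`, `mu`, `A` of the noiseless kinetics, plus the generating
#'   parameters).
#' @examples
#' sp <- generate_plate_dataset(n_replicates = 2)
#' sp$truth$tau_p
#' @export
generate_plate_dataset <- function(growth = growth_params(),
                                   gfp = gfp_params(), init = NULL,
                                   meas = measurement_model(),
                                   n_replicates = 3L, interval = 1 / 6,
                                   duration = 16, condition = "control") {
  stopifnot(inherits(meas, "measurement_model"))
  if (interval <= 0 || duration < interval) {
    stop("need interval > 0 and duration >= interval", call. = FALSE)
  }
  tr <- simulate_growth(growth, gfp, init, t_end = duration, dt = interval)

  od_clean <- od_map(tr$n, meas)
  if (!is.null(meas$artifact)) {
    a <- meas$artifact
    od_clean <- od_clean +
      a$amplitude * exp(-0.5 * ((tr$time - a$center) / a$width)^2)
  }
  fl_clean <- meas$fl_scale * tr$pf + meas$baseline_fl

  # ground truth from the noiseless kinetics, same grid and estimators
  d1 <- forward_diff(trajectory_curve(tr, "n"))
  d2 <- forward_diff(forward_diff(trajectory_curve(tr, "pf")))
  pk_n <- find_peak(d1)
  pk_f <- find_peak(d2)
  gf <- fit_gompertz(new_curve(tr$time, log(tr$n / tr$n[1])))
  truth <- list(tau_p = pk_n$tau, eta_p = pk_n$eta,
                tau_pf = pk_f$tau, eta_pf = pk_f$eta,
                lam = gf$lam, mu = gf$mu, A = gf$A,
                growth = growth, gfp = gfp, meas = meas)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(meas$seed)
  sdlog <- sqrt(log(1 + meas$noise_cv^2))
  noisify <- function(v) {
    if (meas$noise_cv == 0) return(v)
    v * exp(stats::rnorm(length(v), -sdlog^2 / 2, sdlog))
  }
  rows <- lapply(seq_len(n_replicates), function(r) {
    w <- sprintf("%s_r%d", condition, r)
    rbind(
      data.frame(well = w, condition = condition, channel = "OD600",
                 time_hr = tr$time, value = noisify(od_clean)),
      data.frame(well = w, condition = condition, channel = "FL",
                 time_hr = tr$time, value = noisify(fl_clean)))
  })
  ds <- plate_dataset(do.call(rbind, rows))
  structure(list(dataset = ds, truth = truth), class = "synthetic_plate")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  print(x$dataset)
  cat(sprintf(
    "  truth: tau_p = %.3g hr, tau_pf = %.3g hr, lam = %.3g hr, mu = %.3g /hr\n",
    x$truth$tau_p, x$truth$tau_pf, x$truth$lam, x$truth$mu))
  invisible(x)
}
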