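#' Growth-model parameters
#'
#' Parameters of the two-state bacterial growth model in which dormant cells
#' activate into dividing cells that then grow logistically.
#'
#' @param alpha Activation rate (hr^-1) at which dormant cells become active.
#' @param k0 Maximum growth rate (hr^-1) of active cells with unlimited
#'   nutrients.
#' @param N Carrying capacity: maximum possible cell number (dimensionless
#'   count) for the available nutrients.
#'
#' @return An object of class `growth_params`.
#' @examples
#' growth_params()                 # defaults: alpha = 1, k0 = 1, N = 2e9
#' growth_params(alpha = 0.1)
#' @export
growth_params <- function(alpha = 1, k0 = 1, N = 2e9) {
  stopifnot(is.numeric(alpha), is.numeric(k0), is.numeric(N))
  if (!all(is.finite(c(alpha, k0, N)))) {
    stop("growth parameters must be finite", call. = FALSE)
  }
  if (alpha < 0 || k0 < 0) stop("alpha and k0 must be >= 0", call. = FALSE)
  if (N <= 0) stop("N must be > 0", call. = FALSE)
  structure(list(alpha = alpha, k0 = k0, N = N), class = "growth_params")
}

#' GFP expression parameters
#'
#' Parameters of the reporter-protein model: active cells express
#' non-fluorescent GFP at rate `g`; non-fluorescent GFP matures into
#' fluorescent GFP at rate `km`; both species are degraded by shared
#' machinery at rate `gamma` with saturable capacity `M`.
#'
#' @param g GFP generation rate per active cell (hr^-1).
#' @param km Maturation rate (hr^-1).
#' @param gamma Degradation rate (hr^-1).
#' @param M Degradation capacity (dimensionless count); the saturation
#'   constant of the Michaelis-Menten-like degradation term.
#'
#' @return An object of class `gfp_params`.
#' @examples
#' gfp_params()   # defaults: g = 100, km = 1.5, gamma = 500, M = 2e11
#' @export
gfp_params <- function(g = 100, km = 1.5, gamma = 500, M = 2e11) {
  stopifnot(is.numeric(g), is.numeric(km), is.numeric(gamma), is.numeric(M))
  if (!all(is.finite(c(g, km, gamma, M)))) {
    stop("GFP parameters must be finite", call. = FALSE)
  }
  if (g < 0 || km < 0 || gamma < 0) {
    stop("g, km and gamma must be >= 0", call. = FALSE)
  }
  if (M <= 0) stop("M must be > 0", call. = FALSE)
  structure(list(g = g, km = km, gamma = gamma, M = M), class = "gfp_params")
}

#' Initial state of the coupled model
#'
#' By convention a culture starts fully dormant at 5% of carrying capacity
#' with no reporter protein present; `initial_state()` with no arguments
#' applied to a `growth_params` object reproduces that convention.
#'
#' @param nD0 Initial dormant cell count.
#' @param nA0 Initial active cell count.
#' @param pn0 Initial non-fluorescent GFP count.
#' @param pf0 Initial fluorescent GFP count.
#'
#' @return An object of class `initial_state`.
#' @seealso [default_initial_state()]
#' @export
initial_state <- function(nD0, nA0 = 0, pn0 = 0, pf0 = 0) {
  vals <- c(nD0 = nD0, nA0 = nA0, pn0 = pn0, pf0 = pf0)
  if (!all(is.finite(vals))) stop("initial state must be finite", call. = FALSE)
  if (any(vals < 0)) stop("initial state must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "initial_state")
}

#' Default initial state: 5% of carrying capacity, all dormant
#'
#' @param growth A `growth_params` object supplying the carrying capacity.
#' @return An `initial_state` with `nD0 = 0.05 * N` and all other pools empty.
#' @export
default_initial_state <- function(growth = growth_params()) {
  initial_state(nD0 = 0.05 * growth$N)
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth parameters: alpha = %g /hr, k0 = %g /hr, N = %g\n",
              x$alpha, x$k0, x$N))
  invisible(x)
}

#' @export
print.gfp_params <- function(x, ...) {
  cat(sprintf("GFP parameters: g = %g /hr, km = %g /hr, gamma = %g /hr, M = %g\n",
              x$g, x$km, x$gamma, x$M))
  invisible(x)
}

#' Read a flat key:value model configuration file
#'
#' The configuration format is plain text with one `key: value` pair per
#' line; `#` starts a comment.  Recognised keys are `alpha`, `k0`, `N`, `g`,
#' `km`, `gamma`, `M`, `nD0`, `nA0`, `pn0`, `pf0`, `t_end` and `dt`; missing
#' keys fall back to the package defaults.
#'
#' @param path Path to the configuration file.
#' @return A list with components `growth`, `gfp`, `init`, `t_end`, `dt`.
#' @export
read_model_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  bad <- vapply(kv, length, 1L) < 2L
  if (any(bad)) {
    stop("malformed config line: ", lines[bad][1], call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(
    kv, function(p) paste(p[-1], collapse = ":"), ""))))
  if (anyNA(vals)) {
    stop("non-numeric config value for key: ", keys[is.na(vals)][1],
         call. = FALSE)
  }
  known <- c("alpha", "k0", "N", "g", "km", "gamma", "M",
             "nD0", "nA0", "pn0", "pf0", "t_end", "dt")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- as.list(vals[match(known, keys)])
  names(cfg) <- known
  gp <- growth_params(
    alpha = if (is.na(cfg$alpha)) 1 else cfg$alpha,
    k0 = if (is.na(cfg$k0)) 1 else cfg$k0,
    N = if (is.na(cfg$N)) 2e9 else cfg$N)
  fp <- gfp_params(
    g = if (is.na(cfg$g)) 100 else cfg$g,
    km = if (is.na(cfg$km)) 1.5 else cfg$km,
    gamma = if (is.na(cfg$gamma)) 500 else cfg$gamma,
    M = if (is.na(cfg$M)) 2e11 else cfg$M)
  init <- initial_state(
    nD0 = if (is.na(cfg$nD0)) 0.05 * gp$N else cfg$nD0,
    nA0 = if (is.na(cfg$nA0)) 0 else cfg$nA0,
    pn0 = if (is.na(cfg$pn0)) 0 else cfg$pn0,
    pf0 = if (is.na(cfg$pf0)) 0 else cfg$pf0)
  list(growth = gp, gfp = fp, init = init,
       t_end = if (is.na(cfg$t_end)) NULL else cfg$t_end,
       dt = if (is.na(cfg$dt)) 0.01 else cfg$dt)
}
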