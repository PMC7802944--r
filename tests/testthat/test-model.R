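test_that("parameter constructors enforce their invariants", {
  expect_error(growth_params(alpha = -1), "alpha")
  expect_error(growth_params(N = 0), "N must be")
  expect_error(gfp_params(M = -5), "M must be")
  expect_error(initial_state(nD0 = -1), ">= 0")
  expect_error(growth_rhs(c(1, NA, 0, 0), growth_params(), gfp_params()),
               "finite")
})

test_that("right-hand side matches the model equations at hand-checked states", {
  gp <- growth_params(alpha = 2, k0 = 1.3, N = 1e9)
  fp <- gfp_params(g = 50, km = 0.7, gamma = 300, M = 1e11)

  # absorbing zero state
  expect_equal(unname(growth_rhs(c(0, 0, 0, 0), gp, fp)), rep(0, 4))

  # dormant pool only: activation flux conserves total cell number
  d <- growth_rhs(c(1e8, 0, 0, 0), gp, fp)
  expect_equal(d[["nD"]], -2 * 1e8)
  expect_equal(d[["nA"]], 2 * 1e8)
  expect_equal(d[["nD"]] + d[["nA"]], 0)

  # carrying capacity is a fixed point of the active pool
  d2 <- growth_rhs(c(0, 1e9, 0, 0), gp, fp)
  expect_equal(d2[["nA"]], 0)

  # generic state against a direct transcription of the equations
  st <- c(3e7, 4e8, 1e9, 5e8)
  d3 <- growth_rhs(st, gp, fp)
  denom <- st[3] + st[4] + fp$M
  expect_equal(d3[["pn"]], fp$g * st[2] - fp$km * st[3] -
                 fp$gamma * st[3] / denom)
  expect_equal(d3[["pf"]], fp$km * st[3] - fp$gamma * st[4] / denom)
})

test_that("dormant pool decays exponentially and total cells follow the logistic form", {
  gp <- growth_params(alpha = 0.7, k0 = 1, N = 2e9)
  tr <- simulate_growth(gp, gfp_params(), t_end = 16, dt = 0.01)
  expect_equal(tr$nD, 0.05 * gp$N * exp(-0.7 * tr$time), tolerance = 1e-7)

  # with no dormant cells the total follows the logistic closed form
  n0 <- 1e8
  tr2 <- simulate_growth(growth_params(alpha = 0.3, k0 = 1.2, N = 2e9),
                         gfp_params(),
                         init = initial_state(nD0 = 0, nA0 = n0),
                         t_end = 16, dt = 0.01)
  expect_equal(tr2$n, logistic_closed_form(tr2$time, n0, 1.2, 2e9),
               tolerance = 1e-7)
})

test_that("default simulation reaches carrying capacity and matches an RK4 reference", {
  tr <- simulate_growth(t_end = 16, dt = 0.01)
  expect_lt(abs(tr$n[nrow(tr)] - 2e9) / 2e9, 0.01)
  expect_equal(tr$n, tr$nD + tr$nA)
  expect_true(all(diff(tr$n) >= -1e-6 * 2e9))
  # pf keeps increasing without plateau over the run
  expect_true(all(diff(tr$pf) > 0))

  ref <- rk4_reference(1, 1, 2e9, 100, 1.5, 500, 2e11,
                       y0 = c(0.05 * 2e9, 0, 0, 0), t_end = 16)
  final <- unlist(tr[nrow(tr), c("nD", "nA", "pn", "pf")])
  expect_equal(unname(final[2]), ref[2], tolerance = 1e-6)
  expect_equal(unname(final[4]), ref[4], tolerance = 1e-6)
})

test_that("no GFP source means no protein, ever", {
  tr <- simulate_growth(gfp = gfp_params(g = 0), t_end = 16, dt = 0.1)
  expect_equal(max(abs(tr$pn)), 0)
  expect_equal(max(abs(tr$pf)), 0)
})

test_that("state variables stay non-negative over a randomized parameter suite", {
  set.seed(42)
  for (i in 1:15) {
    gp <- growth_params(alpha = 10^runif(1, -3, 1.5), k0 = runif(1, 0.2, 3),
                        N = 10^runif(1, 7, 10))
    fp <- gfp_params(g = 10^runif(1, 0, 3), km = 10^runif(1, -2, 1),
                     gamma = 10^runif(1, 1, 9), M = 10^runif(1, 9, 13))
    tr <- simulate_growth(gp, fp, t_end = 16, dt = 0.1)
    expect_true(all(tr$nD >= 0), label = sprintf("nD >= 0 (draw %d)", i))
    expect_true(all(tr$nA >= 0), label = sprintf("nA >= 0 (draw %d)", i))
    expect_true(all(tr$pn >= 0), label = sprintf("pn >= 0 (draw %d)", i))
    expect_true(all(tr$pf >= 0), label = sprintf("pf >= 0 (draw %d)", i))
    # monotone growth is only guaranteed while the active pool stays at or
    # below carrying capacity (continued dormant influx can overshoot it)
    if (all(tr$nA <= gp$N)) {
      expect_true(all(diff(tr$n) >= -1e-6 * gp$N),
                  label = sprintf("n non-decreasing (draw %d)", i))
    }
  }
})

test_that("protein kinetics reduce to the linear system when pn + pf << M", {
  # constant active pool: alpha = 0, k0 = 0, all cells start active
  nA <- 1e8
  fp <- gfp_params(g = 10, km = 0.8, gamma = 1e3, M = 1e12)
  tr <- simulate_growth(growth_params(alpha = 0, k0 = 0, N = 2e9), fp,
                        init = initial_state(nD0 = 0, nA0 = nA),
                        t_end = 4, dt = 0.5)
  expect_lt(max(tr$pn + tr$pf) / fp$M, 5e-3)  # linear regime holds
  ref <- linear_protein_oracle(tr$time, nA, fp$g, fp$km, fp$gamma, fp$M)
  # the protein states are resolved to an absolute tolerance of 1e-6 * M
  expect_lt(max(abs(tr$pn - ref[1, ])), 1e-6 * fp$M)
  expect_lt(max(abs(tr$pf - ref[2, ])), 1e-6 * fp$M)
  # and to a much tighter relative accuracy once the pools are populated
  late <- tr$time >= 1
  expect_equal(tr$pn[late], ref[1, late], tolerance = 1e-3)
  expect_equal(tr$pf[late], ref[2, late], tolerance = 1e-3)
})

test_that("pf is non-decreasing wherever maturation influx beats degradation", {
  tr <- simulate_growth(gfp = gfp_params(gamma = 1e11), t_end = 16, dt = 0.1)
  influx <- 1.5 * tr$pn
  outflux <- 1e11 * tr$pf / (tr$pn + tr$pf + 2e11)
  rising <- which(influx >= outflux)
  rising <- rising[rising < nrow(tr)]
  expect_true(all(diff(tr$pf)[rising] >= -1e-6 * 2e11))
})

test_that("trajectories round-trip through CSV and config files load", {
  tr <- simulate_growth(t_end = 2, dt = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$n, tr$n, tolerance = 1e-12)

  cfg_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("alpha: 0.5", "k0: 1.2", "N: 1e9", "# comment", "dt: 0.1"),
             cfg_path)
  cfg <- read_model_config(cfg_path)
  expect_equal(cfg$growth$alpha, 0.5)
  expect_equal(cfg$growth$N, 1e9)
  expect_equal(cfg$init$nD0, 0.05 * 1e9)
  expect_equal(cfg$gfp$km, 1.5)  # default fills the gap
  expect_error(read_model_config({
    p <- withr::local_tempfile(); writeLines("alpha zz", p); p
  }), "malformed|non-numeric")
})
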