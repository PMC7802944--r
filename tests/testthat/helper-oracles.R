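# Independent oracles used across the suite. The model equations are
# restated here on purpose so that the reference solutions do not share code
# with the implementation under test.

# fixed-step classical Runge-Kutta integration of the coupled system
rk4_reference <- function(alpha, k0, N, g, km, gamma, M,
                          y0, t_end, dt = 1e-3) {
  f <- function(y) {
    denom <- y[3] + y[4] + M
    c(-alpha * y[1],
      alpha * y[1] + k0 * (1 - y[2] / N) * y[2],
      g * y[2] - km * y[3] - gamma * y[3] / denom,
      km * y[3] - gamma * y[4] / denom)
  }
  n_steps <- round(t_end / dt)
  y <- y0
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# closed-form logistic growth from n0 active cells
logistic_closed_form <- function(t, n0, k0, N) {
  N * n0 * exp(k0 * t) / (N + n0 * (exp(k0 * t) - 1))
}

# linear protein kinetics driven by a constant active-cell count, solved by
# matrix exponential of the augmented (pn, pf, 1) system; valid when
# pn + pf << M so the degradation term is linear with rate gamma / M
linear_protein_oracle <- function(t, nA, g, km, gamma, M) {
  d <- gamma / M
  A <- rbind(c(-(km + d), 0, g * nA),
             c(km, -d, 0),
             c(0, 0, 0))
  vapply(t, function(ti) {
    as.numeric(Matrix::expm(A * ti) %*% c(0, 0, 1))[1:2]
  }, numeric(2))
}

default_curve_grid <- function(t_end = 16, dt = 1 / 6) seq(0, t_end, by = dt)
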