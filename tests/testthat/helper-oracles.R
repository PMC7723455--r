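# Independent numerical oracles for the DIPSHIFT engine. They integrate the
# instantaneous MAS-modulated dipolar frequency numerically instead of using
# the closed-form phase, so they share no code path with the implementation
# under test.

# adaptive-quadrature phase for one (d_eff, beta, gamma, t1)
oracle_phase <- function(d_eff, beta, gamma, t1, nu_r) {
  omega <- function(t) {
    wr <- 2 * pi * nu_r
    2 * pi * d_eff * ((sqrt(2) / 2) * sin(2 * beta) * cos(wr * t + gamma) -
                        0.5 * sin(beta)^2 * cos(2 * wr * t + 2 * gamma))
  }
  if (t1 == 0) return(0)
  stats::integrate(omega, 0, t1, rel.tol = 1e-11, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

# brute-force powder curve: fine independent orientation grid, phase by
# cumulative trapezoid on a fine time grid (t1 points must divide the grid)
oracle_curve <- function(d_eff, t1_grid, nu_r, n_beta = 96, n_gamma = 48,
                         n_time = 2001) {
  tau_r <- 1 / nu_r
  tt <- seq(0, tau_r, length.out = n_time)
  beta <- (seq_len(n_beta) - 0.5) * pi / n_beta
  gam <- (seq_len(n_gamma) - 0.5) * 2 * pi / n_gamma
  w_beta <- sin(beta) / sum(sin(beta)) / n_gamma
  wr <- 2 * pi * nu_r
  acc <- numeric(length(t1_grid))
  idx <- vapply(t1_grid, function(x) which.min(abs(tt - x)), integer(1))
  stopifnot(max(abs(tt[idx] - t1_grid)) < 1e-12)
  for (b in seq_along(beta)) {
    c1 <- (sqrt(2) / 2) * sin(2 * beta[b])
    c2 <- -0.5 * sin(beta[b])^2
    for (g in gam) {
      om <- 2 * pi * d_eff * (c1 * cos(wr * tt + g) + c2 * cos(2 * wr * tt + 2 * g))
      ph <- pracma::cumtrapz(tt, om)
      acc <- acc + w_beta[b] * cos(ph[idx])
    }
  }
  acc
}
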