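test_that("closed-form dipolar phase matches adaptive quadrature", {
  set.seed(42)
  n <- 200
  d <- runif(n, 0, 25000)
  b <- runif(n, 0, pi)
  g <- runif(n, 0, 2 * pi)
  t1 <- runif(n, 0, 2e-4)
  err <- vapply(seq_len(n), function(i) {
    abs(dipolar_phase(d[i], b[i], g[i], t1[i], 5000) -
          oracle_phase(d[i], b[i], g[i], t1[i], 5000))
  }, numeric(1))
  expect_lt(max(err), 1e-6)
})

test_that("phase vanishes at t1 = 0 and refocuses at the full rotor period", {
  set.seed(7)
  for (i in 1:20) {
    b <- runif(1, 0, pi); g <- runif(1, 0, 2 * pi); d <- runif(1, 0, 3e4)
    expect_equal(dipolar_phase(d, b, g, 0, 5000), 0)
    expect_equal(dipolar_phase(d, b, g, 1 / 5000, 5000), 0, tolerance = 1e-10)
  }
  expect_equal(dipolar_phase(0, 1, 1, 1e-4, 5000), 0)
  expect_error(dipolar_phase(1000, 1, 1, 3e-4, 5000), "rotor period")
})

test_that("worked mid-rotor phase value agrees with quadrature", {
  got <- dipolar_phase(5000, pi / 4, 0, 1e-4, 5000)
  expect_equal(got, oracle_phase(5000, pi / 4, 0, 1e-4, 5000),
               tolerance = 1e-8)
})

test_that("dephasing curve refocuses, is symmetric and starts at 1", {
  for (S in c(0.2, 0.85)) {
    cv <- dephasing_curve(effective_coupling(S, fix_pair, fix_scale),
                          fix_mas9, fix_powder)
    n <- length(cv$intensity)
    expect_equal(cv$intensity[1], 1, tolerance = 1e-6)
    expect_equal(cv$intensity[n], 1, tolerance = 1e-6)
    # gamma-averaged curve is invariant under t1 -> tau_r - t1
    expect_lt(max(abs(cv$intensity - rev(cv$intensity))), 1e-6)
  }
})

test_that("zero coupling gives a flat curve of ones", {
  cv <- dephasing_curve(0, fix_mas9, fix_powder)
  expect_equal(cv$intensity, rep(1, 9))
  expect_equal(dephasing_depth(cv), 0)
})

test_that("powder-averaged curve matches the brute-force orientation oracle", {
  t1 <- fix_mas9$t1_grid
  got <- fix_sim9(10000)
  ref <- oracle_curve(10000, t1, 5000)
  expect_lt(max(abs(got - ref)), 1e-3)
})

test_that("the powder curve is independent of the rotor phase origin", {
  # shifting the rotor phase zero shifts gamma coherently in both harmonics;
  # the gamma-averaged curve must not move
  for (phi0 in c(0.37, 1.9)) {
    shifted <- fix_powder
    shifted$gamma <- (shifted$gamma + phi0) %% (2 * pi)
    sim_shift <- dipshift_simulator(fix_mas9, shifted)
    for (d in c(2000, 8000, 12500)) {
      expect_lt(max(abs(fix_sim9(d) - sim_shift(d))), 1e-9)
    }
  }
})

test_that("cos and sin harmonic conventions agree at moderate dephasing", {
  # the literal cos->sin swap flips the relative phase of the two rotor
  # harmonics and is only an approximate symmetry, exact through 4th order
  # in the dephasing angle; at d_eff <= 0.6 nu_r the residual is tiny
  mas5 <- mas_condition(5000, 5)
  sim_cos <- dipshift_simulator(mas5, fix_powder, convention = "cos")
  sim_sin <- dipshift_simulator(mas5, fix_powder, convention = "sin")
  for (d in c(1000, 3000)) {
    expect_lt(max(abs(sim_cos(d) - sim_sin(d))), 1e-4)
  }
})

test_that("headgroup-mobility regime dephases less than 1 percent", {
  # S < 0.04 at 5 kHz MAS: the criterion that lets mobile lipid headgroup
  # signals be neglected in the backbone analysis
  d_eff <- effective_coupling(0.04, fix_pair, fix_scale)
  cv <- dephasing_curve(d_eff, mas_condition(5000, 65), fix_powder)
  expect_lt(dephasing_depth(cv), 0.01)
  expect_gte(min(cv$intensity), 0.99)
})

test_that("dephasing depth grows monotonically with the coupling", {
  # verified oracle scan over d_eff/nu_r in [0, 1]
  d_grid <- seq(0, 5000, by = 250)
  mas_fine <- mas_condition(5000, 33)
  sim <- dipshift_simulator(mas_fine, fix_powder)
  depth <- vapply(d_grid, function(d) 1 - min(sim(d)), numeric(1))
  expect_true(all(diff(depth) >= -1e-9))
  expect_equal(depth[1], 0)
})

test_that("powder convergence check flags a too-coarse scheme", {
  coarse <- powder_scheme(4, 4)
  expect_warning(
    dephasing_curve(15000, fix_mas9, coarse, check_convergence = TRUE),
    "not converged")
  expect_silent(
    dephasing_curve(8000, fix_mas9, fix_powder, check_convergence = TRUE))
})

test_that("mas_condition and powder_scheme validate their invariants", {
  expect_error(mas_condition(-5000), "positive")
  expect_error(mas_condition(5000, t1_grid = c(0, 3e-4)), "rotor period")
  expect_error(mas_condition(5000, t1_grid = c(1e-5, 2e-5)), "start at 0")
  expect_error(mas_condition(5000, t1_grid = c(0, 2e-5, 1e-5)), "ascending")
  m7 <- mas_condition(5000, 7)
  expect_length(m7$t1_grid, 7)
  expect_equal(m7$t1_grid[7], m7$tau_r)
  pw <- powder_scheme(16, 8)
  expect_equal(sum(pw$weight), 1, tolerance = 1e-12)
  expect_true(all(pw$beta >= 0 & pw$beta <= pi))
  expect_true(all(pw$gamma >= 0 & pw$gamma < 2 * pi))
})
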