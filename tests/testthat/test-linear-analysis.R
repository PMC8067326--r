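# Closed-form stability results and the finite-difference growth-rate oracle.

test_that("dispersion relation has the analytic values and sign structure", {
  expect_equal(dispersion_rate(1, 1), 0)
  expect_equal(dispersion_rate(1 / sqrt(2), 1), 0.125)
  expect_equal(dispersion_rate(2, 1), -6)
  expect_equal(dispersion_rate(0, 1), 0)
  ks <- seq(0.05, 3, by = 0.05)
  for (gamma in c(0.5, 1, 2)) {
    om <- dispersion_rate(ks, gamma)
    kc <- critical_wavenumber(gamma)
    expect_true(all(om[ks < kc] > 0))
    expect_true(all(om[ks > kc] < 0))
  }
})

test_that("critical wavenumber is 1/sqrt(gamma)", {
  expect_equal(critical_wavenumber(1), 1)
  expect_equal(critical_wavenumber(4), 0.5)
  expect_equal(critical_wavenumber(0.25), 2)
})

test_that("equilibrium profile is the odd tanh interface", {
  expect_equal(equilibrium_profile(0, 1), 0)
  expect_equal(equilibrium_profile(sqrt(2), 1), tanh(1))
  expect_equal(equilibrium_profile(50, 1), 1, tolerance = 1e-12)
  x <- seq(-3, 3, by = 0.5)
  expect_equal(equilibrium_profile(-x, 2), -equilibrium_profile(x, 2))
})

test_that("interface energy closed form and scaling", {
  expect_equal(interface_energy(1), 2 * sqrt(2) / 3)
  expect_equal(interface_energy(2), 4 / 3)
  expect_equal(interface_energy(4) / interface_energy(1), 2)
  # quadrature oracle: dense trapezoid of f + (gamma/2) psi'^2 on the profile
  x <- seq(-30, 30, by = 1e-3)
  for (gamma in c(1, 2)) {
    prof <- equilibrium_profile(x, gamma)
    dens <- bulk_energy_density(prof) +
      (gamma / 2) * (1 - prof^2)^2 / (2 * gamma)
    quad <- sum((dens[-1] + dens[-length(dens)]) / 2) * 1e-3
    expect_equal(quad, interface_energy(gamma), tolerance = 1e-6)
  }
})

test_that("measured growth rates agree with the dispersion relation", {
  expect_equal(measure_growth_rate_1d(0.5), dispersion_rate(0.5),
               tolerance = 0.05)
  expect_lt(measure_growth_rate_1d(1.5), 0)
  expect_lt(abs(measure_growth_rate_1d(1.0)), 0.01)
})

test_that("oracle enforces its linear-regime preconditions", {
  expect_error(measure_growth_rate_1d(0.5, amplitude = 0.1), "amplitude")
  expect_error(measure_growth_rate_1d(1.5, dt = 0.05), "dt too large")
})

test_that("stationary tanh interface is unchanged by relaxation", {
  d <- line_domain(-10, 10, 401L)
  psi0 <- equilibrium_profile(d$nodes[, 1L], 1)
  st <- ch_state(0L, 0, psi0, chmito:::project_mu(d, psi0, 1))
  cfg <- solver_config(dt = 1e-3)
  for (i in 1:500) st <- theta_step(d, st, cfg)
  expect_lt(l2_norm(d, st$psi - psi0), 1e-4)
})

test_that("only the homogeneous mixture is destabilized by a long-wave mode", {
  res <- uniform_state_stability(n_steps = 2000L, dt = 5e-3,
                                 growth_threshold = 2)
  expect_equal(res$base[res$unstable], 0)
  expect_true(all(res$growth_factor[res$base != 0] < 1))
})
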