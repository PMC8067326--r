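# Theta-method solver: stationary states, symmetry, conservation, granule
# pinning, linear-regime agreement with the independent oracle.

test_that("random initialization is seeded, bounded and validates its range", {
  d <- small_disk()
  expect_identical(initialize_random(d, 0, 0.5, seed = 5),
                   initialize_random(d, 0, 0.5, seed = 5))
  expect_false(identical(initialize_random(d, 0, 0.5, seed = 5),
                         initialize_random(d, 0, 0.5, seed = 6)))
  psi <- initialize_random(d, 0.3, 0, seed = 1)
  expect_true(all(psi == 0.3))
  expect_error(initialize_random(d, 0.5, 0.6, seed = 1), "double-well")
  # sample mean within 4 standard errors of the requested mean
  n <- nrow(d$nodes)
  psi <- initialize_random(d, 0, 0.05, seed = 2)
  expect_lt(abs(mean(psi)), 4 * 0.05 / sqrt(3 * n))
  # granule nodes are overwritten with the pinned value
  dg <- granule_disk()
  pg <- initialize_random(dg, 0, 0.5, seed = 1)
  expect_equal(granule_constraint_residual(dg, pg), 0)
})

test_that("uniform states psi = -1, 0, +1 are stationary", {
  d <- small_disk()
  cfg <- solver_config(dt = 1e-3)
  for (u in c(-1, 0, 1)) {
    psi <- rep(u, nrow(d$nodes))
    st <- ch_state(0L, 0, psi, chmito:::project_mu(d, psi, cfg$gamma))
    st <- theta_step(d, st, cfg)
    expect_lt(max(abs(st$psi - psi)), 1e-12)
  }
})

test_that("granule-free trajectories of psi0 and -psi0 are exact negations", {
  d <- small_disk()
  cfg <- solver_config(dt = 1e-3)
  psi0 <- initialize_random(d, 0, 1, seed = 9)
  sa <- ch_state(0L, 0, psi0, chmito:::project_mu(d, psi0, 1))
  sb <- ch_state(0L, 0, -psi0, chmito:::project_mu(d, -psi0, 1))
  for (i in 1:5) {
    sa <- theta_step(d, sa, cfg)
    sb <- theta_step(d, sb, cfg)
  }
  expect_lt(max(abs(sa$psi + sb$psi)), 1e-8)
})

test_that("mass is conserved and energy decays on a granule-free run", {
  d <- small_disk()
  cfg <- solver_config(dt = 1e-3, record_every = 20L)
  psi0 <- initialize_random(d, 0, 1, seed = 4)
  run <- run_simulation(d, psi0, cfg, 100L, spectral_length = FALSE)
  r <- run$records
  expect_lt(max(abs(r$mass - r$mass[1])) / domain_measure(d), 1e-8)
  expect_true(all(diff(r$F_total) <= 1e-10))
  expect_true(all(r$dissipation <= 0))
  expect_lt(max(abs(run$state$psi)), 1.05)
})

test_that("run_simulation records at step 0 and every record_every steps", {
  d <- small_disk()
  cfg <- solver_config(dt = 1e-3, record_every = 250L)
  psi0 <- initialize_random(d, 0, 1, seed = 1)
  run <- run_simulation(d, psi0, cfg, 1000L, spectral_length = FALSE)
  expect_equal(run$records$step, c(0L, 250L, 500L, 750L, 1000L))
  expect_equal(run$records$time, run$records$step * cfg$dt)
})

test_that("granule pinning is exact after stepping and monitored by the residual", {
  d <- granule_disk()
  cfg <- solver_config(dt = 1e-3)
  psi0 <- initialize_random(d, 0, 0.5, seed = 2)
  st <- ch_state(0L, 0, psi0, chmito:::project_mu(d, psi0, 1))
  st <- theta_step(d, st, cfg)
  expect_equal(granule_constraint_residual(d, st$psi), 0)
  sd <- small_disk()
  expect_error(granule_constraint_residual(sd, rep(0, nrow(sd$nodes))),
               "no granules")
  # pre-projection random field obeys the trivial bound |psi - C| <= 1 + amp
  raw <- runif(nrow(d$nodes), -0.05, 0.05)
  expect_lte(granule_constraint_residual(d, raw), 1.05)
})

test_that("solver growth rates match the dispersion relation in the linear regime", {
  for (k in c(0.5, 1.2)) {
    r <- fem_growth_rate(k)
    expect_lt(abs(r - dispersion_rate(k)) / abs(dispersion_rate(k)), 0.05)
  }
})

test_that("Newton failure reports the residual and the step", {
  d <- small_disk()
  cfg <- solver_config(dt = 50, newton_max_iter = 2L)
  psi0 <- initialize_random(d, 0, 1, seed = 8)
  st <- ch_state(0L, 0, psi0, chmito:::project_mu(d, psi0, 1))
  expect_error(theta_step(d, st, cfg), "Newton did not converge")
})
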