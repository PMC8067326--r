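# Morphometrics: phase fractions, interface extraction, components,
# spectral characteristic length, granule halos.

test_that("phase fractions of uniform and symmetric fields", {
  d <- small_disk()
  n <- nrow(d$nodes)
  expect_equal(unname(phase_fractions(d, rep(1, n))), c(1, 0))
  expect_equal(unname(phase_fractions(d, rep(-1, n))), c(0, 1))
  # half-plane interface through the center: 50/50 within 1%
  psi <- equilibrium_profile(d$nodes[, 1L], 1)
  pf <- phase_fractions(d, psi)
  expect_equal(unname(pf[1]), 0.5, tolerance = 0.01)
  expect_equal(unname(pf[2]), 0.5, tolerance = 0.01)
})

test_that("phase fractions partition the domain to near machine precision", {
  d <- medium_disk()
  for (seed in 1:3) {
    psi <- initialize_random(d, 0, 1, seed = seed)
    pf <- phase_fractions(d, psi)
    expect_true(all(pf >= 0))
    expect_lt(abs(sum(pf) - 1), 1e-9)
  }
  # thresholded fractions respect the circular geometry of a radial interface
  f <- make_fixture("circular_interface", list(radius = 3, r0 = 1.5, h = 0.1))
  pf <- phase_fractions(f$domain, f$psi)
  expect_equal(unname(pf[1]), 1.5^2 / 9, tolerance = 0.01)
})

test_that("interface measure recovers constructed level-set geometries", {
  # uniform field: no crossing
  d <- small_disk()
  expect_equal(interface_measure(d, rep(0.7, nrow(d$nodes))), 0)
  # straight interface across a strip of height 1
  f <- make_fixture("tanh_strip", list(length = 16, h = 0.1))
  expect_equal(interface_measure(f$domain, f$psi), 1, tolerance = 1e-6)
  # concentric circle of radius 1.5: 2 pi r within 2%
  fc <- make_fixture("circular_interface", list(radius = 3, r0 = 1.5, h = 0.1))
  expect_equal(interface_measure(fc$domain, fc$psi), 3 * pi, tolerance = 0.02)
})

test_that("interface measure converges first order on the circle fixture", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) {
    f <- make_fixture("circular_interface", list(radius = 3, r0 = 1.5, h = h))
    abs(interface_measure(f$domain, f$psi) - 3 * pi)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 4)
})

test_that("component counting uses facet adjacency on the requested phase", {
  d <- small_disk()
  n <- nrow(d$nodes)
  expect_equal(count_phase_components(d, rep(-1, n), "membrane"), 1L)
  expect_equal(count_phase_components(d, rep(1, n), "membrane"), 0L)
  expect_equal(count_phase_components(d, rep(1, n), "matrix"), 1L)
  f <- make_fixture("two_blobs")
  expect_equal(count_phase_components(f$domain, f$psi, "membrane"), 2L)
  expect_equal(count_phase_components(f$domain, f$psi, "matrix"), 1L)
})

test_that("characteristic length recovers a single-mode wavelength", {
  f <- make_fixture("sinusoid_mode", list(k = 2))
  g <- resample_to_grid(f$domain, f$psi)
  expect_equal(characteristic_length(g), 2 * pi / 2, tolerance = 0.05)
  f2 <- make_fixture("sinusoid_mode", list(k = 1, n_periods = 3L, h = 0.2))
  expect_equal(characteristic_length(resample_to_grid(f2$domain, f2$psi)),
               2 * pi, tolerance = 0.05)
})

test_that("characteristic length is undefined for uniform fields", {
  f <- make_fixture("sinusoid_mode", list(k = 2))
  u <- rep(0.25, nrow(f$domain$nodes))
  expect_error(characteristic_length(resample_to_grid(f$domain, u)),
               "spectrally flat")
})

test_that("granule halo statistics", {
  d <- granule_disk()
  n <- nrow(d$nodes)
  expect_equal(granule_halo_mean(d, rep(0.7, n), 1, 0.5), 0.7, tolerance = 1e-12)
  # initial random field: halo mean within 4 standard errors of 0, excluding
  # the pinned surface nodes (drop them by probing the raw noise field)
  raw <- local({
    set.seed(31)
    runif(n, -0.05, 0.05)
  })
  hr <- granule_halo_report(d, raw, 1, 0.5)
  n_shell <- 2 * pi * 1 * 0.5 / (0.2^2 / 2)   # rough element count in the shell
  expect_lt(abs(hr$mean), 4 * 0.05 / sqrt(3 * n_shell / 10))
  # thinner than the closest element centroid of this fixed mesh
  expect_error(granule_halo_mean(d, raw, 1, 0.001), "empty halo")
  expect_error(granule_halo_mean(d, raw, 2, 0.5), "no granule")
})

test_that("morphometry report bundles the metrics consistently", {
  d <- granule_disk()
  psi <- initialize_random(d, 0, 1, seed = 6)
  rep_ <- morphometry_report(d, psi, spectral = FALSE)
  expect_lt(abs(rep_$matrix_fraction + rep_$membrane_fraction - 1), 1e-9)
  expect_gt(rep_$interface_measure, 0)
  expect_equal(rep_$granule_halos[[1]]$mean,
               granule_halo_mean(d, psi, 1, 0.5))
})
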