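# Energy, mass and dissipation functionals.

test_that("bulk density is the symmetric double well", {
  expect_equal(bulk_energy_density(1), 0)
  expect_equal(bulk_energy_density(-1), 0)
  expect_equal(bulk_energy_density(0), 0.25)
  expect_equal(bulk_energy_density(0.5), 0.140625)
  x <- seq(-1.2, 1.2, by = 0.1)
  expect_equal(bulk_energy_density(x), bulk_energy_density(-x))
  expect_true(all(bulk_energy_density(x) >= 0))
})

test_that("free energy of uniform fields comes from the bulk term alone", {
  d <- small_disk()
  n <- nrow(d$nodes)
  for (u in c(1, -1)) {
    en <- total_free_energy(d, rep(u, n), gamma = 1)
    expect_equal(en$total, 0, tolerance = 1e-14)
  }
  en0 <- total_free_energy(d, rep(0, n), gamma = 1)
  expect_equal(en0$gradient_part, 0, tolerance = 1e-14)
  expect_equal(en0$total, 0.25 * domain_measure(d), tolerance = 1e-12)
  expect_equal(en0$total, en0$bulk_part + en0$gradient_part)
})

test_that("energy is even under the phase swap psi -> -psi", {
  d <- small_disk()
  psi <- initialize_random(d, 0, 0.8, seed = 11)
  e1 <- total_free_energy(d, psi, gamma = 1.3)
  e2 <- total_free_energy(d, -psi, gamma = 1.3)
  expect_identical(e1$bulk_part, e2$bulk_part)
  expect_identical(e1$gradient_part, e2$gradient_part)
})

test_that("total mass integrates the field exactly for linear fields", {
  d <- small_disk()
  n <- nrow(d$nodes)
  expect_equal(total_mass(d, rep(1, n)), domain_measure(d), tolerance = 1e-12)
  expect_equal(total_mass(d, rep(0, n)), 0)
  # odd field on a centered disk integrates to zero
  expect_lt(abs(total_mass(d, d$nodes[, 1L])), 1e-10)
})

test_that("dissipation diagnostic is -int |grad mu|^2", {
  sq <- cached("unit_square", rect_domain(1, 1, h_target = 0.1))
  # mu = x has |grad mu|^2 = 1 on the unit square
  expect_equal(dissipation_rate(sq, sq$nodes[, 1L]), -1, tolerance = 1e-12)
  expect_equal(dissipation_rate(sq, rep(2, nrow(sq$nodes))), 0)
  psi <- initialize_random(sq, 0, 1, seed = 3)
  expect_lte(dissipation_rate(sq, psi), 0)
})

test_that("vectorized quadrature agrees with a naive per-element loop", {
  # independent brute-force evaluation of the same quadrature definition:
  # plain loops, own measure/gradient formulas, base solve()
  d <- cached("tiny_rect", rect_domain(1, 1, h_target = 0.25))
  set.seed(42)
  psi <- runif(nrow(d$nodes), -1, 1)
  gamma <- 1.7
  bulk <- 0; grad <- 0; mass <- 0
  for (e in seq_len(nrow(d$elements))) {
    v <- d$elements[e, ]
    p <- d$nodes[v, ]
    area <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    vals <- psi[v]
    # gradient of the linear interpolant: solve the plane equation
    A <- cbind(1, p)
    coefs <- solve(A, vals)
    grad <- grad + 0.5 * gamma * area * sum(coefs[2:3]^2)
    # edge-midpoint rule for the quartic bulk term
    mids <- c(mean(vals[1:2]), mean(vals[2:3]), mean(vals[c(3, 1)]))
    bulk <- bulk + area * mean(0.25 * (mids^2 - 1)^2)
    mass <- mass + area * mean(vals)
  }
  en <- total_free_energy(d, psi, gamma)
  expect_equal(en$bulk_part, bulk, tolerance = 1e-12)
  expect_equal(en$gradient_part, grad, tolerance = 1e-12)
  expect_equal(total_mass(d, psi), mass, tolerance = 1e-12)
})

test_that("a sampled equilibrium interface carries the closed-form excess energy", {
  for (gamma in c(1, 2)) {
    d <- line_domain(-10, 10, 401L)
    psi <- equilibrium_profile(d$nodes[, 1L], gamma)
    en <- total_free_energy(d, psi, gamma)
    expect_equal(en$total, interface_energy(gamma), tolerance = 5e-3)
  }
})

test_that("field functionals reject mismatched domains", {
  d <- small_disk()
  expect_error(total_free_energy(d, rep(0, 3), 1), "nodes")
  expect_error(total_mass(d, rep(0, 3)), "nodes")
  expect_error(dissipation_rate(d, rep(0, 3)), "nodes")
})
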