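# Shared meshes and helpers, built once per test session.

.mesh_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.mesh_cache[[key]])) .mesh_cache[[key]] <- force(expr)
  .mesh_cache[[key]]
}

small_disk <- function() cached("small_disk", build_domain("disk", 2, h_target = 0.25))
medium_disk <- function() cached("medium_disk", build_domain("disk", 3, h_target = 0.15))
granule_disk <- function() cached("granule_disk", build_domain(
  "disk", 5, list(granule(c(2.5, 2.5), 1, 1)), h_target = 0.2))

# measure the growth rate of a single k-mode under the finite-element solver
# on a periodic 1D mesh (log-linear fit, transient excluded); used to compare
# the solver against the independent finite-difference oracle
fem_growth_rate <- function(k, gamma = 1, amplitude = 1e-4, n_steps = 400L,
                            dt = 1e-3, h = 0.1) {
  L <- 2 * pi / k
  n <- max(48L, as.integer(ceiling(L / h)))
  d <- periodic_interval_domain(L, n)
  x <- d$nodes[, 1L]
  psi <- amplitude * sin(k * x)
  st <- ch_state(0L, 0, psi, chmito:::project_mu(d, psi, gamma))
  cfg <- solver_config(gamma = gamma, dt = dt)
  amps <- numeric(n_steps + 1L)
  amps[1L] <- chmito:::mode_amplitude(psi, k, x)
  for (s in seq_len(n_steps)) {
    st <- theta_step(d, st, cfg)
    amps[s + 1L] <- chmito:::mode_amplitude(st$psi, k, x)
  }
  tt <- (10:n_steps) * dt
  stats::coef(stats::lm(log(amps[11:(n_steps + 1L)]) ~ tt))[[2L]]
}

# L2 norm of a nodal field through the consistent mass matrix
l2_norm <- function(d, v) {
  M <- chmito:::fem_matrices(d)$M
  sqrt(max(as.numeric(v %*% (M %*% v)), 0))
}
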