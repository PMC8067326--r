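# Time integration of the Cahn-Hilliard system in the mixed two-field form:
# unknowns (psi, mu) on the P1 space, theta-method in time, full Newton on the
# coupled nonlinear system each step. Outer boundaries carry natural zero-flux
# conditions on both fields; granule boundaries pin psi to the granule value C
# (row elimination) while mu keeps its natural zero-flux condition.
#
# Weak form solved per step (M = mass matrix, K = stiffness, mob = mobility):
#   (psi^{n+1} - psi^n)/dt tested against u  +  mob * a(mu_{n+theta}, u) = 0
#   (mu^{n+1}, v) - (f'(psi^{n+1}), v) - gamma * a(psi^{n+1}, v) = 0
# with mu_{n+theta} = (1 - theta) mu^{n+1} + theta mu^n.

#' Solver configuration
#'
#' Collects every scheme parameter of the mixed theta-method solver.
#'
#' @param gamma Transition-region length parameter (positive). Default 1, the
#'   value used throughout the simulation protocols.
#' @param dt Time step.
#' @param theta Theta-method weight in \code{[0, 1]}; the chemical potential
#'   at the implicit level is weighted by \code{1 - theta}, so
#'   \code{theta = 0.5} is the trapezoidal member and \code{theta = 0} fully
#'   implicit.
#' @param mobility Mobility \code{M} multiplying \code{grad mu} in the flux;
#'   the dimensionless model has \code{J = -(1/2) grad mu}, i.e. 0.5.
#' @param newton_abs_tol,newton_rel_tol,newton_max_iter Newton stopping
#'   controls: iterate until the residual 2-norm falls below
#'   \code{max(abs_tol, rel_tol * initial residual)}.
#' @param seed Integer seed recorded with the run and used by
#'   \code{\link{initialize_random}}.
#' @param record_every Record diagnostics every this many steps.
#' @param init_mean,init_amplitude Defaults for the random initial field.
#' @return An object of class \code{ch_solver_config}.
#' @export
solver_config <- function(gamma = 1, dt = 1e-3, theta = 0.5, mobility = 0.5,
                          newton_abs_tol = 1e-10, newton_rel_tol = 1e-8,
                          newton_max_iter = 25L, seed = 1L,
                          record_every = 250L, init_mean = 0,
                          init_amplitude = 0.05) {
  stopifnot(gamma > 0, dt > 0, mobility > 0,
            newton_abs_tol > 0, newton_rel_tol > 0, newton_max_iter >= 1)
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (record_every < 1) stop("record_every must be a positive integer")
  structure(list(gamma = gamma, dt = dt, theta = theta, mobility = mobility,
                 newton_abs_tol = newton_abs_tol,
                 newton_rel_tol = newton_rel_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 init_mean = init_mean, init_amplitude = init_amplitude),
            class = "ch_solver_config")
}

#' @exportS3Method base::print
print.ch_solver_config <- function(x, ...) {
  cat(sprintf("<ch_solver_config> gamma %g, dt %g, theta %g, mobility %g, seed %d\n",
              x$gamma, x$dt, x$theta, x$mobility, x$seed))
  invisible(x)
}

# pinned psi degrees of freedom (granule-tagged nodes) and their values
pinned_dofs <- function(d) {
  if (!length(d$granules)) return(list(idx = integer(0), val = numeric(0)))
  idx <- which(!is.na(d$node_tag) & d$node_tag > 0L)
  val <- vapply(d$node_tag[idx], function(g) d$granules[[g]]$value, numeric(1))
  list(idx = idx, val = val)
}

#' Random uniform initial field
#'
#' Nodal values i.i.d. uniform on \code{[mean - amplitude, mean + amplitude]},
#' emulating the randomly and uniformly distributed initial mixture of inner
#' membrane and fluid matrix. Granule-tagged nodes are overwritten with their
#' pinned value. Reproducible for a given seed; the caller's RNG state is
#' left untouched.
#'
#' @param d A \code{ch_domain}.
#' @param mean Mean of the initial field; \code{|mean| + amplitude} must not
#'   exceed 1 so the field starts inside the double-well range.
#' @param amplitude Half-width of the uniform noise.
#' @param seed Integer seed.
#' @return Numeric vector of nodal values.
#' @export
initialize_random <- function(d, mean = 0, amplitude = 0.05, seed = 1L) {
  stopifnot(inherits(d, "ch_domain"), amplitude >= 0)
  if (abs(mean) + amplitude > 1) {
    stop("|mean| + amplitude must be <= 1 (outside the double-well range)")
  }
  n <- nrow(d$nodes)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  psi <- stats::runif(n, mean - amplitude, mean + amplitude)
  pd <- pinned_dofs(d)
  if (length(pd$idx)) psi[pd$idx] <- pd$val
  psi
}

# mu consistent with psi through the weak chemical-potential equation:
# (mu, v) = (f'(psi), v) + gamma a(psi, v)
project_mu <- function(d, psi, gamma) {
  fem <- fem_matrices(d)
  rhs <- fem$M %*% dwell_prime(psi) + gamma * (fem$K %*% psi)
  as.numeric(Matrix::solve(fem$M, rhs))
}

#' Simulation state constructor
#'
#' @param step Nonnegative step counter.
#' @param time Physical time (\code{step * dt}).
#' @param psi Nodal order parameter.
#' @param mu Nodal chemical potential.
#' @return An object of class \code{ch_state}.
#' @export
ch_state <- function(step, time, psi, mu) {
  structure(list(step = as.integer(step), time = time, psi = psi, mu = mu),
            class = "ch_state")
}

#' @exportS3Method base::print
print.ch_state <- function(x, ...) {
  cat(sprintf("<ch_state> step %d, t = %g, %d nodes, psi in [%.4g, %.4g]\n",
              x$step, x$time, length(x$psi), min(x$psi), max(x$psi)))
  invisible(x)
}

# precomputed operators for repeated stepping on one domain + config
solver_ops <- function(d, cfg) {
  key <- sprintf("ops_%.17g_%.17g_%.17g_%.17g", cfg$gamma, cfg$dt, cfg$theta,
                 cfg$mobility)
  if (!is.null(d$cache[[key]])) return(d$cache[[key]])
  fem <- fem_matrices(d)
  n <- fem$n
  pd <- pinned_dofs(d)
  free <- setdiff(seq_len(2L * n), pd$idx)
  # constant part of the Jacobian
  Jc <- rbind(
    cbind(fem$M / cfg$dt, cfg$mobility * (1 - cfg$theta) * fem$K),
    cbind(-cfg$gamma * fem$K, fem$M)
  )
  Jc <- methods::as(Jc, "CsparseMatrix")
  ops <- list(fem = fem, n = n, pinned = pd, free = free, Jc = Jc,
              V_i = fem$M_i + n, V_j = fem$M_j, V_base = -fem$M_x)
  d$cache[[key]] <- ops
  ops
}

newton_residual <- function(ops, cfg, psi, mu, psi_n, mu_n) {
  fem <- ops$fem
  r_psi <- as.numeric(fem$M %*% (psi - psi_n)) / cfg$dt +
    cfg$mobility * as.numeric(fem$K %*% ((1 - cfg$theta) * mu + cfg$theta * mu_n))
  r_mu <- as.numeric(fem$M %*% (mu - dwell_prime(psi))) -
    cfg$gamma * as.numeric(fem$K %*% psi)
  c(r_psi, r_mu)
}

#' Advance one theta-method step
#'
#' Solves the coupled weak-form system for \code{(psi, mu)} at the next time
#' level by full Newton iteration (the double-well derivative is treated
#' implicitly). Granule-tagged psi degrees of freedom are eliminated at their
#' pinned values.
#'
#' @param d A \code{ch_domain}.
#' @param s A \code{\link{ch_state}}.
#' @param cfg A \code{\link{solver_config}}.
#' @return The state at \code{step + 1}.
#' @export
theta_step <- function(d, s, cfg) {
  stopifnot(inherits(d, "ch_domain"), inherits(s, "ch_state"),
            inherits(cfg, "ch_solver_config"))
  check_field(d, s$psi, "psi")
  check_field(d, s$mu, "mu")
  ops <- solver_ops(d, cfg)
  n <- ops$n
  psi_n <- s$psi; mu_n <- s$mu
  psi <- psi_n; mu <- mu_n
  if (length(ops$pinned$idx)) psi[ops$pinned$idx] <- ops$pinned$val

  res <- newton_residual(ops, cfg, psi, mu, psi_n, mu_n)[ops$free]
  r0 <- sqrt(sum(res^2))
  tol <- max(cfg$newton_abs_tol, cfg$newton_rel_tol * r0)
  it <- 0L
  while (sqrt(sum(res^2)) > tol) {
    if (it >= cfg$newton_max_iter) {
      stop(sprintf(paste0("Newton did not converge in %d iterations ",
                          "(residual %.3e, step %d -> %d); reduce dt or ",
                          "refine the mesh"),
                   cfg$newton_max_iter, sqrt(sum(res^2)), s$step, s$step + 1L))
    }
    # varying Jacobian block: -(M diag(f''(psi))) in the mu-equation
    V <- Matrix::sparseMatrix(i = ops$V_i, j = ops$V_j,
                              x = ops$V_base * dwell_second(psi)[ops$V_j],
                              dims = c(2L * n, 2L * n))
    J <- ops$Jc + V
    delta <- as.numeric(Matrix::solve(J[ops$free, ops$free], -res))
    full <- numeric(2L * n)
    full[ops$free] <- delta
    psi <- psi + full[seq_len(n)]
    mu <- mu + full[n + seq_len(n)]
    res <- newton_residual(ops, cfg, psi, mu, psi_n, mu_n)[ops$free]
    it <- it + 1L
  }
  ch_state(s$step + 1L, (s$step + 1L) * cfg$dt, psi, mu)
}

#' Maximum violation of the granule pinning constraint
#'
#' @param d A \code{ch_domain} with at least one granule.
#' @param psi Nodal order parameter.
#' @return \code{max |psi - C|} over granule-tagged nodes (0 after a step).
#' @export
granule_constraint_residual <- function(d, psi) {
  stopifnot(inherits(d, "ch_domain"))
  check_field(d, psi, "psi")
  pd <- pinned_dofs(d)
  if (!length(pd$idx)) stop("domain has no granules")
  max(abs(psi[pd$idx] - pd$val))
}

#' Run a simulation and record diagnostics
#'
#' Advances \code{n_steps} theta-method steps from an initial field, recording
#' mass, free energy, dissipation and morphometrics at step 0 and every
#' \code{cfg$record_every} steps. An initial chemical potential consistent
#' with the weak mu-equation is computed by a mass-matrix solve.
#'
#' @param d A \code{ch_domain}.
#' @param initial Nodal initial order parameter (e.g. from
#'   \code{\link{initialize_random}}), or a \code{\link{ch_state}} to resume
#'   from.
#' @param cfg A \code{\link{solver_config}}.
#' @param n_steps Number of steps to advance.
#' @param sinks Optional list of callbacks \code{function(state, domain)}
#'   invoked at every record step (e.g. snapshot writers).
#' @param spectral_length Compute the spectral characteristic length at
#'   record steps (2D default on; costs a grid resampling per record).
#' @param halo_shell_width Shell width for per-granule halo means.
#' @param verbose Emit a structured \code{key=value} log line per record step.
#' @return A list of class \code{ch_run}: \code{records} (data frame),
#'   \code{state} (final \code{ch_state}), \code{domain}, \code{config}.
#' @export
run_simulation <- function(d, initial, cfg, n_steps, sinks = NULL,
                           spectral_length = (d$dim == 2L),
                           halo_shell_width = 0.5, verbose = FALSE) {
  stopifnot(inherits(d, "ch_domain"), inherits(cfg, "ch_solver_config"),
            n_steps >= 1)
  if (inherits(initial, "ch_state")) {
    state <- initial
  } else {
    check_field(d, initial, "initial")
    psi0 <- initial
    pd <- pinned_dofs(d)
    if (length(pd$idx)) psi0[pd$idx] <- pd$val
    state <- ch_state(0L, 0, psi0, project_mu(d, psi0, cfg$gamma))
  }
  records <- list()
  take_record <- function(st) {
    en <- total_free_energy(d, st$psi, cfg$gamma)
    pf <- phase_fractions(d, st$psi)
    cl <- NA_real_
    if (spectral_length && d$dim >= 2L) {
      cl <- tryCatch(
        characteristic_length(resample_to_grid(d, st$psi)),
        error = function(e) NA_real_)
    }
    rec <- data.frame(
      step = st$step, time = st$time,
      mass = total_mass(d, st$psi),
      F_bulk = en$bulk_part, F_grad = en$gradient_part, F_total = en$total,
      dissipation = dissipation_rate(d, st$mu),
      matrix_fraction = pf[["matrix_fraction"]],
      membrane_fraction = pf[["membrane_fraction"]],
      interface_measure = interface_measure(d, st$psi),
      n_membrane_components = count_phase_components(d, st$psi, "membrane"),
      characteristic_length = cl)
    if (length(d$granules)) {
      for (gi in seq_along(d$granules)) {
        rec[[paste0("halo_mean_", gi)]] <-
          granule_halo_mean(d, st$psi, gi, shell_width = halo_shell_width)
      }
    }
    if (verbose) {
      message(sprintf("step=%d time=%.6g mass=%.10g F_total=%.10g dissipation=%.4g",
                      st$step, st$time, rec$mass, rec$F_total, rec$dissipation))
    }
    if (!is.null(sinks)) for (f in sinks) f(st, d)
    rec
  }
  records[[1L]] <- take_record(state)
  target <- state$step + n_steps
  while (state$step < target) {
    state <- tryCatch(theta_step(d, state, cfg), error = function(e) {
      stop(sprintf("simulation failed at step %d: %s", state$step + 1L,
                   conditionMessage(e)))
    })
    if (state$step %% cfg$record_every == 0L || state$step == target) {
      records[[length(records) + 1L]] <- take_record(state)
    }
  }
  records <- do.call(rbind, records)
  records <- records[!duplicated(records$step), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, state = state, domain = d, config = cfg),
            class = "ch_run")
}

#' @exportS3Method base::print
print.ch_run <- function(x, ...) {
  r <- x$records
  cat(sprintf("<ch_run> %d steps on %s domain; %d records\n",
              x$state$step, x$domain$shape, nrow(r)))
  cat(sprintf("  final: mass %.8g, F_total %.8g, matrix fraction %.4f\n",
              r$mass[nrow(r)], r$F_total[nrow(r)], r$matrix_fraction[nrow(r)]))
  invisible(x)
}
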