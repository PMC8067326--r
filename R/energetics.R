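# Field functionals of the phase-field model: double-well bulk density,
# Ginzburg-Landau free energy F = int f(psi) + (gamma/2)|grad psi|^2,
# total mass int psi, and the dissipation diagnostic -int |grad mu|^2.

#' Double-well bulk free-energy density
#'
#' \code{f(psi) = (1/4) (psi^2 - 1)^2}: the free energy per unit volume of the
#' binary membrane/matrix mixture, minimized exactly at the pure phases
#' \code{psi = -1} (inner membrane) and \code{psi = +1} (fluid matrix).
#'
#' @param psi Numeric vector of order-parameter values.
#' @return Nonnegative density values.
#' @examples
#' bulk_energy_density(c(-1, 0, 1))  # 0, 0.25, 0
#' @export
bulk_energy_density <- function(psi) {
  0.25 * (psi^2 - 1)^2
}

dwell_prime <- function(psi) psi^3 - psi
dwell_second <- function(psi) 3 * psi^2 - 1

#' Total Ginzburg-Landau free energy of a phase field
#'
#' Integrates \code{f(psi) + (gamma/2) |grad psi|^2} over the domain. The
#' gradient term is integrated exactly (piecewise-linear gradients are
#' element-wise constant, so it equals \code{(gamma/2) psi' K psi}); the
#' quartic bulk term uses a multi-point quadrature rule (3-point in 2D,
#' 4-point in 3D, 3-point Gauss in 1D) because a one-point rule visibly
#' biases the energy.
#'
#' @param d A \code{ch_domain}.
#' @param psi Nodal order-parameter values.
#' @param gamma Transition-region length parameter (positive).
#' @return An object of class \code{ch_energy}: list with \code{bulk_part},
#'   \code{gradient_part} (nonnegative) and \code{total}.
#' @export
total_free_energy <- function(d, psi, gamma = 1) {
  stopifnot(inherits(d, "ch_domain"), gamma > 0)
  check_field(d, psi, "psi")
  fem <- fem_matrices(d)
  bulk <- quad_integral(d, psi, bulk_energy_density)
  grad <- 0.5 * gamma * as.numeric(psi %*% (fem$K %*% psi))
  structure(list(bulk_part = bulk, gradient_part = max(grad, 0),
                 total = bulk + max(grad, 0)),
            class = "ch_energy")
}

#' @exportS3Method base::print
print.ch_energy <- function(x, ...) {
  cat(sprintf("<ch_energy> total F = %.8g (bulk %.8g + gradient %.8g)\n",
              x$total, x$bulk_part, x$gradient_part))
  invisible(x)
}

#' Total mass of the order parameter
#'
#' The conserved quantity of the dynamics under zero-flux boundaries:
#' \code{int_Omega psi dr}, computed exactly for piecewise-linear fields.
#'
#' @inheritParams total_free_energy
#' @return A scalar.
#' @export
total_mass <- function(d, psi) {
  stopifnot(inherits(d, "ch_domain"))
  check_field(d, psi, "psi")
  fem <- fem_matrices(d)
  sum(as.numeric(fem$M %*% psi))
}

#' Free-energy dissipation rate diagnostic
#'
#' Returns \code{-int |grad mu|^2 dr}, the right-hand side of the energy
#' decay identity \code{dF/dt = -int |grad mu|^2}. Always nonpositive.
#'
#' @param d A \code{ch_domain}.
#' @param mu Nodal chemical-potential values.
#' @return A nonpositive scalar.
#' @export
dissipation_rate <- function(d, mu) {
  stopifnot(inherits(d, "ch_domain"))
  check_field(d, mu, "mu")
  fem <- fem_matrices(d)
  -max(as.numeric(mu %*% (fem$K %*% mu)), 0)
}
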