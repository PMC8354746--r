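#' SPH continuity right-hand side
#'
#' \deqn{\frac{D\rho_i}{Dt} = \sum_j m_j\, (v_i - v_j)\cdot\nabla_i W_{ij}}
#' evaluated for every particle over its kernel-support neighborhood. Pure:
#' returns the rates, does not advance the state.
#'
#' @param system a [particle_system()].
#' @param kernel a [kernel_spec()].
#' @param periodic_x wrap pair displacements in x (analytic channel cases).
#' @return numeric vector of density rates (kg m^-3 s^-1).
#' @export
continuity_rhs <- function(system, kernel, periodic_x = FALSE) {
  stopifnot(inherits(system, "particle_system"), inherits(kernel, "kernel_spec"))
  continuity_rhs_cpp(system$x, system$y, system$vx, system$vy, system$mass,
                     kernel$h, kernel$alpha2d, periodic_x,
                     system$bounds[1], system$bounds[2])
}

#' SPH momentum right-hand side
#'
#' The symmetric-pressure gradient term, the Morris laminar viscous term and
#' the body force:
#' \deqn{\frac{Dv_i}{Dt} = -\sum_j m_j\left(\frac{p_j}{\rho_j^2} +
#'   \frac{p_i}{\rho_i^2}\right)\nabla_i W_{ij}
#'   + \sum_j m_j \frac{\mu_i + \mu_j}{\rho_i \rho_j}\, v_{ij}\,
#'     \frac{1}{r_{ij}} \frac{\partial W_{ij}}{\partial r_{ij}}
#'   + \frac{F}{\rho_i}.}
#' Pressures are taken from \code{system$p}; compute them first with
#' [tait_pressure()]. Coincident particles (r = 0) indicate numerical
#' instability and raise an error.
#'
#' @inheritParams continuity_rhs
#' @param props a [fluid_properties()] (viscosity and body force).
#' @return a list with numeric vectors \code{ax}, \code{ay} (m/s^2).
#' @export
momentum_rhs <- function(system, props, kernel, periodic_x = FALSE) {
  stopifnot(inherits(system, "particle_system"),
            inherits(props, "fluid_properties"),
            inherits(kernel, "kernel_spec"))
  momentum_rhs_cpp(system$x, system$y, system$vx, system$vy,
                   system$rho, system$p, system$mass,
                   props$mu, kernel$h, kernel$alpha2d,
                   props$body_force[1], props$body_force[2],
                   periodic_x, system$bounds[1], system$bounds[2])
}

#' Density reinitialization filter
#'
#' The weakly compressible solver ties pressure directly to density, so
#' density noise becomes pressure noise. This filter pulls each density
#' toward its kernel-weighted neighborhood:
#' \deqn{\tilde\rho_i = \rho_i - \varepsilon \sum_j
#'   \frac{m_j (\rho_i - \rho_j) W_{ij}}{0.5(\rho_i + \rho_j)}}
#' with \eqn{\varepsilon = 0.01} by default. \code{epsilon = 0} is the
#' identity map; a uniform density field is left unchanged.
#'
#' @inheritParams continuity_rhs
#' @param epsilon filter strength in \[0, 1).
#' @return corrected density vector (kg/m^3).
#' @export
smooth_density <- function(system, kernel, epsilon = 0.01, periodic_x = FALSE) {
  stopifnot(inherits(system, "particle_system"), inherits(kernel, "kernel_spec"),
            is.numeric(epsilon), length(epsilon) == 1L,
            epsilon >= 0, epsilon < 1)
  smooth_density_cpp(system$x, system$y, system$rho, system$mass,
                     kernel$h, kernel$alpha2d, epsilon, periodic_x,
                     system$bounds[1], system$bounds[2])
}
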