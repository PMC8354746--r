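#' Fluid properties for the weakly compressible solver
#'
#' Bundles the reference density, dynamic viscosity, artificial speed of
#' sound and Tait exponent, and derives the reference pressure constant
#' \eqn{B = \rho_0 c_s^2 / \gamma}. Weak compressibility requires the speed
#' of sound to be much larger than the flow speed: with
#' \eqn{c_s \ge 10 |v|_{max}} density variations stay within about 1% of
#' \eqn{\rho_0}.
#'
#' @param rho0 reference density (kg/m^3). Default 1000; set 1027 for seawater.
#' @param mu dynamic viscosity (Pa s). Default 1e-3 (water). Scenario
#'   configurations may raise this to an effective viscosity; see the
#'   methods vignette.
#' @param cs reference speed of sound (m/s). Default 10.
#' @param gamma Tait equation-of-state exponent; 7 for water.
#' @param epsilon density-filter strength in \[0, 1); default 0.01.
#' @param body_force body force per unit volume (N/m^3), length-2 vector.
#'   Zero by default; the hydrostatic validation case uses
#'   \code{c(0, -rho0 * 9.81)}.
#' @param p_background constant background pressure (Pa) added to the Tait
#'   pressure inside the integration loop. Leaves pressure gradients (and so
#'   the dynamics) unchanged while keeping the field non-tensile, which
#'   suppresses particle pairing in rarefied wake pockets. Default 0; the
#'   growth scenario uses a few percent of B. Not applied by
#'   [tait_pressure()] or [momentum_rhs()], which evaluate the bare
#'   equations.
#' @return An object of class \code{"fluid_properties"} with the above fields
#'   plus the derived \code{B} (Pa).
#' @examples
#' fp <- fluid_properties()
#' fp$B  # 1000 * 10^2 / 7
#' @export
fluid_properties <- function(rho0 = 1000, mu = 1e-3, cs = 10, gamma = 7,
                             epsilon = 0.01, body_force = c(0, 0),
                             p_background = 0) {
  stopifnot(is.numeric(rho0), length(rho0) == 1L, rho0 > 0,
            is.numeric(mu), length(mu) == 1L, mu >= 0,
            is.numeric(cs), length(cs) == 1L, cs > 0,
            is.numeric(gamma), length(gamma) == 1L, gamma > 0,
            is.numeric(epsilon), length(epsilon) == 1L,
            epsilon >= 0, epsilon < 1,
            is.numeric(body_force), length(body_force) == 2L,
            all(is.finite(body_force)),
            is.numeric(p_background), length(p_background) == 1L,
            p_background >= 0)
  structure(list(rho0 = rho0, mu = mu, cs = cs, gamma = gamma,
                 B = rho0 * cs^2 / gamma, epsilon = epsilon,
                 body_force = as.numeric(body_force),
                 p_background = p_background),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf(paste0("WCSPH fluid: rho0 = %g kg/m^3, mu = %g Pa s, cs = %g m/s,",
                     " gamma = %g, B = %g Pa, epsilon = %g\n"),
              x$rho0, x$mu, x$cs, x$gamma, x$B, x$epsilon))
  invisible(x)
}

#' Tait equation of state
#'
#' \deqn{p = B\left[(\rho/\rho_0)^\gamma - 1\right]}
#' Strictly increasing in density; zero at the reference density.
#'
#' @param rho density (kg/m^3), vectorized. Must be strictly positive: a
#'   non-positive density indicates solver blow-up and raises an error.
#' @param props a [fluid_properties()].
#' @return pressure in Pa.
#' @examples
#' fp <- fluid_properties()
#' tait_pressure(1000, fp)       # 0
#' tait_pressure(1010, fp)       # about 1.03e3 Pa
#' @export
tait_pressure <- function(rho, props) {
  stopifnot(inherits(props, "fluid_properties"))
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho <= 0))
    stop("non-positive or non-finite density: solver blow-up", call. = FALSE)
  props$B * ((rho / props$rho0)^props$gamma - 1)
}

#' Time-step control for the WCSPH integrator
#'
#' The step is the CFL coefficient times the most restrictive of three caps:
#' acoustic (\eqn{h / (c_s + |v|_{max})}), viscous diffusion
#' (\eqn{0.125\, h^2 \rho_{min} / \mu}, the standard explicit-diffusion
#' bound) and body force
#' (\eqn{\sqrt{h / |F/\rho|_{max}}}). Inactive caps (zero viscosity or body
#' force) are infinite.
#'
#' @param system a [particle_system()].
#' @param props a [fluid_properties()].
#' @param kernel a [kernel_spec()].
#' @param cfl_coeff dimensionless CFL coefficient, default 0.25.
#' @return the time step in seconds (positive scalar).
#' @examples
#' # acoustic-limited: 0.25 * 0.065 / (10 + 0.5)
#' @export
compute_dt <- function(system, props, kernel, cfl_coeff = 0.25) {
  stopifnot(inherits(system, "particle_system"),
            inherits(props, "fluid_properties"),
            inherits(kernel, "kernel_spec"),
            cfl_coeff > 0, system$n > 0)
  h <- kernel$h
  vmax <- if (any(system$phase == PHASE["FLUID"])) {
    idx <- system$phase == PHASE["FLUID"]
    max(sqrt(system$vx[idx]^2 + system$vy[idx]^2))
  } else 0
  cap <- h / (props$cs + vmax)
  if (props$mu > 0)
    cap <- min(cap, 0.125 * h^2 * min(system$rho) / props$mu)
  fmag <- sqrt(sum(props$body_force^2))
  if (fmag > 0)
    cap <- min(cap, sqrt(h / (fmag / props$rho0)))
  cfl_coeff * cap
}
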