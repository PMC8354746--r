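#' Boundary-condition flags for the integration loop
#'
#' Describes the velocity prescriptions and open-boundary handling a solver
#' run applies each step: a parabolic inlet band on the left, a constant-
#' velocity lid band at the top, outlet-to-inlet recycling on the right, or
#' x-periodic wrapping (analytic channel cases only). All disabled by
#' default, which gives a closed/free system.
#'
#' @param inlet_width width of the inlet prescription band (m); 0 disables.
#' @param inlet_peak peak (top-of-column) inlet speed (m/s).
#' @param inlet_height water-column height H used by the inlet profile
#'   \eqn{u(y) = u_{peak}(2\eta - \eta^2)}, \eqn{\eta = y/H}: zero at the
#'   seabed, peak at the top.
#' @param lid_y0 fluid particles above this height carry the lid velocity;
#'   \code{Inf} disables the lid.
#' @param lid_speed lid speed (m/s).
#' @param recycle recycle fluid leaving through the right boundary back to
#'   the left with inlet-profile velocity and reference density.
#' @param periodic_x minimal-image periodic wrapping in x.
#' @param enforce_bounds error if a particle strays far outside the domain
#'   (divergence guard).
#' @return a \code{"flow_conditions"} list.
#' @export
flow_conditions <- function(inlet_width = 0, inlet_peak = 0, inlet_height = 1,
                            lid_y0 = Inf, lid_speed = 0, recycle = FALSE,
                            periodic_x = FALSE, enforce_bounds = FALSE) {
  structure(list(inlet_width = inlet_width, inlet_peak = inlet_peak,
                 inlet_height = inlet_height, lid_y0 = lid_y0,
                 lid_speed = lid_speed, recycle = recycle,
                 periodic_x = periodic_x, enforce_bounds = enforce_bounds),
            class = "flow_conditions")
}

#' Advance the particle system in time
#'
#' Runs \code{n_steps} of the WCSPH loop: cell-list rebuild, Tait pressures
#' (boundary pressures floored at zero), continuity and momentum pair sums,
#' step control ([compute_dt()] caps), Verlet integration with an Euler
#' corrector every \code{n_euler} steps, boundary prescriptions/recycling,
#' and the density filter every \code{smooth_every} steps. Boundary-phase
#' particles (wall, live coral, dead coral) never move; their densities and
#' pressures evolve like the fluid's.
#'
#' @param system a [particle_system()].
#' @param props a [fluid_properties()].
#' @param kernel a [kernel_spec()].
#' @param n_steps number of solver steps.
#' @param dt fixed time step (s); \code{NULL} (default) uses adaptive step
#'   control.
#' @param flow a [flow_conditions()].
#' @param cfl CFL coefficient for adaptive stepping.
#' @param n_euler Euler-corrector cadence (steps); prevents velocity/position
#'   decoupling of the Verlet scheme.
#' @param smooth_every density-filter cadence (steps); applied every step by
#'   default.
#' @param damping optional velocity damping rate (1/s) used when settling
#'   static cases; 0 for production runs.
#' @param avg_window number of trailing steps over which per-particle speed
#'   magnitudes are averaged for the returned \code{mean_speed}.
#' @param eps_ts strength of the artificial-stress (tensile instability)
#'   correction: short-range repulsion between particle pairs under
#'   negative pressure, preventing pairing collapse. 0 disables.
#' @param v_clamp per-particle speed cap (m/s), a numerical safeguard for
#'   pocketed colony geometries where trapped fluid can acquire runaway
#'   velocities; \code{Inf} (default) disables. Scenario runs cap at twice
#'   the lid speed.
#' @return a list: \code{system} (advanced [particle_system()]),
#'   \code{ke} (per-step total fluid kinetic energy, J per metre of depth),
#'   \code{mean_speed} (per-particle trailing-window mean speed, m/s),
#'   \code{dt} (last step size, s).
#' @export
advance <- function(system, props, kernel, n_steps, dt = NULL,
                    flow = flow_conditions(), cfl = 0.25, n_euler = 10,
                    smooth_every = 1, damping = 0,
                    avg_window = min(n_steps, 100L), eps_ts = 0.05,
                    v_clamp = Inf) {
  stopifnot(inherits(system, "particle_system"),
            inherits(props, "fluid_properties"),
            inherits(kernel, "kernel_spec"),
            inherits(flow, "flow_conditions"),
            is.numeric(n_steps), n_steps >= 0)
  n_steps <- as.integer(n_steps)
  if (n_steps == 0L)
    return(list(system = system, ke = numeric(0),
                mean_speed = rep(NA_real_, system$n), dt = NA_real_))
  par <- list(h = kernel$h, alpha = kernel$alpha2d,
              rho0 = props$rho0, gamma = props$gamma, B = props$B,
              pb = props$p_background, dx = system$dx,
              eps_ts = eps_ts, v_clamp = v_clamp,
              cs = props$cs, mu = props$mu, eps = props$epsilon,
              smooth_every = as.integer(smooth_every),
              fx = props$body_force[1], fy = props$body_force[2],
              n_steps = n_steps, cfl = cfl,
              dt = if (is.null(dt)) NA_real_ else as.numeric(dt),
              n_euler = as.integer(n_euler), damping = damping,
              xlo = system$bounds[1], xhi = system$bounds[2],
              ylo = system$bounds[3], yhi = system$bounds[4],
              periodic_x = isTRUE(flow$periodic_x),
              recycle = isTRUE(flow$recycle),
              inlet_on = flow$inlet_width > 0,
              inlet_w = flow$inlet_width, inlet_umax = flow$inlet_peak,
              inlet_H = flow$inlet_height,
              lid_on = is.finite(flow$lid_y0),
              lid_y0 = if (is.finite(flow$lid_y0)) flow$lid_y0 else 0,
              lid_u = flow$lid_speed,
              avg_window = as.integer(avg_window),
              enforce_bounds = isTRUE(flow$enforce_bounds))
  out <- advance_cpp(list(x = system$x, y = system$y, vx = system$vx,
                          vy = system$vy, rho = system$rho,
                          phase = system$phase, mass = system$mass), par)
  system$x <- out$x; system$y <- out$y
  system$vx <- out$vx; system$vy <- out$vy
  system$rho <- out$rho; system$p <- out$p
  list(system = system, ke = out$ke, mean_speed = out$mean_speed, dt = out$dt)
}

#' One Verlet step at the R level
#'
#' Thin wrapper over a single iteration of the integration loop with a fixed
#' step, convenient for unit-scale checks (e.g. ballistic motion of a free
#' particle). \code{dt = 0} leaves the state unchanged.
#'
#' @inheritParams advance
#' @param dt fixed time step (s), required.
#' @return as [advance()] with \code{n_steps = 1}.
#' @export
verlet_step <- function(system, props, kernel, dt, flow = flow_conditions(),
                        n_euler = 10) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt >= 0)
  if (dt == 0)
    return(list(system = system, ke = numeric(0),
                mean_speed = rep(NA_real_, system$n), dt = 0))
  advance(system, props, kernel, n_steps = 1L, dt = dt, flow = flow,
          n_euler = n_euler)
}
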