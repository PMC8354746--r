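#' Growth-scenario domain geometry
#'
#' The reef scenario domain: a rectangular water column of \code{width} by
#' \code{height} metres filled with fluid particles on a regular lattice of
#' spacing \code{dx}, a flat seabed of \code{wall_layers} rows of wall
#' particles below y = 0, a hemispherical (half-disc) live-coral seed at the
#' centre of the seabed, a parabolic inlet on the left, an outlet (recycled
#' to the inlet) on the right, and a fast lid current along the top. The
#' defaults are the full-scale scenario: 10 x 5 m at dx = 0.05 m (20 000
#' interior lattice sites) with a 50 cm/s lid.
#'
#' @param width,height domain size (m); must be integer multiples of dx.
#' @param dx initial particle spacing (m).
#' @param wall_layers seabed thickness in particle rows; must cover the
#'   kernel support (>= ceiling(support / dx)).
#' @param lid_speed top-boundary current speed (m/s).
#' @param inlet_peak peak inlet speed (m/s); defaults to \code{lid_speed} so
#'   the inlet parabola is anchored at 0 on the seabed and \code{lid_speed}
#'   at the top of the column.
#' @param seed_radius radius of the half-disc coral seed (m); 0 for no seed.
#' @param lid_rows thickness of the lid prescription band in particle rows.
#' @param inlet_cols width of the inlet prescription band in particle columns.
#' @return a \code{"domain_spec"} list.
#' @export
domain_spec <- function(width = 10, height = 5, dx = 0.05, wall_layers = 3,
                        lid_speed = 0.5, inlet_peak = lid_speed,
                        seed_radius = 0.25, lid_rows = 3, inlet_cols = 3) {
  stopifnot(width > 0, height > 0, dx > 0, wall_layers >= 1, lid_speed > 0,
            inlet_peak >= 0, seed_radius >= 0)
  nx <- width / dx
  ny <- height / dx
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("width and height must be integer multiples of dx", call. = FALSE)
  structure(list(width = width, height = height, dx = dx,
                 wall_layers = as.integer(wall_layers),
                 lid_speed = lid_speed, inlet_peak = inlet_peak,
                 seed_radius = seed_radius,
                 lid_rows = as.integer(lid_rows),
                 inlet_cols = as.integer(inlet_cols)),
            class = "domain_spec")
}

#' Parabolic inlet velocity profile
#'
#' \eqn{u(y) = u_{peak}\,(2\eta - \eta^2)} with \eqn{\eta = y / H} clamped
#' to \[0, 1\]: zero at the seabed (no-slip endpoint), peak at the top of
#' the water column with zero shear.
#'
#' @param y height above the seabed (m), vectorized.
#' @param spec a [domain_spec()].
#' @return inlet x-velocity (m/s).
#' @export
inlet_profile <- function(y, spec) {
  eta <- pmin(pmax(y / spec$height, 0), 1)
  spec$inlet_peak * (2 * eta - eta^2)
}

#' Build the growth-scenario particle system
#'
#' Fluid particles at lattice sites \code{((i - 1/2) dx, (j - 1/2) dx)} fill
#' the interior — exactly \code{(width/dx) * (height/dx)} of them —
#' \code{wall_layers} rows of seabed wall particles sit below y = 0, and
#' lattice sites inside the half-disc of radius \code{seed_radius} centred
#' on the seabed midpoint are converted in place to live coral, keeping the
#' total particle count fixed. Every particle has mass \code{rho0 * dx^2}.
#'
#' @param spec a [domain_spec()].
#' @param props a [fluid_properties()].
#' @param kernel a [kernel_spec()]; used to check that the seabed is thick
#'   enough to cover the kernel support.
#' @return a [particle_system()] with initial velocities already prescribed
#'   by [apply_boundary_conditions()].
#' @export
build_domain <- function(spec, props, kernel = kernel_spec(1.3 * spec$dx)) {
  stopifnot(inherits(spec, "domain_spec"), inherits(props, "fluid_properties"),
            inherits(kernel, "kernel_spec"))
  if (spec$wall_layers < ceiling(kernel$support / spec$dx))
    stop("wall_layers too thin for the kernel support", call. = FALSE)
  if (spec$seed_radius > 0 && spec$seed_radius < spec$dx)
    stop("seed_radius below dx: seed must contain at least one particle",
         call. = FALSE)
  dx <- spec$dx
  nx <- round(spec$width / dx)
  ny <- round(spec$height / dx)
  gx <- (seq_len(nx) - 0.5) * dx
  gy <- (seq_len(ny) - 0.5) * dx
  fx <- rep(gx, times = ny)
  fy <- rep(gy, each = nx)
  wy <- -(seq_len(spec$wall_layers) - 0.5) * dx
  wx <- rep(gx, times = spec$wall_layers)
  wyv <- rep(wy, each = nx)
  x <- c(fx, wx)
  y <- c(fy, wyv)
  phase <- c(rep(PHASE[["FLUID"]], length(fx)),
             rep(PHASE[["WALL"]], length(wx)))
  if (spec$seed_radius > 0) {
    cx <- spec$width / 2
    inseed <- phase == PHASE[["FLUID"]] &
      (x - cx)^2 + y^2 <= spec$seed_radius^2
    phase[inseed] <- PHASE[["LIVE_CORAL"]]
  }
  # start the water column on the inlet profile rather than at rest: the
  # run then begins near the through-flow balance instead of with an
  # impulsive global acceleration transient
  vx0 <- ifelse(phase == PHASE[["FLUID"]], inlet_profile(y, spec), 0)
  ps <- particle_system(x = x, y = y, vx = vx0, vy = 0 * x,
                        rho = props$rho0, mass = props$rho0 * dx^2,
                        phase = phase, dx = dx,
                        bounds = c(0, spec$width, 0, spec$height),
                        check_spacing = FALSE)
  apply_boundary_conditions(ps, spec)
}

#' Prescribe boundary-particle states
#'
#' Sets the inlet band to the parabolic profile, the lid band to the lid
#' velocity, zeroes wall/coral velocities, and recycles any fluid particle
#' past the right boundary back to the left with inlet-profile velocity and
#' reference density. The integration loop applies the same prescriptions
#' internally every step; this function initializes a freshly built system
#' and is exposed for inspection and tests.
#'
#' @param system a [particle_system()] built by [build_domain()].
#' @param spec the [domain_spec()] used to build it.
#' @param rho0 reference density used when recycling (kg/m^3).
#' @return the updated system.
#' @export
apply_boundary_conditions <- function(system, spec, rho0 = 1000) {
  stopifnot(inherits(system, "particle_system"), inherits(spec, "domain_spec"))
  solid <- system$phase != PHASE[["FLUID"]]
  system$vx[solid] <- 0
  system$vy[solid] <- 0
  fluid <- !solid
  out <- fluid & system$x >= spec$width
  if (any(out)) {
    system$x[out] <- system$x[out] - spec$width
    system$vx[out] <- inlet_profile(system$y[out], spec)
    system$vy[out] <- 0
    system$rho[out] <- rho0
  }
  inlet <- fluid & system$x < spec$inlet_cols * spec$dx
  system$vx[inlet] <- inlet_profile(system$y[inlet], spec)
  system$vy[inlet] <- 0
  # the inlet prescription wins where the bands overlap (top-left corner)
  lid <- fluid & !inlet & system$y > spec$height - spec$lid_rows * spec$dx
  system$vx[lid] <- spec$lid_speed
  system$vy[lid] <- 0
  system
}

#' Flow-condition flags matching a scenario domain
#'
#' @param spec a [domain_spec()].
#' @return a [flow_conditions()] with the inlet band, lid band and outlet
#'   recycling of the growth scenario enabled.
#' @export
scenario_flow <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  flow_conditions(inlet_width = spec$inlet_cols * spec$dx,
                  inlet_peak = spec$inlet_peak,
                  inlet_height = spec$height,
                  lid_y0 = spec$height - spec$lid_rows * spec$dx,
                  lid_speed = spec$lid_speed,
                  recycle = TRUE, enforce_bounds = TRUE)
}
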