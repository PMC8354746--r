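#' Body-force-driven laminar channel (plane Poiseuille) validation
#'
#' A channel of height \code{height} periodic in x, no-slip walls top and
#' bottom, driven from rest by a constant horizontal body acceleration
#' \code{g}. The steady analytic profile is
#' \eqn{u(y) = \frac{g}{2\nu} y (H - y)} with peak \eqn{g H^2 / (8\nu)}.
#' The numeric steady profile (per-row mean streamwise velocity) is
#' compared to the analytic one by relative L2 error. This closed-form case
#' is the solver's validation surface: it exercises the continuity and
#' momentum sums, the equation of state, the viscous term and the wall
#' treatment jointly.
#'
#' @param height channel height H (m).
#' @param length channel length (m), periodic direction.
#' @param dx particle spacing (m).
#' @param body_accel driving acceleration g (m/s^2); the body force per
#'   unit volume is \code{rho0 * g}.
#' @param props a [fluid_properties()]; choose \code{cs} at least 10x the
#'   analytic peak speed and a viscosity putting the flow in the laminar
#'   regime.
#' @param t_end integration time (s); default six decay times
#'   \eqn{H^2 / (\pi^2 \nu)} of the slowest transient mode.
#' @param h_over_dx smoothing-length ratio.
#' @return a list of class \code{"analytic_case"}: \code{name},
#'   \code{profile} (data frame y, u_num, u_ana), \code{l2_rel} (relative
#'   L2 error), \code{u_peak_ana}, \code{max_density_dev_pct} (max over
#'   fluid of 100 |rho - rho0| / rho0), \code{system}, \code{params}.
#' @export
poiseuille_case <- function(height = 0.5, length = 1, dx = 0.025,
                            body_accel = 6.4e-3,
                            props = fluid_properties(mu = 5, cs = 0.4),
                            t_end = NULL, h_over_dx = 1.3) {
  nu <- props$mu / props$rho0
  u_peak <- body_accel * height^2 / (8 * nu)
  if (is.null(t_end)) t_end <- 6 * height^2 / (pi^2 * nu)
  kernel <- kernel_spec(h_over_dx * dx)
  props <- fluid_properties(rho0 = props$rho0, mu = props$mu, cs = props$cs,
                            gamma = props$gamma, epsilon = props$epsilon,
                            body_force = c(props$rho0 * body_accel, 0))
  ps <- channel_system(height, length, dx, props, kernel)
  flow <- flow_conditions(periodic_x = TRUE, enforce_bounds = TRUE)
  dt <- compute_dt(ps, props, kernel)
  # fixed step sized for the final speed, so the CFL cap holds throughout
  dt <- dt * props$cs / (props$cs + u_peak)
  n_steps <- as.integer(ceiling(t_end / dt))
  st <- advance(ps, props, kernel, n_steps = n_steps, dt = dt, flow = flow)
  ps <- st$system
  fluid <- ps$phase == PHASE[["FLUID"]]
  row <- round((ps$y[fluid] - dx / 2) / dx)
  u_num <- tapply(ps$vx[fluid], row, mean)
  y_row <- (as.numeric(names(u_num)) + 0.5) * dx
  u_ana <- body_accel / (2 * nu) * y_row * (height - y_row)
  l2 <- sqrt(sum((u_num - u_ana)^2) / sum(u_ana^2))
  dev <- max(abs(ps$rho[fluid] - props$rho0)) / props$rho0 * 100
  structure(list(name = "poiseuille",
                 profile = data.frame(y = y_row, u_num = as.numeric(u_num),
                                      u_ana = u_ana),
                 l2_rel = l2, u_peak_ana = u_peak,
                 max_density_dev_pct = dev, system = ps,
                 params = list(height = height, length = length, dx = dx,
                               body_accel = body_accel, nu = nu,
                               t_end = t_end, n_steps = n_steps, dt = dt)),
            class = "analytic_case")
}

# Periodic channel particle layout: fluid lattice between two banks of wall
# layers.
channel_system <- function(height, length, dx, props, kernel) {
  nx <- round(length / dx)
  ny <- round(height / dx)
  layers <- ceiling(kernel$support / dx)
  gx <- (seq_len(nx) - 0.5) * dx
  fy <- (seq_len(ny) - 0.5) * dx
  wy <- c(-(seq_len(layers) - 0.5) * dx, height + (seq_len(layers) - 0.5) * dx)
  x <- c(rep(gx, times = ny), rep(gx, times = 2 * layers))
  y <- c(rep(fy, each = nx), rep(wy, each = nx))
  phase <- c(rep(PHASE[["FLUID"]], nx * ny), rep(PHASE[["WALL"]], 2 * layers * nx))
  particle_system(x = x, y = y, vx = 0 * x, vy = 0 * x, rho = props$rho0,
                  mass = props$rho0 * dx^2, phase = phase, dx = dx,
                  bounds = c(0, length, -layers * dx, height + layers * dx),
                  check_spacing = FALSE)
}

#' Weak-compressibility channel check
#'
#' Runs the scaled laminar channel (2 x 1 m at dx = 0.025 m by default)
#' with the speed of sound set to exactly 10x the analytic peak speed,
#' integrates to quasi-steady state and reports the maximum relative
#' density deviation over fluid particles as a percentage. Weakly
#' compressible design intent: with \eqn{c_s \ge 10 |v|_{max}} this stays
#' at or below 1%.
#'
#' @param height,length,dx channel geometry (m).
#' @param u_peak target analytic peak speed (m/s).
#' @param mu dynamic viscosity (Pa s).
#' @param rho0 reference density (kg/m^3).
#' @return an \code{"analytic_case"} (see [poiseuille_case()]); the
#'   headline number is \code{max_density_dev_pct}.
#' @export
weak_compressibility_case <- function(height = 1, length = 2, dx = 0.025,
                                      u_peak = 0.05, mu = 5, rho0 = 1000) {
  nu <- mu / rho0
  g <- 8 * nu * u_peak / height^2
  poiseuille_case(height = height, length = length, dx = dx, body_accel = g,
                  props = fluid_properties(rho0 = rho0, mu = mu,
                                           cs = 10 * u_peak))
}

#' Hydrostatic tank validation
#'
#' A closed tank (walls on the bottom and both sides, free surface on top)
#' under gravity, initialized at the analytic hydrostatic density profile
#' and settled with mild velocity damping. Validates the Tait equation of
#' state, the body-force term and the boundary treatment together: the
#' settled pressure at depth d should match \eqn{\rho_0 g d} and the
#' density deviation from \eqn{\rho_0} stays within 1% when
#' \eqn{c_s^2 \ge 100 g d}.
#'
#' @param depth water depth (m).
#' @param width tank width (m).
#' @param dx particle spacing (m).
#' @param g gravitational acceleration (m/s^2).
#' @param cs speed of sound (m/s); default \code{sqrt(200 * g * depth)},
#'   comfortably inside the 1% density band.
#' @param settle_time damped settling time (s).
#' @param rho0 reference density (kg/m^3).
#' @return a list of class \code{"analytic_case"}: \code{p_mid} (kernel-
#'   interpolated pressure at mid-depth, Pa), \code{p_mid_ana}
#'   (\eqn{\rho_0 g d/2}), \code{p_surface} (pressure just below the
#'   surface), \code{max_density_dev_pct}, \code{system}, \code{params}.
#' @export
hydrostatic_case <- function(depth = 0.5, width = 0.5, dx = 0.025, g = 9.81,
                             cs = sqrt(200 * g * depth), settle_time = 3,
                             rho0 = 1000) {
  kernel <- kernel_spec(1.3 * dx)
  props <- fluid_properties(rho0 = rho0, mu = 0.05, cs = cs,
                            body_force = c(0, -rho0 * g))
  layers <- ceiling(kernel$support / dx)
  nx <- round(width / dx)
  ny <- round(depth / dx)
  gx <- (seq_len(nx) - 0.5) * dx
  fy <- (seq_len(ny) - 0.5) * dx
  fx <- rep(gx, times = ny)
  fyv <- rep(fy, each = nx)
  # walls: bottom slab + side columns spanning the full height
  bx <- rep(c(-(seq_len(layers) - 0.5) * dx,
              width + (seq_len(layers) - 0.5) * dx),
            each = ny + layers)
  by <- rep(c(-(seq_len(layers) - 0.5) * dx, fy), times = 2 * layers)
  sx <- rep(gx, times = layers)
  sy <- rep(-(seq_len(layers) - 0.5) * dx, each = nx)
  x <- c(fx, sx, bx)
  y <- c(fyv, sy, by)
  phase <- c(rep(PHASE[["FLUID"]], length(fx)),
             rep(PHASE[["WALL"]], length(sx) + length(bx)))
  # hydrostatic initial densities (walls take the bottom value)
  d <- pmax(depth - y, 0)
  rho <- rho0 * (1 + rho0 * g * d / props$B)^(1 / props$gamma)
  ps <- particle_system(x = x, y = y, vx = 0 * x, vy = 0 * x, rho = rho,
                        mass = rho0 * dx^2, phase = phase, dx = dx,
                        bounds = c(-layers * dx, width + layers * dx,
                                   -layers * dx, depth),
                        check_spacing = FALSE)
  dt <- compute_dt(ps, props, kernel)
  n_steps <- as.integer(ceiling(settle_time / dt))
  st <- advance(ps, props, kernel, n_steps = n_steps, dt = dt,
                flow = flow_conditions(), damping = 5)
  ps <- st$system
  probe_p <- function(pos) {
    fluid <- ps$phase == PHASE[["FLUID"]]
    ddx <- ps$x[fluid] - pos[1]
    ddy <- ps$y[fluid] - pos[2]
    sel <- ddx^2 + ddy^2 < kernel$support^2
    w <- wendland_value(cbind(ddx[sel], ddy[sel]), kernel)
    sum(w * ps$p[fluid][sel]) / sum(w)
  }
  fluid <- ps$phase == PHASE[["FLUID"]]
  structure(list(name = "hydrostatic",
                 p_mid = probe_p(c(width / 2, depth / 2)),
                 p_mid_ana = rho0 * g * depth / 2,
                 p_surface = probe_p(c(width / 2, depth - dx)),
                 max_density_dev_pct = max(abs(ps$rho[fluid] - rho0)) / rho0 * 100,
                 system = ps,
                 params = list(depth = depth, width = width, dx = dx, g = g,
                               cs = cs, settle_time = settle_time,
                               n_steps = n_steps)),
            class = "analytic_case")
}

#' @export
print.analytic_case <- function(x, ...) {
  cat(sprintf("<analytic_case: %s>\n", x$name))
  if (x$name == "poiseuille")
    cat(sprintf("  relative L2 error %.3g, peak u %.4g m/s, max density dev %.3g%%\n",
                x$l2_rel, x$u_peak_ana, x$max_density_dev_pct))
  if (x$name == "hydrostatic")
    cat(sprintf("  p(mid) %.4g Pa (analytic %.4g), max density dev %.3g%%\n",
                x$p_mid, x$p_mid_ana, x$max_density_dev_pct))
  invisible(x)
}

#' Frozen growth-rule fixture
#'
#' A hand-laid arrangement exercising the growth rule without running the
#' solver: one live coral particle and three fluid particles at distances
#' 1.0, 1.4 and 1.6 dx with buffered mean speeds 0.02, 0.045 and
#' 0.07 m/s. The expected conversion set is computed here by direct rule
#' evaluation (band AND proximity applied literally, independent of
#' [growth_event()]'s neighbor-search machinery): at the default band and
#' proximity, only the particle at 1.4 dx with 0.045 m/s converts.
#'
#' @param band optimal speed band, length 2 (m/s).
#' @param proximity_dx proximity radius in units of dx.
#' @param dx particle spacing (m).
#' @return a list of class \code{"frozen_fixture"}: \code{system},
#'   \code{mean_speed} (per particle), \code{expected_converted}
#'   (particle indices by direct rule evaluation), \code{config} (the
#'   matching [goldilocks_config()]).
#' @export
frozen_growth_fixture <- function(band = c(0.03, 0.06), proximity_dx = 1.5,
                                  dx = 0.05) {
  # coral at the centre; fluid along distinct directions so spacing holds
  cx <- 5 * dx
  cy <- 5 * dx
  ang <- c(90, 45, 0) * pi / 180
  dist <- c(1.0, 1.4, 1.6) * dx
  speeds <- c(0.02, 0.045, 0.07)
  x <- c(cx, cx + dist * cos(ang))
  y <- c(cy, cy + dist * sin(ang))
  phase <- c(PHASE[["LIVE_CORAL"]], rep(PHASE[["FLUID"]], 3))
  ps <- particle_system(x = x, y = y, vx = 0 * x, vy = 0 * x, rho = 1000,
                        mass = 1000 * dx^2, phase = phase, dx = dx,
                        bounds = c(0, 10 * dx, 0, 10 * dx))
  mean_speed <- c(NA_real_, speeds)
  # independent oracle: literal band-and-proximity evaluation
  d_to_coral <- sqrt((x - cx)^2 + (y - cy)^2)
  expected <- which(phase == PHASE[["FLUID"]] &
                      d_to_coral <= proximity_dx * dx &
                      mean_speed >= band[1] & mean_speed <= band[2])
  structure(list(system = ps, mean_speed = mean_speed,
                 expected_converted = expected,
                 config = goldilocks_config(v_opt_min = band[1],
                                            v_opt_max = band[2],
                                            proximity_dx = proximity_dx)),
            class = "frozen_fixture")
}

#' Write the frozen-fixture files
#'
#' Writes the fixture particle table and its oracle-derived expected
#' outcome table as CSV. The copies committed under
#' \code{inst/extdata/} are regenerated by this function in the test suite
#' and must match exactly.
#'
#' @param dir output directory.
#' @return the two file paths, invisibly.
#' @export
write_fixture_files <- function(dir = ".") {
  fx <- frozen_growth_fixture()
  pfile <- file.path(dir, "frozen_growth_particles.csv")
  efile <- file.path(dir, "frozen_growth_expected.csv")
  df <- as.data.frame(fx$system)
  df$mean_speed <- fx$mean_speed
  write.csv(format(df, digits = 12, trim = TRUE), pfile,
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(expected_converted = fx$expected_converted), efile,
            row.names = FALSE, quote = FALSE)
  invisible(c(pfile, efile))
}
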