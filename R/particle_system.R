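#' Particle phase codes
#'
#' Integer codes for the four particle phases. Fluid particles move; wall,
#' live-coral and dead-coral particles are dynamic boundary particles whose
#' positions and velocities are fixed (their densities and pressures still
#' evolve). The only legal phase transitions are FLUID -> LIVE_CORAL
#' (growth) and LIVE_CORAL -> DEAD_CORAL (death).
#'
#' @format A named integer vector with entries \code{FLUID}, \code{WALL},
#'   \code{LIVE_CORAL}, \code{DEAD_CORAL}.
#' @export
PHASE <- c(FLUID = 0L, WALL = 1L, LIVE_CORAL = 2L, DEAD_CORAL = 3L)

phase_name <- function(code) names(PHASE)[match(code, PHASE)]

#' Construct a particle system
#'
#' The state container for the solver: parallel vectors of positions,
#' velocities, densities, pressures, masses, phases and the per-particle
#' suboptimal-streak counters used by the death rule. Particle indices are
#' stable for the whole run, so growth/death conversions are auditable.
#'
#' Invariants enforced: densities positive; masses positive and constant;
#' non-fluid particles have zero velocity; the streak counter is zero for
#' every non-live-coral particle; no two particles closer than
#' \code{0.5 * dx} at construction (checked when \code{check_spacing}).
#'
#' @param x,y positions (m).
#' @param vx,vy velocities (m/s).
#' @param rho densities (kg/m^3).
#' @param mass particle masses (kg per metre of depth); scalar or vector.
#' @param phase integer phase codes (see [PHASE]); scalar or vector.
#' @param streak suboptimal-streak counters; defaults to 0.
#' @param dx initial particle spacing (m).
#' @param bounds domain bounds \code{c(xmin, xmax, ymin, ymax)} (m).
#' @param pressure pressures (Pa); defaults to 0.
#' @param check_spacing verify the minimum-spacing invariant (O(n) via the
#'   cell list). Default TRUE.
#' @return An object of class \code{"particle_system"}.
#' @export
particle_system <- function(x, y, vx, vy, rho, mass, phase, dx, bounds,
                            streak = 0L, pressure = 0, check_spacing = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n, length(vx) == n, length(vy) == n,
            is.numeric(dx), length(dx) == 1L, dx > 0,
            is.numeric(bounds), length(bounds) == 4L)
  rho <- rep_len(as.numeric(rho), n)
  mass <- rep_len(as.numeric(mass), n)
  phase <- rep_len(as.integer(phase), n)
  streak <- rep_len(as.integer(streak), n)
  pressure <- rep_len(as.numeric(pressure), n)
  if (any(!phase %in% PHASE)) stop("unknown phase code", call. = FALSE)
  if (any(rho <= 0)) stop("densities must be positive", call. = FALSE)
  if (any(mass <= 0)) stop("masses must be positive", call. = FALSE)
  solid <- phase != PHASE["FLUID"]
  if (any(solid & (vx != 0 | vy != 0)))
    stop("boundary-phase particles must have zero velocity", call. = FALSE)
  if (any(streak != 0L & phase != PHASE["LIVE_CORAL"]))
    stop("suboptimal streak must be zero for non-live-coral particles",
         call. = FALSE)
  ps <- structure(list(n = n, id = seq_len(n),
                       x = as.numeric(x), y = as.numeric(y),
                       vx = as.numeric(vx), vy = as.numeric(vy),
                       rho = as.numeric(rho), p = pressure, mass = mass,
                       phase = phase, streak = streak,
                       dx = dx, bounds = as.numeric(bounds)),
                  class = "particle_system")
  if (check_spacing && n > 1) {
    nb <- build_cell_list(ps, cutoff = 0.5 * dx)
    if (any(lengths(nb) > 0))
      stop("particles closer than 0.5 * dx at initialization", call. = FALSE)
  }
  ps
}

#' @export
print.particle_system <- function(x, ...) {
  pc <- phase_counts(x)
  cat(sprintf("<particle_system> n = %d, dx = %g m, bounds = [%g, %g] x [%g, %g] m\n",
              x$n, x$dx, x$bounds[1], x$bounds[2], x$bounds[3], x$bounds[4]))
  cat("  ", paste(sprintf("%s = %d", names(pc$counts), pc$counts),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.particle_system <- function(x, ...) {
  data.frame(id = x$id, x = x$x, y = x$y, vx = x$vx, vy = x$vy,
             rho = x$rho, p = x$p, mass = x$mass,
             phase = phase_name(x$phase), streak = x$streak)
}

#' Cell-linked-list neighbor search
#'
#' Returns, for each particle, the indices of all other particles within
#' \code{cutoff}, found on a uniform grid of cells of size \code{cutoff}
#' (so candidate pairs live in the 3x3 cell patch). Deterministic: each
#' neighbor set is sorted by particle index. \code{method = "brute"} runs
#' the all-pairs O(n^2) scan instead and is the reference oracle for the
#' cell list.
#'
#' @param system a [particle_system()].
#' @param cutoff neighbor radius (m); must be positive, and at least the
#'   kernel support radius when used for SPH sums.
#' @param method \code{"cell"} (default) or \code{"brute"}.
#' @param periodic_x wrap displacements across the x extent of the domain
#'   bounds (used only by the analytic channel validation cases).
#' @return a list of integer vectors, one per particle (self excluded).
#' @export
build_cell_list <- function(system, cutoff, method = c("cell", "brute"),
                            periodic_x = FALSE) {
  stopifnot(inherits(system, "particle_system"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive scalar", call. = FALSE)
  method <- match.arg(method)
  if (method == "brute")
    return(neighbors_brute(system, cutoff, periodic_x = periodic_x))
  cell_neighbors_cpp(system$x, system$y, cutoff, periodic_x,
                     system$bounds[1], system$bounds[2])
}

#' @rdname build_cell_list
#' @export
neighbors_brute <- function(system, cutoff, periodic_x = FALSE) {
  stopifnot(inherits(system, "particle_system"), cutoff > 0)
  n <- system$n
  width <- system$bounds[2] - system$bounds[1]
  lapply(seq_len(n), function(i) {
    dx <- system$x[i] - system$x
    if (periodic_x) dx <- dx - width * round(dx / width)
    dy <- system$y[i] - system$y
    j <- which(dx^2 + dy^2 < cutoff^2)
    j[j != i]
  })
}

#' Phase census of a particle system
#'
#' @param system a [particle_system()].
#' @return a list with \code{counts} (named integer vector over the four
#'   phases, summing to \code{system$n}), \code{total}, and
#'   \code{live_dead_ratio} (live / dead; \code{NA} while no particle has
#'   died, so early-run ratios are undefined rather than infinite).
#' @export
phase_counts <- function(system) {
  stopifnot(inherits(system, "particle_system"))
  counts <- vapply(PHASE, function(code) sum(system$phase == code), integer(1))
  ratio <- if (counts[["DEAD_CORAL"]] > 0)
    counts[["LIVE_CORAL"]] / counts[["DEAD_CORAL"]] else NA_real_
  list(counts = counts, total = system$n, live_dead_ratio = ratio)
}

#' Apply a phase transition
#'
#' Only the ecological transitions are legal: FLUID -> LIVE_CORAL (growth)
#' and LIVE_CORAL -> DEAD_CORAL (death). Converted particles keep their mass
#' and last density; velocity is zeroed (dynamic boundary particles are
#' static) and the streak counter reset.
#'
#' @param system a [particle_system()].
#' @param idx indices of particles to convert.
#' @param new_phase target phase code (see [PHASE]).
#' @return the updated system.
#' @export
set_phase <- function(system, idx, new_phase) {
  stopifnot(inherits(system, "particle_system"))
  if (length(idx) == 0) return(system)
  new_phase <- as.integer(new_phase)
  stopifnot(length(new_phase) == 1L, new_phase %in% PHASE)
  old <- system$phase[idx]
  ok <- (old == PHASE["FLUID"] & new_phase == PHASE["LIVE_CORAL"]) |
        (old == PHASE["LIVE_CORAL"] & new_phase == PHASE["DEAD_CORAL"])
  if (!all(ok))
    stop(sprintf("illegal phase transition %s -> %s",
                 phase_name(old[!ok][1]), phase_name(new_phase)), call. = FALSE)
  system$phase[idx] <- new_phase
  system$vx[idx] <- 0
  system$vy[idx] <- 0
  system$streak[idx] <- 0L
  system
}
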