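#' Goldilocks growth/death rule configuration
#'
#' The ecological rules: a fluid particle adjacent to the colony (within
#' \code{proximity_dx * dx} of any live or dead coral particle) whose
#' time-averaged speed lies in the optimal band becomes live coral at the
#' next growth event; a live coral particle that sees no adjacent in-band
#' fluid for \code{death_interval} consecutive growth events becomes dead
#' framework, permanently. \code{death_interval = Inf} disables death.
#'
#' @param v_opt_min,v_opt_max optimal flow band (m/s); defaults 0.03 and
#'   0.06 (the 3--6 cm/s prey-capture optimum).
#' @param proximity_dx adjacency radius as a multiple of the particle
#'   spacing; default 1.5.
#' @param death_interval K: consecutive suboptimal growth events before a
#'   live particle dies; \code{Inf} = no death rule.
#' @param settle_steps solver steps run between growth events.
#' @param avg_window trailing solver steps over which local speeds are
#'   averaged before rule evaluation.
#' @param steady_tol relative change of windowed mean kinetic energy below
#'   which the flow counts as steady.
#' @param max_settle_rounds extra settling rounds allowed while waiting for
#'   steadiness before an event fires regardless.
#' @param cap_per_event maximum conversions per growth event; \code{Inf}
#'   (default) converts every qualifying particle, \code{1} reproduces a
#'   strict one-particle-per-growth-step reading.
#' @param reset_streak if TRUE (default) a single optimal evaluation resets
#'   a live particle's suboptimal streak; FALSE accumulates without reset
#'   (sensitivity mode).
#' @param death_cadence evaluate the death rule at every growth event
#'   (\code{1}, default) or only at events that are multiples of this
#'   cadence.
#' @return a \code{"goldilocks_config"} list.
#' @export
goldilocks_config <- function(v_opt_min = 0.03, v_opt_max = 0.06,
                              proximity_dx = 1.5, death_interval = Inf,
                              settle_steps = 300L, avg_window = 150L,
                              steady_tol = 0.05, max_settle_rounds = 2L,
                              cap_per_event = Inf, reset_streak = TRUE,
                              death_cadence = 1L) {
  stopifnot(v_opt_min > 0, v_opt_max > v_opt_min, proximity_dx > 0,
            death_interval >= 1, settle_steps >= 1, avg_window >= 1,
            steady_tol > 0, cap_per_event >= 1, death_cadence >= 1)
  structure(list(v_opt_min = v_opt_min, v_opt_max = v_opt_max,
                 proximity_dx = proximity_dx, death_interval = death_interval,
                 settle_steps = as.integer(settle_steps),
                 avg_window = as.integer(avg_window),
                 steady_tol = steady_tol,
                 max_settle_rounds = as.integer(max_settle_rounds),
                 cap_per_event = cap_per_event,
                 reset_streak = isTRUE(reset_streak),
                 death_cadence = as.integer(death_cadence)),
            class = "goldilocks_config")
}

#' Steady-flow detector
#'
#' The flow counts as steady when the windowed mean of the domain kinetic
#' energy stops changing: the relative difference between the means of the
#' last two windows of length \code{window} falls below \code{steady_tol}.
#'
#' @param ke_history numeric vector of per-step total kinetic energies.
#' @param steady_tol relative tolerance.
#' @param window window length in steps.
#' @return TRUE/FALSE; FALSE for histories shorter than two windows.
#' @export
steady_state_reached <- function(ke_history, steady_tol = 0.05, window = 50L) {
  n <- length(ke_history)
  if (n < 2L * window) return(FALSE)
  m2 <- mean(ke_history[(n - window + 1L):n])
  m1 <- mean(ke_history[(n - 2L * window + 1L):(n - window)])
  ref <- max(abs(m1), abs(m2), .Machine$double.eps)
  abs(m2 - m1) / ref < steady_tol
}

# Adjacency between coral and fluid particles within the proximity radius.
# Returns a list: for each particle, its neighbor indices within proximity.
proximity_neighbors <- function(system, cfg) {
  build_cell_list(system, cutoff = cfg$proximity_dx * system$dx)
}

#' Mean local flow speeds adjacent to a coral particle
#'
#' For one coral particle, the trailing-window mean speed of every fluid
#' particle within the proximity radius (Euclidean distance between
#' particle centres).
#'
#' @param system a [particle_system()].
#' @param mean_speed per-particle trailing-window mean speeds, as returned
#'   by [advance()].
#' @param coral_particle index of the coral particle.
#' @param cfg a [goldilocks_config()].
#' @return named numeric vector (names = fluid particle indices); empty when
#'   no fluid is adjacent.
#' @export
local_mean_speed <- function(system, mean_speed, coral_particle, cfg) {
  stopifnot(inherits(system, "particle_system"),
            inherits(cfg, "goldilocks_config"),
            length(mean_speed) == system$n)
  nb <- proximity_neighbors(system, cfg)[[coral_particle]]
  nb <- nb[system$phase[nb] == PHASE[["FLUID"]]]
  out <- mean_speed[nb]
  names(out) <- nb
  out
}

# Internal shared rule evaluation: for the pre-event snapshot, which fluid
# particles qualify for growth and which live particles saw optimal flow.
evaluate_rules <- function(system, mean_speed, cfg) {
  nb <- proximity_neighbors(system, cfg)
  fluid <- system$phase == PHASE[["FLUID"]]
  coral <- system$phase %in% PHASE[c("LIVE_CORAL", "DEAD_CORAL")]
  inband <- fluid & is.finite(mean_speed) &
    mean_speed >= cfg$v_opt_min & mean_speed <= cfg$v_opt_max
  grow <- which(inband & vapply(nb, function(j) any(coral[j]), logical(1)))
  live <- which(system$phase == PHASE[["LIVE_CORAL"]])
  optimal_live <- vapply(live, function(i) {
    j <- nb[[i]]
    any(fluid[j] & is.finite(mean_speed[j]) &
          mean_speed[j] >= cfg$v_opt_min & mean_speed[j] <= cfg$v_opt_max)
  }, logical(1))
  list(grow = grow, live = live, optimal_live = optimal_live)
}

#' Growth event: convert optimal adjacent fluid to live coral
#'
#' Every fluid particle within the proximity radius of at least one coral
#' particle (live or dead) whose buffered mean speed lies in the optimal
#' band is converted to live coral with zero velocity. Conversions are
#' evaluated simultaneously against the pre-event snapshot; no particles
#' are created or destroyed. With a finite \code{cap_per_event} only the
#' lowest-index qualifiers convert (deterministic tie-break).
#'
#' @inheritParams local_mean_speed
#' @return a list: \code{system} (updated), \code{converted} (indices).
#' @export
growth_event <- function(system, mean_speed, cfg) {
  stopifnot(inherits(system, "particle_system"),
            inherits(cfg, "goldilocks_config"),
            length(mean_speed) == system$n)
  grow <- evaluate_rules(system, mean_speed, cfg)$grow
  if (is.finite(cfg$cap_per_event) && length(grow) > cfg$cap_per_event)
    grow <- grow[seq_len(cfg$cap_per_event)]
  list(system = set_phase(system, grow, PHASE[["LIVE_CORAL"]]),
       converted = grow)
}

#' Death event: suboptimal streaks and live-to-dead conversion
#'
#' A live coral particle's suboptimal streak increments when no adjacent
#' fluid particle has an in-band mean speed — interior particles with no
#' adjacent fluid at all are suboptimal by construction — and (by default)
#' resets to zero after a single optimal evaluation. A particle whose
#' streak reaches \code{death_interval} becomes dead framework permanently.
#' With \code{death_interval = Inf} streaks still accumulate but nothing
#' ever dies.
#'
#' @inheritParams local_mean_speed
#' @return a list: \code{system} (updated), \code{died} (indices).
#' @export
death_event <- function(system, mean_speed, cfg) {
  stopifnot(inherits(system, "particle_system"),
            inherits(cfg, "goldilocks_config"),
            length(mean_speed) == system$n)
  ev <- evaluate_rules(system, mean_speed, cfg)
  live <- ev$live
  opt <- ev$optimal_live
  if (length(live)) {
    system$streak[live[!opt]] <- system$streak[live[!opt]] + 1L
    if (cfg$reset_streak) system$streak[live[opt]] <- 0L
  }
  died <- live[system$streak[live] >= cfg$death_interval]
  list(system = set_phase(system, died, PHASE[["DEAD_CORAL"]]), died = died)
}

#' Run a full growth scenario
#'
#' Alternates solver settling phases with growth/death events: after an
#' initial spin-up of about two flow-through times, each growth step runs
#' \code{settle_steps} solver steps (repeating up to
#' \code{max_settle_rounds} extra rounds while the flow is not yet steady),
#' averages per-particle speeds over the trailing \code{avg_window} steps,
#' evaluates the death rule and the growth rule against the same pre-event
#' snapshot, and records the phase census. Deterministic: the loop contains
#' no randomness.
#'
#' @param config a [scenario_config()].
#' @param verbose print a one-line summary per growth step.
#' @return an object of class \code{"scenario_result"}: a list with
#'   \code{counts} (data frame: step, n_fluid, n_live, n_dead,
#'   live_dead_ratio, converted, died, steady), \code{events} (data frame of
#'   individual conversions: step, id, transition), \code{snapshots} (named
#'   list of [particle_system()]s at the requested steps),
#'   \code{extinction_step} (growth step at which live count reached zero,
#'   or NA), \code{system} (final state), \code{config} and
#'   \code{config_hash}.
#' @export
run_scenario <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  spec <- config$domain
  props <- config$fluid
  kernel <- kernel_spec(config$kernel$h_over_dx * spec$dx)
  cfg <- config$goldilocks
  run <- config$run

  ps <- build_domain(spec, props, kernel)
  flow <- scenario_flow(spec)
  v_clamp <- 2 * spec$lid_speed

  # spin-up: integrate for init_time seconds of simulated time
  dt0 <- compute_dt(ps, props, kernel)
  n_init <- as.integer(ceiling(run$init_time / dt0))
  st <- advance(ps, props, kernel, n_steps = n_init, flow = flow,
                avg_window = cfg$avg_window, v_clamp = v_clamp)
  ps <- st$system

  counts <- vector("list", run$max_growth_steps)
  events <- list()
  snapshots <- list()
  extinction <- NA_integer_
  ke_hist <- st$ke

  for (step in seq_len(run$max_growth_steps)) {
    rounds <- 0L
    repeat {
      st <- advance(ps, props, kernel, n_steps = cfg$settle_steps, flow = flow,
                    avg_window = cfg$avg_window, v_clamp = v_clamp)
      ps <- st$system
      ke_hist <- c(ke_hist, st$ke)
      steady <- steady_state_reached(ke_hist, cfg$steady_tol,
                                     window = cfg$avg_window)
      if (steady || rounds >= cfg$max_settle_rounds) break
      rounds <- rounds + 1L
    }
    ms <- st$mean_speed

    # death and growth evaluated against the same pre-event snapshot
    died <- integer(0)
    if (is.finite(cfg$death_interval) && step %% cfg$death_cadence == 0L) {
      de <- death_event(ps, ms, cfg)
      died <- de$died
      streaks <- de$system$streak
    } else {
      streaks <- NULL
    }
    ge <- growth_event(ps, ms, cfg)
    ps2 <- ge$system
    if (!is.null(streaks)) {
      # merge: growth applied to the snapshot, death bookkeeping on top
      keep <- ps2$phase == PHASE[["LIVE_CORAL"]] & ps$phase == PHASE[["LIVE_CORAL"]]
      ps2$streak[keep] <- streaks[keep]
      ps2 <- set_phase(ps2, died, PHASE[["DEAD_CORAL"]])
    }
    ps <- ps2

    pc <- phase_counts(ps)
    counts[[step]] <- data.frame(step = step,
                                 n_fluid = pc$counts[["FLUID"]],
                                 n_live = pc$counts[["LIVE_CORAL"]],
                                 n_dead = pc$counts[["DEAD_CORAL"]],
                                 n_wall = pc$counts[["WALL"]],
                                 live_dead_ratio = pc$live_dead_ratio,
                                 converted = length(ge$converted),
                                 died = length(died),
                                 steady = steady)
    if (length(ge$converted))
      events[[length(events) + 1L]] <-
        data.frame(step = step, id = ge$converted, transition = "FLUID->LIVE_CORAL")
    if (length(died))
      events[[length(events) + 1L]] <-
        data.frame(step = step, id = died, transition = "LIVE_CORAL->DEAD_CORAL")
    if (step %in% run$snapshot_steps)
      snapshots[[as.character(step)]] <- ps
    if (verbose)
      message(sprintf("growth-step %3d: fluid %d, live %d, dead %d (%+d, -%d)%s",
                      step, pc$counts[["FLUID"]], pc$counts[["LIVE_CORAL"]],
                      pc$counts[["DEAD_CORAL"]], length(ge$converted),
                      length(died), if (steady) "" else " [not steady]"))
    if (pc$counts[["LIVE_CORAL"]] == 0L) {
      extinction <- step
      break
    }
  }

  counts <- do.call(rbind, counts[!vapply(counts, is.null, logical(1))])
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(step = integer(0), id = integer(0), transition = character(0))
  structure(list(counts = counts, events = events, snapshots = snapshots,
                 extinction_step = extinction, system = ps,
                 config = config, config_hash = config_hash(config)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  last <- x$counts[nrow(x$counts), ]
  cat(sprintf("<scenario_result> %d growth-steps; final: fluid %d, live %d, dead %d\n",
              nrow(x$counts), last$n_fluid, last$n_live, last$n_dead))
  if (!is.na(x$extinction_step))
    cat(sprintf("  colony extinct at growth-step %d\n", x$extinction_step))
  cat(sprintf("  config hash %s\n", x$config_hash))
  invisible(x)
}
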