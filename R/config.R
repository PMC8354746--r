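#' Full scenario configuration
#'
#' Bundles the domain geometry, fluid properties, kernel ratio, Goldilocks
#' rules and run schedule for [run_scenario()]. The defaults are the
#' full-scale growth scenario: a 10 x 5 m domain at dx = 0.05 m (20 000
#' interior lattice sites), lid current 0.5 m/s, speed of sound 10 m/s,
#' Tait exponent 7, density-filter epsilon 0.01, optimal band 3--6 cm/s
#' with proximity 1.5 dx, and 230 growth steps. The scenario fluid uses an
#' effective viscosity of 0.5 Pa s (see the methods vignette); gravity is
#' excluded — the flow is driven by the inlet and lid, and the growth band
#' concerns horizontal current speed.
#'
#' @param domain a [domain_spec()].
#' @param fluid a [fluid_properties()].
#' @param h_over_dx smoothing length as a multiple of dx; default 1.3.
#' @param goldilocks a [goldilocks_config()].
#' @param init_time spin-up time before the first growth event (s of
#'   simulated time); default two flow-through times.
#' @param max_growth_steps number of growth events to run.
#' @param snapshot_steps growth steps at which to keep full snapshots.
#' @return a \code{"scenario_config"} list.
#' @export
scenario_config <- function(domain = domain_spec(),
                            fluid = fluid_properties(mu = 0.5),
                            h_over_dx = 1.3,
                            goldilocks = goldilocks_config(),
                            init_time = 2 * domain$width / domain$lid_speed,
                            max_growth_steps = 230L,
                            snapshot_steps = c(20L, 80L, 140L, 230L)) {
  stopifnot(inherits(domain, "domain_spec"),
            inherits(fluid, "fluid_properties"),
            inherits(goldilocks, "goldilocks_config"),
            h_over_dx > 0, init_time >= 0, max_growth_steps >= 1)
  structure(list(domain = domain, fluid = fluid,
                 kernel = list(h_over_dx = h_over_dx),
                 goldilocks = goldilocks,
                 run = list(init_time = init_time,
                            max_growth_steps = as.integer(max_growth_steps),
                            snapshot_steps = as.integer(snapshot_steps))),
            class = "scenario_config")
}

#' Reduced-scale scenario configuration
#'
#' A scaled-down version of the growth scenario (2 x 1 m at dx = 0.025 m,
#' 3 200 fluid particles) preserving the lid speed, optimal
#' band, proximity rule and equation-of-state constants of the full
#' scenario. This is the desk-scale configuration used for the property
#' checks and the death-interval sweep; see the methods vignette for the
#' choice of problem sizes.
#'
#' @param death_interval K, the death rule interval; \code{Inf} disables
#'   death.
#' @param max_growth_steps number of growth events; default 100.
#' @param ... overrides passed to [goldilocks_config()].
#' @return a \code{"scenario_config"}.
#' @export
reduced_scenario_config <- function(death_interval = Inf,
                                    max_growth_steps = 100L, ...) {
  scenario_config(
    domain = domain_spec(width = 2, height = 1, dx = 0.025,
                         seed_radius = 0.25),
    fluid = fluid_properties(mu = 0.5),
    goldilocks = goldilocks_config(death_interval = death_interval, ...),
    max_growth_steps = max_growth_steps,
    snapshot_steps = c(20L, 50L, max_growth_steps))
}

canonical_config_string <- function(config) {
  flat <- unlist(lapply(config, function(el) {
    if (inherits(el, c("domain_spec", "fluid_properties",
                       "goldilocks_config")) || is.list(el))
      unclass(el) else el
  }))
  paste(names(flat), vapply(flat, function(v) format(v, digits = 15),
                            character(1)),
        sep = "=", collapse = ";")
}

#' Configuration hash
#'
#' A short deterministic hash of the canonical configuration string,
#' embedded in every output file so metrics, snapshots and event logs can
#' be traced to the configuration that produced them.
#'
#' @param config a [scenario_config()].
#' @return an 8-character lowercase hex string.
#' @export
config_hash <- function(config) {
  s <- canonical_config_string(config)
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Load a scenario configuration from a YAML file
#'
#' The file holds nested blocks \code{domain}, \code{fluid}, \code{kernel},
#' \code{goldilocks} and \code{run}, each optional; omitted keys take the
#' documented defaults (gamma = 7, cs = 10 m/s, epsilon = 0.01, band
#' 3--6 cm/s, ...). Unknown keys are rejected with an error naming the key;
#' invalid values are rejected by the constructors with the violated
#' constraint.
#'
#' @param path path to a YAML file.
#' @return a [scenario_config()].
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known_blocks <- c("domain", "fluid", "kernel", "goldilocks", "run")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  take <- function(block, fn) {
    args <- raw[[block]]
    if (is.null(args)) return(fn())
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop(sprintf("unknown key(s) in `%s`: %s", block,
                   paste(bad, collapse = ", ")), call. = FALSE)
    do.call(fn, args)
  }
  domain <- take("domain", domain_spec)
  fluid <- take("fluid", function(rho0 = 1000, mu = 0.5, cs = 10, gamma = 7,
                                  epsilon = 0.01, body_force = c(0, 0),
                                  p_background = 0)
    fluid_properties(rho0, mu, cs, gamma, epsilon, unlist(body_force),
                     p_background))
  gl <- take("goldilocks", goldilocks_config)
  kn <- raw$kernel
  if (!is.null(kn)) {
    bad <- setdiff(names(kn), "h_over_dx")
    if (length(bad))
      stop("unknown key(s) in `kernel`: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  rn <- raw$run
  if (!is.null(rn)) {
    bad <- setdiff(names(rn), c("init_time", "max_growth_steps", "snapshot_steps"))
    if (length(bad))
      stop("unknown key(s) in `run`: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  args <- c(list(domain = domain, fluid = fluid, goldilocks = gl),
            if (!is.null(kn$h_over_dx)) list(h_over_dx = kn$h_over_dx),
            rn)
  do.call(scenario_config, args)
}

#' Save a scenario configuration to YAML
#'
#' Round-trips losslessly through [load_config()]: the reloaded
#' configuration has an identical [config_hash()].
#'
#' @param config a [scenario_config()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  gl <- unclass(config$goldilocks)
  out <- list(domain = unclass(config$domain),
              fluid = unclass(config$fluid)[c("rho0", "mu", "cs", "gamma",
                                              "epsilon", "body_force",
                                              "p_background")],
              kernel = config$kernel,
              goldilocks = gl,
              run = config$run)
  yaml::write_yaml(out, path)
  invisible(path)
}
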