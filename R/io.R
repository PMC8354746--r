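#' Write a particle snapshot
#'
#' Canonical snapshot format: a CSV particle table (columns id, x, y, vx,
#' vy, rho, p, mass, phase, streak) with the config hash embedded as a
#' leading comment line. \code{format = "vtk"} additionally understands the
#' legacy VTK ASCII point-cloud format (phase written as a scalar field)
#' for visual inspection of colony renders; the CSV remains the canonical,
#' diffable format.
#'
#' @param system a [particle_system()].
#' @param path output path.
#' @param format \code{"csv"} (default) or \code{"vtk"}.
#' @param hash config hash to embed (see [config_hash()]); \code{""} for
#'   none.
#' @return \code{path}, invisibly.
#' @seealso [read_snapshot()]
#' @export
write_snapshot <- function(system, path, format = c("csv", "vtk"), hash = "") {
  stopifnot(inherits(system, "particle_system"))
  format <- match.arg(format)
  df <- as.data.frame(system)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (nzchar(hash)) writeLines(sprintf("# config_hash=%s", hash), con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else {
    lines <- c("# vtk DataFile Version 3.0",
               sprintf("reefsph snapshot config_hash=%s", hash),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", system$n),
               sprintf("%g %g 0", system$x, system$y),
               sprintf("POINT_DATA %d", system$n),
               "SCALARS phase int 1", "LOOKUP_TABLE default",
               sprintf("%d", system$phase),
               "SCALARS speed float 1", "LOOKUP_TABLE default",
               sprintf("%g", sqrt(system$vx^2 + system$vy^2)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a particle snapshot CSV
#'
#' @param path a CSV written by [write_snapshot()].
#' @param dx particle spacing of the system (m); recovered from the minimum
#'   particle distance when omitted.
#' @param bounds domain bounds; recovered from the particle extent when
#'   omitted.
#' @return a [particle_system()].
#' @export
read_snapshot <- function(path, dx = NULL, bounds = NULL) {
  df <- read.csv(path, comment.char = "#")
  need <- c("id", "x", "y", "vx", "vy", "rho", "p", "mass", "phase", "streak")
  if (!all(need %in% names(df)))
    stop("snapshot is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  code <- PHASE[df$phase]
  if (any(is.na(code))) stop("unknown phase label in snapshot", call. = FALSE)
  if (is.null(dx)) {
    ux <- sort(unique(df$x))
    dx <- if (length(ux) > 1) min(diff(ux)[diff(ux) > 1e-12]) else 1
  }
  if (is.null(bounds))
    bounds <- c(min(df$x) - dx / 2, max(df$x) + dx / 2,
                min(df$y) - dx / 2, max(df$y) + dx / 2)
  particle_system(x = df$x, y = df$y, vx = df$vx, vy = df$vy, rho = df$rho,
                  mass = df$mass, phase = unname(code), streak = df$streak,
                  pressure = df$p, dx = dx, bounds = bounds,
                  check_spacing = FALSE)
}

#' Write the per-growth-step metrics table
#'
#' One row per growth step (step, n_fluid, n_live, n_dead, n_wall,
#' live_dead_ratio, converted, died, steady) with the config hash embedded
#' as a leading comment line.
#'
#' @param result a [run_scenario()] result.
#' @param path output path.
#' @param what \code{"counts"} (default) or \code{"events"} (conversion and
#'   death log: step, id, transition).
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(result, path, what = c("counts", "events")) {
  stopifnot(inherits(result, "scenario_result"))
  what <- match.arg(what)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", result$config_hash), con)
  write.csv(result[[what]], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract a flow-speed probe series from snapshots
#'
#' Mirrors in silico the extraction of flow vectors at fixed positions:
#' for each snapshot, the fluid speed at the probe position is the
#' Shepard-normalized kernel-weighted mean of the speeds of fluid particles
#' within \code{radius}; the series mean and standard error are attached.
#'
#' @param snapshots a list of [particle_system()]s.
#' @param position length-2 probe position (m); must lie inside the domain.
#' @param radius probe support radius (m); kernel smoothing length is
#'   \code{radius / 2}.
#' @return a list of class \code{"probe_series"}: \code{position},
#'   \code{samples} (speed per snapshot, m/s), \code{mean}, \code{se}.
#' @export
extract_probe <- function(snapshots, position, radius) {
  stopifnot(is.list(snapshots), length(snapshots) >= 1,
            length(position) == 2L, radius > 0)
  b <- snapshots[[1]]$bounds
  if (position[1] < b[1] || position[1] > b[2] ||
      position[2] < b[3] || position[2] > b[4])
    stop("probe position outside the domain", call. = FALSE)
  ks <- kernel_spec(radius / 2)
  samples <- vapply(snapshots, function(ps) {
    stopifnot(inherits(ps, "particle_system"))
    fluid <- ps$phase == PHASE[["FLUID"]]
    dx <- ps$x[fluid] - position[1]
    dy <- ps$y[fluid] - position[2]
    sel <- dx^2 + dy^2 < radius^2
    if (!any(sel)) return(NA_real_)
    w <- wendland_value(cbind(dx[sel], dy[sel]), ks)
    spd <- sqrt(ps$vx[fluid][sel]^2 + ps$vy[fluid][sel]^2)
    sum(w * spd) / sum(w)
  }, numeric(1))
  m <- mean(samples, na.rm = TRUE)
  se <- if (sum(!is.na(samples)) > 1)
    sd(samples, na.rm = TRUE) / sqrt(sum(!is.na(samples))) else 0
  structure(list(position = as.numeric(position), samples = samples,
                 mean = m, se = se), class = "probe_series")
}

#' @export
print.probe_series <- function(x, ...) {
  cat(sprintf("<probe_series> at (%g, %g) m: mean %.4g m/s, se %.3g (n = %d)\n",
              x$position[1], x$position[2], x$mean, x$se, length(x$samples)))
  invisible(x)
}
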