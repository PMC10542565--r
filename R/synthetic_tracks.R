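# Gradient-plate worm tracks: a biased random walk sampled at 1 Hz, and
# CSV import/export with a plate-geometry header block.

#' Default assay plate
#'
#' A 10-cm square plate with a linear thermal gradient from 23 degC (cold
#' edge) to 28 degC (warm edge) at 0.5 degC/cm along `axis` (the unit
#' vector pointing toward warm).
#'
#' @param width,height Plate dimensions, mm.
#' @param axis Gradient axis (toward warm) in plate coordinates.
#' @param T_cold,T_warm Edge temperatures, degC.
#' @param steepness Gradient steepness, degC/cm.
#' @return A `plate` object (list).
#' @export
default_plate <- function(width = 100, height = 100, axis = c(1, 0),
                          T_cold = 23, T_warm = 28, steepness = 0.5) {
  if (T_cold >= T_warm) stop("T_cold must be below T_warm")
  if (steepness <= 0) stop("steepness must be positive")
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("gradient axis must be a non-zero vector")
  structure(list(width = width, height = height, axis = axis / n,
                 T_cold = T_cold, T_warm = T_warm, steepness = steepness),
            class = "plate")
}

#' Temperature at plate positions
#'
#' Linear in the projection onto the gradient axis, in degC, clamped to
#' `[T_cold, T_warm]`. Steepness is given per cm; positions are mm.
#'
#' @param plate A [default_plate()] object.
#' @param x,y Positions, mm.
#' @return Temperatures, degC.
#' @export
temperature_at <- function(plate, x, y) {
  proj <- x * plate$axis[1] + y * plate$axis[2]
  pmin(pmax(plate$T_cold + plate$steepness / 10 * proj, plate$T_cold),
       plate$T_warm)
}

# reflect unbounded coordinates into [0, L] (billiard reflection)
fold_reflect <- function(p, L) {
  m <- p %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}

#' Simulate one gradient-plate track
#'
#' A discrete biased random walk sampled at 1 Hz: each step of length
#' `step_length` is taken cold-ward (against the gradient axis) with
#' probability `drift_p`, otherwise warm-ward, with optional Gaussian
#' lateral jitter; the walk reflects at the plate walls. The default
#' duration (2100 steps = 35 min at 1 Hz) matches a standard thermotaxis
#' assay recording; the worm starts at the plate center.
#'
#' @param drift_p Probability of a cold-ward step, in `[0, 1]`.
#' @param n_steps Number of 1-s steps; default 2100.
#' @param step_length Step length, mm; default 0.025 (chosen so that even a
#'   strongly biased 35-min walk stays within the 10-cm plate interior --
#'   the walk models gradient-directed displacement statistics, not
#'   absolute crawling speed).
#' @param plate A [default_plate()] object.
#' @param lateral_sd SD of lateral jitter per step, mm; default 0.
#' @param seed Optional integer seed.
#' @return A `worm_track` data.frame (`t` seconds, `x`, `y` mm) with the
#'   plate stored in `attr(, "plate")`.
#' @export
simulate_track <- function(drift_p, n_steps = 2100L, step_length = 0.025,
                           plate = default_plate(), lateral_sd = 0,
                           seed = NULL) {
  if (drift_p < 0 || drift_p > 1) stop("drift_p must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  a <- plate$axis
  ortho <- c(-a[2], a[1])
  dir <- ifelse(stats::runif(n_steps) < drift_p, -1, 1)  # -1 = cold-ward
  lat <- if (lateral_sd > 0) stats::rnorm(n_steps, 0, lateral_sd) else numeric(n_steps)
  dx <- dir * step_length * a[1] + lat * ortho[1]
  dy <- dir * step_length * a[2] + lat * ortho[2]
  x <- plate$width / 2 + cumsum(c(0, dx))
  y <- plate$height / 2 + cumsum(c(0, dy))
  track <- data.frame(t = 0:n_steps,
                      x = fold_reflect(x, plate$width),
                      y = fold_reflect(y, plate$height))
  attr(track, "plate") <- plate
  class(track) <- c("worm_track", "data.frame")
  track
}

#' Write / read a track CSV
#'
#' The CSV carries the plate geometry in a `#`-prefixed header block
#' (`# key: value` lines) followed by `t,x,y` rows, so a track file is
#' self-describing.
#'
#' @param track A `worm_track`.
#' @param path File path.
#' @return `write_track_csv()`: `path`, invisibly. `read_track_csv()`: a
#'   `worm_track` with its plate attribute restored.
#' @export
write_track_csv <- function(track, path) {
  plate <- attr(track, "plate")
  if (is.null(plate)) plate <- default_plate()
  hdr <- c(sprintf("# width_mm: %.6g", plate$width),
           sprintf("# height_mm: %.6g", plate$height),
           sprintf("# axis: %.10g %.10g", plate$axis[1], plate$axis[2]),
           sprintf("# T_cold_C: %.6g", plate$T_cold),
           sprintf("# T_warm_C: %.6g", plate$T_warm),
           sprintf("# steepness_C_per_cm: %.6g", plate$steepness),
           "t,x,y")
  body <- sprintf("%.10g,%.10g,%.10g", track$t, track$x, track$y)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  lines <- readLines(path)
  hd <- grepl("^#", lines)
  kv <- list()
  for (l in lines[hd]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  num <- function(k, default) if (!is.null(kv[[k]])) as.numeric(kv[[k]]) else default
  axis <- if (!is.null(kv[["axis"]])) as.numeric(strsplit(kv[["axis"]], "\\s+")[[1]]) else c(1, 0)
  plate <- default_plate(width = num("width_mm", 100), height = num("height_mm", 100),
                         axis = axis, T_cold = num("T_cold_C", 23),
                         T_warm = num("T_warm_C", 28),
                         steepness = num("steepness_C_per_cm", 0.5))
  body <- lines[!hd]
  body <- body[body != "" & body != "t,x,y"]
  parts <- do.call(rbind, strsplit(body, ","))
  track <- data.frame(t = as.numeric(parts[, 1]), x = as.numeric(parts[, 2]),
                      y = as.numeric(parts[, 3]))
  attr(track, "plate") <- plate
  class(track) <- c("worm_track", "data.frame")
  track
}

#' Plot a track on its plate
#'
#' @param x A `worm_track`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.worm_track <- function(x, ...) {
  plate <- attr(x, "plate")
  graphics::plot(x$x, x$y, type = "l", xlab = "x (mm)", ylab = "y (mm)",
                 xlim = c(0, plate$width), ylim = c(0, plate$height),
                 asp = 1, ...)
  invisible(x)
}
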