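# Behavioral statistics used to classify strains: thermotaxis bias on a
# spatial gradient, grid exploration count, and chemotaxis index.

#' Gradient geometry of an assay plate
#'
#' @param axis Unit vector pointing toward the warm edge, in plate
#'   coordinates.
#' @param T_cold,T_warm Edge temperatures, degC (`T_cold < T_warm`).
#' @param steepness Gradient steepness, degC/cm (> 0). The default, 0.5
#'   degC/cm over a 23-28 degC range, is the self-consistent geometry for a
#'   10-cm plate.
#' @return A `gradient_geometry` object.
#' @export
gradient_geometry <- function(axis = c(1, 0), T_cold = 23, T_warm = 28,
                              steepness = 0.5) {
  if (T_cold >= T_warm) stop("T_cold must be below T_warm")
  if (steepness <= 0) stop("steepness must be positive")
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be a non-zero vector")
  structure(list(axis = axis / n, T_cold = T_cold, T_warm = T_warm,
                 steepness = steepness), class = "gradient_geometry")
}

geometry_from_plate <- function(plate) {
  gradient_geometry(axis = plate$axis, T_cold = plate$T_cold,
                    T_warm = plate$T_warm, steepness = plate$steepness)
}

#' Thermotaxis bias of a track
#'
#' Each inter-sample step is classified as toward-cold, toward-warm, or
#' neutral: steps slower than `speed_min` are neutral, and a moving step
#' counts as gradient-directed only if its displacement lies within
#' `angle_band` degrees of the (anti-)gradient axis. The bias is the
#' time-fraction difference
#' `(t_toward_cold - t_toward_warm) / (t_toward_cold + t_toward_warm)`,
#' a bounded, sign-symmetric statistic in `[-1, 1]` that recovers `2p - 1`
#' on a Bernoulli walk with cold-ward step probability `p`. Positive bias
#' means net movement toward colder temperatures, i.e. stronger negative
#' thermotaxis.
#'
#' @param track A `worm_track` (data.frame `t`, `x`, `y`; >= 2 samples).
#' @param geom A [gradient_geometry()]; default: the track's plate.
#' @param speed_min Speed threshold, mm/s (default 0.02).
#' @param angle_band Half-width of the angular band, degrees (default 45).
#' @return A `bias_result` list: `bias`, `t_toward_cold`, `t_toward_warm`,
#'   `t_neutral` (seconds; components sum to the track duration).
#' @export
thermotaxis_bias <- function(track, geom = NULL, speed_min = 0.02,
                             angle_band = 45) {
  if (nrow(track) < 2) stop("track must have at least 2 samples")
  if (is.null(geom)) {
    plate <- attr(track, "plate")
    geom <- if (!is.null(plate)) geometry_from_plate(plate) else gradient_geometry()
  }
  dt <- diff(track$t)
  if (any(dt <= 0)) stop("track times must be strictly increasing")
  dx <- diff(track$x)
  dy <- diff(track$y)
  disp <- sqrt(dx^2 + dy^2)
  speed <- disp / dt
  a <- geom$axis
  cosang <- ifelse(disp > 0, (dx * a[1] + dy * a[2]) / disp, 0)
  cb <- cos(angle_band * pi / 180)
  moving <- speed >= speed_min
  toward_warm <- moving & cosang >= cb
  toward_cold <- moving & cosang <= -cb
  t_cold <- sum(dt[toward_cold])
  t_warm <- sum(dt[toward_warm])
  t_neutral <- sum(dt) - t_cold - t_warm
  if (t_cold + t_warm == 0) {
    warning("no gradient-directed moving time: bias set to 0")
    bias <- 0
  } else {
    bias <- (t_cold - t_warm) / (t_cold + t_warm)
  }
  structure(list(bias = bias, t_toward_cold = t_cold, t_toward_warm = t_warm,
                 t_neutral = t_neutral), class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("thermotaxis bias %.3f (cold %gs, warm %gs, neutral %gs)\n",
              x$bias, x$t_toward_cold, x$t_toward_warm, x$t_neutral))
  invisible(x)
}

#' Grid exploration count
#'
#' Number of distinct grid squares entered by a track on a square arena:
#' cells are indexed by floor-division of position by the grid pitch, and
#' every cell crossed by the straight segment between consecutive samples is
#' counted (grid-line crossings are enumerated exactly, so refining the
#' sampling of the same geometric path cannot change the count). Positions
#' are clamped to the arena, so the count never exceeds `(arena / grid)^2`.
#'
#' @param track A `worm_track`.
#' @param grid Grid pitch, mm (default 3.5, the standard exploration-assay
#'   grid).
#' @param arena Arena side, mm (default 35, a standard small assay plate).
#' @return Integer count of visited squares (>= 1).
#' @export
exploration_count <- function(track, grid = 3.5, arena = 35) {
  if (grid <= 0 || arena <= 0) stop("grid and arena must be positive")
  nc <- as.integer(ceiling(arena / grid))
  eps <- arena * 1e-12
  x <- pmin(pmax(track$x, 0), arena - eps)
  y <- pmin(pmax(track$y, 0), arena - eps)
  visited <- matrix(FALSE, nc, nc)
  mark <- function(px, py) {
    i <- min(floor(px / grid), nc - 1)
    j <- min(floor(py / grid), nc - 1)
    visited[i + 1, j + 1] <<- TRUE
  }
  crossings <- function(p0, p1) {
    lo <- min(p0, p1); hi <- max(p0, p1)
    kl <- ceiling(lo / grid); kh <- floor(hi / grid)
    if (kh < kl) return(numeric(0))
    (seq(kl, kh) * grid - p0) / (p1 - p0)
  }
  mark(x[1], y[1])
  for (s in seq_len(nrow(track) - 1)) {
    x0 <- x[s]; y0 <- y[s]; x1 <- x[s + 1]; y1 <- y[s + 1]
    ts <- c(0, 1)
    if (x1 != x0) ts <- c(ts, crossings(x0, x1))
    if (y1 != y0) ts <- c(ts, crossings(y0, y1))
    ts <- sort(unique(pmin(pmax(ts, 0), 1)))
    mid <- (head(ts, -1) + ts[-1]) / 2
    for (tm in mid) mark(x0 + tm * (x1 - x0), y0 + tm * (y1 - y0))
    mark(x1, y1)
  }
  sum(visited)
}

#' Chemotaxis index
#'
#' The standard population index `(n_odorant - n_diluent) / n_total`, in
#' `[-1, 1]`: +1 when every animal reaches the odorant spot, -1 when every
#' animal reaches the diluent control.
#'
#' @param n_odorant,n_diluent,n_total Non-negative animal counts;
#'   `n_total > 0` and `n_odorant + n_diluent <= n_total`.
#' @return The index.
#' @examples
#' chemotaxis_index(60, 20, 100)  # 0.4
#' @export
chemotaxis_index <- function(n_odorant, n_diluent, n_total) {
  if (any(c(n_odorant, n_diluent, n_total) < 0)) {
    stop("counts must be non-negative")
  }
  if (n_total <= 0) stop("n_total must be positive")
  if (n_odorant + n_diluent > n_total) {
    stop("n_odorant + n_diluent cannot exceed n_total")
  }
  (n_odorant - n_diluent) / n_total
}

#' Per-track bias table for a set of tracks
#'
#' Convenience wrapper: computes [thermotaxis_bias()] for each track and
#' returns one row per track plus an assay-level aggregate attribute
#' (mean and SEM of per-track biases -- an assay is summarized by the mean
#' bias of its animals).
#'
#' @param tracks List of `worm_track` objects (optionally named).
#' @param ... Passed to [thermotaxis_bias()].
#' @return data.frame: `track`, `bias`, `t_toward_cold`, `t_toward_warm`,
#'   `t_neutral`; attributes `mean_bias`, `sem_bias`.
#' @export
assay_bias <- function(tracks, ...) {
  nm <- names(tracks)
  if (is.null(nm)) nm <- sprintf("track%03d", seq_along(tracks))
  rows <- lapply(seq_along(tracks), function(i) {
    b <- thermotaxis_bias(tracks[[i]], ...)
    data.frame(track = nm[i], bias = b$bias, t_toward_cold = b$t_toward_cold,
               t_toward_warm = b$t_toward_warm, t_neutral = b$t_neutral,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_bias") <- mean(out$bias)
  attr(out, "sem_bias") <- stats::sd(out$bias) / sqrt(nrow(out))
  out
}
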