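#' Default pixel scale of the tracking arena
#'
#' Microns per pixel of the worm tracker, derived from the equivalence
#' 1.17 pixels/s = 38.15 um/s used by the track-inclusion criterion.
#' @export
MICRONS_PER_PIXEL <- 38.15 / 1.17

#' Construct a worm track
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param x,y Centroid positions in pixels, finite.
#' @param track_id Identifier.
#' @param genotype Genotype label (optional).
#' @return An object of class `worm_track`.
#' @export
worm_track <- function(t, x, y, track_id = "track", genotype = NA_character_) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) < 2L)
    stop("track '", track_id, "': needs at least 2 samples")
  if (length(x) != length(t) || length(y) != length(t))
    stop("track '", track_id, "': t, x, y lengths differ")
  if (any(diff(t) <= 0))
    stop("track '", track_id, "': time must be strictly increasing")
  if (any(!is.finite(c(x, y))))
    stop("track '", track_id, "': coordinates must be finite")
  structure(list(track_id = as.character(track_id),
                 genotype = as.character(genotype), t = t, x = x, y = y),
            class = "worm_track")
}

#' @export
print.worm_track <- function(x, ...) {
  cat("<worm_track> ", x$track_id,
      if (!is.na(x$genotype)) paste0(" [", x$genotype, "]") else "",
      ": ", length(x$t), " samples, t = ", format(min(x$t)), "..",
      format(max(x$t)), " s\n", sep = "")
  invisible(x)
}

#' Instantaneous speed series of a track
#'
#' Euclidean displacement between consecutive samples divided by the time
#' step and converted to um/s; each speed is assigned to the later of the
#' two samples.
#'
#' @param track A `worm_track` (positions in pixels).
#' @param microns_per_pixel Pixel scale (default [MICRONS_PER_PIXEL]).
#' @return A data.frame with columns `t` (seconds, length n-1) and
#'   `speed` (um/s).
#' @export
speed_series <- function(track, microns_per_pixel = MICRONS_PER_PIXEL) {
  stopifnot(inherits(track, "worm_track"), microns_per_pixel > 0)
  dt <- diff(track$t)
  disp <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  data.frame(t = track$t[-1], speed = microns_per_pixel * disp / dt)
}

#' Heading-change series of a track
#'
#' The heading of each step is the angle of its displacement vector; the
#' heading change is the absolute angular difference between consecutive
#' headings, wrapped to [0, 180] degrees, divided by the time step.
#' Steps with zero displacement inherit the previous defined heading
#' (a pausing worm keeps its orientation); leading undefined headings
#' yield `NA` changes, except that a fully stationary track returns an
#' all-zero series. Each change is assigned to the later sample.
#'
#' @param track A `worm_track` with at least 3 samples.
#' @return A data.frame with columns `t` (length n-2) and `dps`
#'   (degrees per second).
#' @export
heading_change_series <- function(track) {
  stopifnot(inherits(track, "worm_track"))
  n <- length(track$t)
  if (n < 3L)
    stop("track '", track$track_id, "': needs at least 3 samples for headings")
  dx <- diff(track$x); dy <- diff(track$y)
  h <- atan2(dy, dx)
  h[dx == 0 & dy == 0] <- NA_real_
  if (all(is.na(h)))
    return(data.frame(t = track$t[-(1:2)], dps = rep(0, n - 2L)))
  # carry the last defined heading across pauses
  for (i in seq_along(h)[-1]) if (is.na(h[i])) h[i] <- h[i - 1]
  d <- abs(diff(h)) %% (2 * pi)
  d <- pmin(d, 2 * pi - d) * 180 / pi
  data.frame(t = track$t[-(1:2)], dps = d / diff(track$t)[-1])
}

#' Flag high-angle turns
#'
#' A high-angle turn is a change of direction of at least `threshold`
#' degrees per second (the boundary value counts as a turn).
#'
#' @param dps Heading-change rates in degrees/s (vector or the data.frame
#'   from [heading_change_series()]).
#' @param threshold Turn threshold in degrees/s (default 50).
#' @return Logical vector (`NA` where the heading change is undefined).
#' @export
detect_turns <- function(dps, threshold = 50) {
  if (is.data.frame(dps)) dps <- dps$dps
  dps >= threshold
}

#' Track quality control
#'
#' Retains tracks lasting at least `min_duration` seconds whose mean
#' instantaneous speed is at least `min_mean_speed` pixels/s; short or
#' slow objects are almost always debris or tracking artifacts rather
#' than worms.
#'
#' @param tracks A list of `worm_track` objects.
#' @param min_duration Minimum track duration in seconds (default 30).
#' @param min_mean_speed Minimum mean speed in pixels/s (default 1.17,
#'   i.e. 38.15 um/s at the default pixel scale).
#' @param microns_per_pixel Pixel scale (default [MICRONS_PER_PIXEL]).
#' @return The retained subset of `tracks` (same ordering).
#' @export
filter_tracks <- function(tracks, min_duration = 30, min_mean_speed = 1.17,
                          microns_per_pixel = MICRONS_PER_PIXEL) {
  keep <- vapply(tracks, function(tr) {
    dur <- tr$t[length(tr$t)] - tr$t[1]
    if (dur < min_duration) return(FALSE)
    sp <- speed_series(tr, microns_per_pixel)$speed / microns_per_pixel
    mean(sp) >= min_mean_speed
  }, logical(1))
  tracks[keep]
}

#' Population speed and turn-probability time series
#'
#' At each requested time point, averages the instantaneous speed of all
#' tracks with a sample there and computes the fraction of those tracks
#' executing a high-angle turn. Time points covered by no track yield
#' `NA`.
#'
#' @param tracks A list of `worm_track` objects.
#' @param time_grid Time points (seconds) at which to evaluate; tracks
#'   are matched to grid points within half a grid step.
#' @param microns_per_pixel Pixel scale (default [MICRONS_PER_PIXEL]).
#' @param turn_threshold Turn threshold in degrees/s (default 50).
#' @return A data.frame with columns `t`, `mean_speed` (um/s),
#'   `turn_probability`, `n_tracks`.
#' @export
population_series <- function(tracks, time_grid,
                              microns_per_pixel = MICRONS_PER_PIXEL,
                              turn_threshold = 50) {
  time_grid <- sort(as.numeric(time_grid))
  step <- if (length(time_grid) > 1L) min(diff(time_grid)) else 1
  tol <- step / 2
  ng <- length(time_grid)
  sp_sum <- sp_n <- tp_sum <- tp_n <- numeric(ng)
  grid_of <- function(tt) {
    i <- findInterval(tt, time_grid + tol) + 1L
    i[i > ng] <- NA_integer_
    off <- abs(tt - time_grid[pmin(i, ng)])
    i[is.na(i) | off > tol] <- NA_integer_
    i
  }
  for (tr in tracks) {
    sp <- speed_series(tr, microns_per_pixel)
    gi <- grid_of(sp$t)
    okv <- !is.na(gi)
    if (any(okv)) {
      sp_sum[gi[okv]] <- sp_sum[gi[okv]] + sp$speed[okv]
      sp_n[gi[okv]] <- sp_n[gi[okv]] + 1
    }
    if (length(tr$t) >= 3L) {
      hc <- heading_change_series(tr)
      turn <- detect_turns(hc$dps, turn_threshold)
      gi <- grid_of(hc$t)
      okv <- !is.na(gi) & !is.na(turn)
      if (any(okv)) {
        tp_sum[gi[okv]] <- tp_sum[gi[okv]] + as.numeric(turn[okv])
        tp_n[gi[okv]] <- tp_n[gi[okv]] + 1
      }
    }
  }
  data.frame(
    t = time_grid,
    mean_speed = ifelse(sp_n > 0, sp_sum / pmax(sp_n, 1), NA_real_),
    turn_probability = ifelse(tp_n > 0, tp_sum / pmax(tp_n, 1), NA_real_),
    n_tracks = as.integer(sp_n))
}

#' Locate the population extremum and build the quantification window
#'
#' Finds the time of minimum mean speed (or maximum turn probability)
#' within a stimulus window (inclusive endpoints; ties resolve to the
#' earliest point) and returns the asymmetric per-track quantification
#' window around it.
#'
#' @param series A data.frame from [population_series()].
#' @param stimulus_window `c(start, end)` in seconds, inclusive.
#' @param mode `"min_speed"` or `"max_turn"`.
#' @param before,after Seconds before/after the extremum (defaults 15
#'   and 17).
#' @return `c(start, end)` of the quantification window, with the
#'   extremum time attached as attribute `t_star`.
#' @export
extremum_window <- function(series, stimulus_window,
                            mode = c("min_speed", "max_turn"),
                            before = 15, after = 17) {
  mode <- match.arg(mode)
  idx <- which(series$t >= stimulus_window[1] & series$t <= stimulus_window[2])
  if (length(idx) == 0L)
    stop("stimulus window holds no time points of the series")
  v <- if (mode == "min_speed") series$mean_speed[idx]
       else series$turn_probability[idx]
  if (all(is.na(v)))
    stop("population series is all-NA within the stimulus window")
  i_star <- idx[if (mode == "min_speed") which.min(v) else which.max(v)]
  t_star <- series$t[i_star]
  structure(c(start = t_star - before, end = t_star + after),
            t_star = t_star)
}

#' Per-track mean metric over a quantification window
#'
#' A track "spans" the window when its first sample time is at or before
#' the window start and its last at or after the window end; only
#' spanning tracks are quantified. The metric is averaged over the
#' track's samples falling inside the window (inclusive endpoints).
#'
#' @param tracks A list of `worm_track` objects.
#' @param window `c(start, end)` in seconds (e.g. from
#'   [extremum_window()]).
#' @param metric `"speed"` (um/s) or `"turn"` (fraction of samples
#'   flagged as high-angle turns).
#' @param microns_per_pixel Pixel scale (default [MICRONS_PER_PIXEL]).
#' @param turn_threshold Turn threshold in degrees/s (default 50).
#' @return A data.frame with one row per spanning track: `track_id`,
#'   `genotype`, `value` (may have zero rows).
#' @export
per_track_window_mean <- function(tracks, window, metric = c("speed", "turn"),
                                  microns_per_pixel = MICRONS_PER_PIXEL,
                                  turn_threshold = 50) {
  metric <- match.arg(metric)
  rows <- lapply(tracks, function(tr) {
    n <- length(tr$t)
    if (!(tr$t[1] <= window[1] && tr$t[n] >= window[2])) return(NULL)
    if (metric == "speed") {
      s <- speed_series(tr, microns_per_pixel)
      v <- s$speed[s$t >= window[1] & s$t <= window[2]]
    } else {
      hc <- heading_change_series(tr)
      turn <- detect_turns(hc$dps, turn_threshold)
      v <- turn[hc$t >= window[1] & hc$t <= window[2]]
      v <- as.numeric(v[!is.na(v)])
    }
    if (length(v) == 0L) return(NULL)
    data.frame(track_id = tr$track_id, genotype = tr$genotype,
               value = mean(v), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(track_id = character(), genotype = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Chemotaxis avoidance index
#'
#' `AI = (n_air - n_co2) / (n_air + n_co2)`: +1 when every worm is on the
#' air side (complete avoidance of CO2), -1 when every worm is on the CO2
#' side, 0 for an even split.
#'
#' @param n_air Worms counted on the air side (vectorised over trials).
#' @param n_co2 Worms counted on the CO2 side.
#' @return Avoidance index in [-1, 1].
#' @export
#' @examples
#' avoidance_index(30, 10)  # 0.5
avoidance_index <- function(n_air, n_co2) {
  if (any(n_air < 0) || any(n_co2 < 0))
    stop("counts must be non-negative")
  tot <- n_air + n_co2
  if (any(tot == 0))
    stop("total worm count must be positive")
  (n_air - n_co2) / tot
}
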