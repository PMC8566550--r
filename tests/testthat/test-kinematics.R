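test_that("speed series converts pixel displacements to um/s", {
  # straight line at 1 px per 1 s step
  tr <- worm_track(t = 0:10, x = 0:10, y = rep(0, 11))
  s <- speed_series(tr)
  expect_equal(s$speed, rep(38.15 / 1.17, 10))
  expect_equal(s$t, 1:10)

  # stationary worm
  tr0 <- worm_track(t = 0:5, x = rep(2, 6), y = rep(3, 6))
  expect_equal(speed_series(tr0)$speed, rep(0, 5))

  # rigid-body invariance and linear scaling with the pixel scale
  set.seed(3)
  x <- cumsum(rnorm(20)); y <- cumsum(rnorm(20))
  tr1 <- worm_track(t = 1:20, x = x, y = y)
  th <- 0.7
  tr2 <- worm_track(t = 1:20, x = 5 + x * cos(th) - y * sin(th),
                    y = -2 + x * sin(th) + y * cos(th))
  expect_equal(speed_series(tr1)$speed, speed_series(tr2)$speed,
               tolerance = 1e-9)
  expect_equal(speed_series(tr1, 10)$speed * 2, speed_series(tr1, 20)$speed)
})

test_that("heading changes are wrapped to [0, 180] and rated per second", {
  # straight line: no heading change
  tr <- worm_track(t = 0:10, x = 0:10, y = rep(0, 11))
  expect_equal(heading_change_series(tr)$dps, rep(0, 9))

  # right-angle turn over one 1 s step
  tr <- worm_track(t = 0:2, x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(heading_change_series(tr)$dps, 90)

  # reversal (180 deg) at 2 s sampling: 90 deg/s
  tr <- worm_track(t = c(0, 2, 4), x = c(0, 1, 0), y = c(0, 0, 0))
  expect_equal(heading_change_series(tr)$dps, 90)

  # pauses inherit the previous heading; fully stationary tracks are zero
  tr <- worm_track(t = 0:3, x = c(0, 1, 1, 2), y = rep(0, 4))
  expect_equal(heading_change_series(tr)$dps, c(0, 0))
  tr0 <- worm_track(t = 0:3, x = rep(1, 4), y = rep(1, 4))
  expect_equal(heading_change_series(tr0)$dps, rep(0, 2))
})

test_that("high-angle turn detection is inclusive at the threshold", {
  expect_identical(detect_turns(c(60, 49, 50, 0)), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("track retention needs 30 s duration and 1.17 px/s mean speed", {
  mk <- function(dur, px_per_s, id) {
    t <- seq(0, dur)
    worm_track(t = t, x = t * px_per_s, y = rep(0, length(t)), track_id = id)
  }
  tracks <- list(mk(29, 2, "short"), mk(40, 2, "good"), mk(40, 1.0, "slow"),
                 mk(40, 1.17, "boundary"))
  kept <- filter_tracks(tracks)
  expect_identical(vapply(kept, `[[`, character(1), "track_id"),
                   c("good", "boundary"))
  # idempotence
  expect_identical(filter_tracks(kept), kept)
})

test_that("population series matches a brute-force per-point census", {
  set.seed(17)
  tracks <- gen_tracks(n_worms = 8, duration = 60, stagger = 20,
                       stimulus_windows = list(c(20, 40)), seed = 17)
  grid <- 0:60
  pop <- population_series(tracks, grid)
  # brute force: census each grid point over all tracks
  for (g in c(5, 25, 47)) {
    speeds <- c(); turns <- c()
    for (tr in tracks) {
      s <- speed_series(tr)
      i <- which(abs(s$t - g) < 0.5)
      if (length(i) == 1) speeds <- c(speeds, s$speed[i])
      hc <- heading_change_series(tr)
      j <- which(abs(hc$t - g) < 0.5)
      if (length(j) == 1 && !is.na(hc$dps[j]))
        turns <- c(turns, hc$dps[j] >= 50)
    }
    i_g <- which(pop$t == g)
    expect_equal(pop$n_tracks[i_g], length(speeds))
    if (length(speeds)) expect_equal(pop$mean_speed[i_g], mean(speeds))
    if (length(turns))
      expect_equal(pop$turn_probability[i_g], mean(turns))
  }
  expect_true(all(pop$turn_probability >= 0 & pop$turn_probability <= 1,
                  na.rm = TRUE))
  expect_true(all(pop$mean_speed >= 0, na.rm = TRUE))
})

test_that("extremum window is t* - 15 to t* + 17 with earliest-tie rule", {
  # V-shaped speed series with the minimum at t = 100
  t <- 0:200
  series <- data.frame(t = t, mean_speed = abs(t - 100) + 10,
                       turn_probability = 0, n_tracks = 5)
  w <- extremum_window(series, c(50, 150), "min_speed")
  expect_equal(as.numeric(w), c(85, 117))
  expect_equal(attr(w, "t_star"), 100, ignore_attr = TRUE)

  # flat series: earliest point of the stimulus window wins
  series$mean_speed <- 7
  w <- extremum_window(series, c(50, 150), "min_speed")
  expect_equal(attr(w, "t_star"), 50)

  # injected turn-probability peak is recovered
  series$turn_probability[t == 123] <- 0.9
  w <- extremum_window(series, c(50, 150), "max_turn")
  expect_equal(attr(w, "t_star"), 123)
  expect_error(extremum_window(series, c(300, 400), "min_speed"),
               "no time points")
})

test_that("per-track window means include only tracks spanning the window", {
  mk <- function(t0, t1, v_px, id) {
    t <- t0:t1
    worm_track(t = t, x = (t - t0) * v_px, y = rep(0, length(t)),
               track_id = id)
  }
  scale <- 10
  tracks <- list(mk(0, 100, 2, "full"), mk(40, 60, 2, "partial"))
  out <- per_track_window_mean(tracks, c(30, 62), "speed",
                               microns_per_pixel = scale)
  expect_identical(out$track_id, "full")
  expect_equal(out$value, 20)

  # turn metric is the count of flagged samples over the samples in window:
  # a zigzag with exactly 8 right-angle direction changes
  n_step <- 320
  dirs <- rep(rep(c(0, pi / 2), length.out = 9), times = c(rep(36, 8), 32))
  trk <- worm_track(t = 0:n_step, x = cumsum(c(0, cos(dirs))),
                    y = cumsum(c(0, sin(dirs))), track_id = "zig")
  hc <- heading_change_series(trk)
  flags <- detect_turns(hc$dps)
  expect_equal(sum(flags), 8)
  out <- per_track_window_mean(list(trk), c(2, 320), "turn")
  expect_equal(out$value, 8 / length(flags))

  # no spanning tracks: empty result
  out <- per_track_window_mean(tracks, c(-10, 200), "speed")
  expect_equal(nrow(out), 0)
})

test_that("the avoidance index is the signed fraction preferring air", {
  expect_equal(avoidance_index(30, 10), 0.5)
  expect_equal(avoidance_index(20, 20), 0)
  expect_equal(avoidance_index(40, 0), 1)
  expect_error(avoidance_index(0, 0), "positive")
  expect_error(avoidance_index(-1, 5), "non-negative")

  # antisymmetry and range over random counts
  set.seed(23)
  a <- rpois(50, 20); b <- rpois(50, 20)
  keep <- a + b > 0
  ai <- avoidance_index(a[keep], b[keep])
  expect_equal(ai, -avoidance_index(b[keep], a[keep]))
  expect_true(all(ai >= -1 & ai <= 1))
})
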