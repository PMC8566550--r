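#' @noRd
# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards so simulation helpers do not perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# First-order relaxation of a signal toward a piecewise-constant target.
# tau <= 0 gives instantaneous kinetics.
relax_to_target <- function(target, dt, tau) {
  if (tau <= 0) return(target)
  a <- 1 - exp(-dt / tau)
  x <- numeric(length(target))
  x[1] <- target[1]
  for (i in seq_along(target)[-1]) x[i] <- x[i - 1] + a * (target[i] - x[i - 1])
  x
}

#' Generate a synthetic pHluorin calibration recording
#'
#' Simulates one punctum's raw-fluorescence trace through an NH4Cl pulse
#' and a MES pulse. The dF/F plateaus are set by the forward calibration
#' model at the requested ground-truth lumenal pH and surface fraction
#' (gamma during NH4Cl, -epsilon during MES), approached with first-order
#' kinetics, with i.i.d. Gaussian noise added in dF/F units. The raw
#' trace is `F = F0 * (1 + dff)`.
#'
#' @param pH_true Ground-truth lumenal pH (between `pH_acid` and
#'   `pH_external`).
#' @param SF_true Ground-truth surface fraction in (0, 1).
#' @param seed RNG seed (restored on exit).
#' @param constants A [ph_constants()] object.
#' @param dt Sampling interval in seconds (default 0.1).
#' @param noise_sd Gaussian noise SD in dF/F units (default 0.02).
#' @param tau Response time constant in seconds (default 1; 0 for
#'   instantaneous).
#' @param nh4_window,mes_window Application windows in seconds within the
#'   trace (defaults 20-60 and 80-140).
#' @param duration Total trace length in seconds (default 160).
#' @param F0 Baseline fluorescence in arbitrary units (default 100).
#' @param trace_id,genotype Labels for the trace.
#' @return A `sensor_trace` with raw `F`; the ground truth (`pH`, `SF`,
#'   `gamma`, `epsilon`) and the application windows are attached as
#'   attributes `ground_truth` and `windows`.
#' @export
gen_calibration_experiment <- function(pH_true, SF_true, seed = 1,
                                       constants = ph_constants(),
                                       dt = 0.1, noise_sd = 0.02, tau = 1,
                                       nh4_window = c(20, 60),
                                       mes_window = c(80, 140),
                                       duration = 160, F0 = 100,
                                       trace_id = "cal", genotype = NA) {
  stopifnot(noise_sd >= 0, pH_true > constants$pH_acid - 1.5,
            pH_true < constants$pH_external, SF_true > 0, SF_true < 1)
  cal <- forward_calibration(pH_true, SF_true, constants)
  t <- seq(0, duration, by = dt)
  target <- numeric(length(t))
  target[t >= nh4_window[1] & t < nh4_window[2]] <- cal$gamma
  target[t >= mes_window[1] & t < mes_window[2]] <- -cal$epsilon
  dff <- relax_to_target(target, dt, tau)
  dff <- with_seed(seed, dff + stats::rnorm(length(t), sd = noise_sd))
  tr <- sensor_trace(t = t, F = pmax(F0 * (1 + dff), 0), trace_id = trace_id,
                     genotype = genotype)
  attr(tr, "ground_truth") <- list(pH = pH_true, SF = SF_true,
                                   gamma = cal$gamma, epsilon = cal$epsilon)
  attr(tr, "windows") <- list(baseline = c(0, nh4_window[1]),
                              nh4 = nh4_window, mes = mes_window)
  tr
}

#' Generate a synthetic evoked-response dF/F trace
#'
#' Baseline zero with Gaussian noise; a stimulus step of the requested
#' amplitude with first-order onset kinetics, held for `stim_duration`
#' seconds and relaxing back afterwards. An optional pre-stimulus
#' transient (a Gaussian bump, emulating a movement artifact) can be
#' injected for testing the calcium exclusion gate.
#'
#' @param amplitude Response plateau in dF/F units (0 for a null trace).
#' @param seed RNG seed (restored on exit).
#' @param onset Stimulus onset in seconds (default 10).
#' @param stim_duration Stimulus duration in seconds (default 10).
#' @param duration Total trace length in seconds (default 30).
#' @param dt Sampling interval in seconds (default 0.1).
#' @param noise_sd Gaussian noise SD in dF/F units (default 0.02).
#' @param tau Response time constant in seconds (default 1).
#' @param transient Optional list with `amplitude`, `time` and `width`
#'   (seconds; default width 0.5) describing a Gaussian artifact added
#'   before the stimulus.
#' @param trace_id,genotype Labels for the trace.
#' @return A `sensor_trace` with `dff` populated; ground truth attached
#'   as attribute `ground_truth`.
#' @export
gen_response_trace <- function(amplitude, seed = 1, onset = 10,
                               stim_duration = 10, duration = 30, dt = 0.1,
                               noise_sd = 0.02, tau = 1, transient = NULL,
                               trace_id = "resp", genotype = NA) {
  stopifnot(noise_sd >= 0, onset >= 0, onset < duration)
  t <- seq(0, duration, by = dt)
  target <- ifelse(t >= onset & t < onset + stim_duration, amplitude, 0)
  dff <- relax_to_target(target, dt, tau)
  if (!is.null(transient)) {
    w <- if (is.null(transient$width)) 0.5 else transient$width
    dff <- dff + transient$amplitude * exp(-((t - transient$time) / w)^2 / 2)
  }
  dff <- with_seed(seed, dff + stats::rnorm(length(t), sd = noise_sd))
  tr <- sensor_trace(t = t, dff = dff, trace_id = trace_id,
                     genotype = genotype)
  attr(tr, "ground_truth") <- list(amplitude = amplitude,
                                   transient = transient)
  tr
}

#' Generate synthetic worm tracks with a stimulus-evoked slowdown
#'
#' Correlated random walks: each worm draws a per-step speed around the
#' active regime's target (baseline outside the stimulus windows,
#' stimulus speed inside, with a shallow quadratic bowl so the population
#' minimum sits mid-window), a slowly diffusing heading, and Poisson turn
#' events that jump the heading by at least 60 degrees at the active
#' regime's rate. Track starts and ends are staggered by a few seconds to
#' exercise window-spanning rules.
#'
#' @param n_worms Number of tracks (default 50).
#' @param seed RNG seed (restored on exit).
#' @param v_baseline,v_stimulus Target speeds in um/s (defaults 150, 60).
#' @param turn_rate_baseline,turn_rate_stimulus Turn-event rates in
#'   events/s (defaults 0.05, 0.25).
#' @param stimulus_windows List of `c(start, end)` windows in seconds
#'   during which the stimulus regime is active (default one window
#'   60-180 s).
#' @param duration Recording length in seconds (default 240).
#' @param dt Sampling interval in seconds (default 1).
#' @param speed_jitter_sd Per-step speed SD in um/s (default 20).
#' @param worm_speed_sd SD of the per-worm speed offset in um/s
#'   (default 10): individual worms crawl systematically faster or slower
#'   than the population target, as real animals do, so per-track window
#'   means carry genuine between-animal variance.
#' @param bowl_depth Extra speed at the stimulus-window edges relative to
#'   its center, in um/s (default 15); anchors the population speed
#'   minimum at the window center.
#' @param stagger Maximum random trim of each track's start and end, in
#'   seconds (default 10).
#' @param heading_sd Heading diffusion SD in degrees per step (default 10).
#' @param microns_per_pixel Pixel scale used to convert to pixel
#'   coordinates (default [MICRONS_PER_PIXEL]).
#' @param genotype Label applied to all tracks.
#' @return A list of `worm_track` objects; ground truth attached as
#'   attribute `ground_truth`.
#' @export
gen_tracks <- function(n_worms = 50, seed = 1, v_baseline = 150,
                       v_stimulus = 60, turn_rate_baseline = 0.05,
                       turn_rate_stimulus = 0.25,
                       stimulus_windows = list(c(60, 180)), duration = 240,
                       dt = 1, speed_jitter_sd = 20, worm_speed_sd = 10,
                       bowl_depth = 15, stagger = 10, heading_sd = 10,
                       microns_per_pixel = MICRONS_PER_PIXEL,
                       genotype = NA) {
  stopifnot(v_baseline >= 0, v_stimulus >= 0, turn_rate_baseline >= 0,
            turn_rate_stimulus >= 0)
  grid <- seq(0, duration, by = dt)
  in_stim <- function(tt) {
    hit <- rep(FALSE, length(tt))
    for (w in stimulus_windows) hit <- hit | (tt >= w[1] & tt <= w[2])
    hit
  }
  target_speed <- function(tt) {
    v <- rep(v_baseline, length(tt))
    for (w in stimulus_windows) {
      inside <- tt >= w[1] & tt <= w[2]
      c0 <- mean(w); hw <- diff(w) / 2
      v[inside] <- v_stimulus + bowl_depth * ((tt[inside] - c0) / hw)^2
    }
    v
  }
  tracks <- with_seed(seed, lapply(seq_len(n_worms), function(i) {
    i0 <- 1L + sample.int(max(1L, round(stagger / dt) + 1L), 1L) - 1L
    i1 <- length(grid) - (sample.int(max(1L, round(stagger / dt) + 1L), 1L) - 1L)
    tt <- grid[i0:i1]
    n <- length(tt)
    v_offset <- stats::rnorm(1, sd = worm_speed_sd)
    v <- pmax(target_speed(tt[-1]) + v_offset +
                stats::rnorm(n - 1L, sd = speed_jitter_sd), 0)
    rate <- ifelse(in_stim(tt[-1]), turn_rate_stimulus, turn_rate_baseline)
    turn <- stats::runif(n - 1L) < rate * dt
    dh <- stats::rnorm(n - 1L, sd = heading_sd * pi / 180)
    jump <- stats::runif(n - 1L, 60, 180) * pi / 180 *
      sample(c(-1, 1), n - 1L, replace = TRUE)
    dh[turn] <- dh[turn] + jump[turn]
    h <- cumsum(c(stats::runif(1, 0, 2 * pi), dh))[-1]
    step_px <- v * dt / microns_per_pixel
    x <- cumsum(c(stats::runif(1, 0, 100), step_px * cos(h)))
    y <- cumsum(c(stats::runif(1, 0, 100), step_px * sin(h)))
    worm_track(t = tt, x = x, y = y, track_id = sprintf("w%03d", i),
               genotype = genotype)
  }))
  attr(tracks, "ground_truth") <- list(
    v_baseline = v_baseline, v_stimulus = v_stimulus,
    turn_rate_baseline = turn_rate_baseline,
    turn_rate_stimulus = turn_rate_stimulus,
    stimulus_windows = stimulus_windows, dt = dt)
  tracks
}

#' Generate synthetic chemotaxis count data
#'
#' Each trial places `n_worms` worms independently on the air side with
#' probability `p_air`; the expected avoidance index is `2 p_air - 1`.
#'
#' @param n_worms Worms per trial (default 40).
#' @param p_air Per-worm probability of ending on the air side.
#' @param n_trials Number of trials (default 10).
#' @param seed RNG seed (restored on exit).
#' @param genotype Label applied to all trials.
#' @return A data.frame with columns `trial_id`, `genotype`, `n_air`,
#'   `n_co2`.
#' @export
gen_chemotaxis_counts <- function(n_worms = 40, p_air = 0.5, n_trials = 10,
                                  seed = 1, genotype = NA) {
  stopifnot(p_air >= 0, p_air <= 1, n_worms >= 1, n_trials >= 1)
  n_air <- with_seed(seed, stats::rbinom(n_trials, n_worms, p_air))
  data.frame(trial_id = sprintf("trial%03d", seq_len(n_trials)),
             genotype = as.character(genotype),
             n_air = n_air, n_co2 = n_worms - n_air,
             stringsAsFactors = FALSE)
}
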