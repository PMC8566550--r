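#' Normalise a raw fluorescence trace to dF/F
#'
#' Subtracts the per-sample background (when present), averages the
#' background-subtracted fluorescence over the baseline window to obtain F0,
#' and returns a new trace carrying `dff = (F' - F0) / F0`.
#'
#' @param trace A `sensor_trace` with raw `F` populated.
#' @param baseline A `time_window` (or `c(start, end)`) over which F0 is
#'   computed; must contain at least 2 samples.
#' @return A `sensor_trace` with `dff` populated and the same time base.
#' @export
#' @examples
#' tr <- sensor_trace(t = seq(0, 2, 0.1), F = c(rep(10, 11), rep(25, 10)))
#' round(delta_f_over_f(tr, c(0, 1))$dff[15], 3)
delta_f_over_f <- function(trace, baseline) {
  stopifnot(inherits(trace, "sensor_trace"))
  if (is.null(trace$F))
    stop("trace '", trace$trace_id, "': delta_f_over_f needs raw F")
  Fp <- trace$F
  if (!is.null(trace$F_bg)) Fp <- Fp - trace$F_bg
  idx <- window_index(trace$t, baseline)
  if (length(idx) < 2L)
    stop("baseline window holds fewer than 2 samples")
  F0 <- mean(Fp[idx])
  if (!is.finite(F0) || F0 <= 0)
    stop("trace '", trace$trace_id, "': degenerate baseline (F0 = ",
         format(F0), " <= 0); cannot normalise")
  out <- trace
  out$dff <- (Fp - F0) / F0
  out
}

#' Centered moving-average filter
#'
#' Boxcar smoothing used throughout the sensor analyses (1 s for responder
#' gating, 0.5 s for calcium pre-stimulus screening, 5 s for calibration
#' amplitude measurement). The filter is centered; the number of taps is
#' `floor(width / dt)` rounded down to the nearest odd count (at least 1),
#' and the window shrinks symmetrically at the trace edges so the output has
#' the input's length.
#'
#' @param trace A `sensor_trace` (either signal).
#' @param width Filter width in seconds; must be at least the sampling
#'   interval.
#' @return A `sensor_trace` with the primary signal smoothed.
#' @export
moving_average <- function(trace, width) {
  stopifnot(inherits(trace, "sensor_trace"))
  dt <- trace_dt(trace)
  if (width < dt - 1e-12)
    stop("filter width ", width, " s is below the sampling interval ",
         signif(dt, 6), " s")
  n_tap <- floor(width / dt + 1e-9)
  if (n_tap %% 2L == 0L) n_tap <- n_tap - 1L
  n_tap <- max(n_tap, 1L)
  out <- trace
  sig <- if (!is.null(trace$dff)) "dff" else "F"
  out[[sig]] <- running_mean(trace[[sig]], n_tap)
  out
}

# Centered running mean over n_tap (odd) samples with edge truncation.
running_mean <- function(x, n_tap) {
  if (n_tap == 1L) return(x)
  n <- length(x)
  h <- (n_tap - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Baseline mean, SD and mode of a dF/F trace
#'
#' The mode is estimated by histogram binning: bins of width `mode_bin`
#' span the data range within the window, and the center of the most
#' populated bin is returned (ties go to the lowest bin). The mode is the
#' preferred baseline for calcium recordings, where a movement transient
#' inflates both the mean and the SD of the pre-stimulus period.
#'
#' @param trace A `sensor_trace` with `dff`.
#' @param window Baseline `time_window`; needs at least 2 samples.
#' @param mode_bin Histogram bin width in dF/F units (default 0.01).
#' @return A list with `mean`, `sd` (sample SD, n-1 denominator) and `mode`.
#' @export
baseline_stats <- function(trace, window, mode_bin = 0.01) {
  stopifnot(mode_bin > 0)
  x <- window_values(trace, window, "dff", min_n = 2L)
  list(mean = mean(x), sd = stats::sd(x), mode = binned_mode(x, mode_bin))
}

# Histogram-mode estimator: bins of fixed width from min(x); ties -> lowest.
binned_mode <- function(x, bin) {
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[1])))
    return(rng[1])
  k <- pmin(floor((x - rng[1]) / bin), ceiling((rng[2] - rng[1]) / bin) - 1)
  counts <- table(k)
  k_star <- as.numeric(names(counts)[which.max(counts)])
  rng[1] + (k_star + 0.5) * bin
}

#' Gate a trace on baseline fluorescence versus background
#'
#' ROIs whose baseline fluorescence sits close to the background level
#' produce dF/F values too noisy to analyse. A trace is kept only when its
#' mean raw fluorescence over the window strictly exceeds the background
#' trace's mean + `k` SD over the same window; equality excludes.
#'
#' @param trace A `sensor_trace` with raw `F`.
#' @param background_trace A `sensor_trace` with raw `F` on the same time
#'   base (an ROI placed outside the cell).
#' @param window The baseline `time_window` (typically 0-10 s).
#' @param k SD multiplier (default 3).
#' @return `TRUE` to keep the trace, `FALSE` to exclude it.
#' @export
above_background_gate <- function(trace, background_trace, window, k = 3) {
  f <- window_values(trace, window, "F", min_n = 2L)
  b <- window_values(background_trace, window, "F", min_n = 2L)
  mean(f) > mean(b) + k * stats::sd(b)
}

#' Classify a trace as stimulus responder or non-responder
#'
#' The trace is smoothed with a centered moving average of `filter_width`,
#' then the extremum of the smoothed signal over the response window is
#' compared against the smoothed baseline mean +/- `k` SD. For
#' `direction = "increase"` the call is responder when
#' `max(response) > mean + k * sd`; for `"decrease"` when
#' `min(response) < mean - k * sd` (used for acid-quench responses).
#'
#' @param trace A `sensor_trace` with `dff`.
#' @param baseline Baseline `time_window` (typically 0-10 s).
#' @param response Response `time_window` (typically 10-20 s).
#' @param filter_width Moving-average width in seconds (default 1).
#' @param k SD multiplier (default 3).
#' @param direction `"increase"` or `"decrease"`.
#' @param above_background Result of the raw-fluorescence gate for this
#'   trace, when available upstream; a trace failing that gate is never a
#'   responder and is flagged with reason `"below_background"`.
#' @return A list of class `responder_call` with fields `trace_id`,
#'   `above_background`, `responder`, `peak_value`, `peak_time`, `reason`.
#' @export
classify_responder <- function(trace, baseline, response, filter_width = 1,
                               k = 3, direction = c("increase", "decrease"),
                               above_background = TRUE) {
  direction <- match.arg(direction)
  sm <- moving_average(trace, filter_width)
  bl <- window_values(sm, baseline, "dff", min_n = 2L)
  idx <- window_index(sm$t, response)
  if (length(idx) == 0L)
    stop("response window holds no samples of trace '", trace$trace_id, "'")
  resp <- sm$dff[idx]
  if (direction == "increase") {
    i_pk <- idx[which.max(resp)]
    hit <- max(resp) > mean(bl) + k * stats::sd(bl)
  } else {
    i_pk <- idx[which.min(resp)]
    hit <- min(resp) < mean(bl) - k * stats::sd(bl)
  }
  responder <- isTRUE(above_background) && hit
  reason <- if (!isTRUE(above_background)) "below_background"
            else if (!hit) "no_response" else "none"
  structure(
    list(trace_id = trace$trace_id, above_background = isTRUE(above_background),
         responder = responder, peak_value = sm$dff[i_pk],
         peak_time = sm$t[i_pk], reason = reason),
    class = "responder_call")
}

#' @export
print.responder_call <- function(x, ...) {
  cat("<responder_call> ", x$trace_id, ": ",
      if (x$responder) "responder" else paste0("non-responder (", x$reason, ")"),
      ", peak ", signif(x$peak_value, 4), " dF/F at ", x$peak_time, " s\n",
      sep = "")
  invisible(x)
}

#' Scalar response metric over a window
#'
#' Computes the trapezoidal area under the curve (dF/F * s), or the maximum
#' or minimum of dF/F, over a window of the raw (unfiltered) trace.
#' Quantification deliberately uses the unfiltered signal; smoothing is
#' reserved for classification thresholds.
#'
#' @param trace A `sensor_trace` with `dff`.
#' @param window The `time_window` to quantify (e.g. 10-20 s for
#'   depolarisation-evoked release, 10-15 s for CO2 presentation).
#' @param kind One of `"auc"`, `"max"`, `"min"`.
#' @return A single numeric value.
#' @export
window_metric <- function(trace, window, kind = c("auc", "max", "min")) {
  kind <- match.arg(kind)
  if (is.null(trace$dff))
    stop("trace '", trace$trace_id, "': dff is not populated")
  idx <- window_index(trace$t, window)
  if (length(idx) == 0L)
    stop("window holds no samples of trace '", trace$trace_id, "'")
  x <- trace$dff[idx]
  switch(kind,
    auc = if (length(idx) < 2L) 0 else
      sum(diff(trace$t[idx]) * (x[-1] + x[-length(x)]) / 2),
    max = max(x),
    min = min(x))
}

#' Pre-stimulus motion-transient exclusion for calcium traces
#'
#' Recordings occasionally show large stimulus-independent fluorescence
#' increases during the pre-stimulus period (movement artifacts). Each
#' trace is smoothed (default 0.5 s), and a trace is excluded when its
#' smoothed baseline maximum exceeds its own baseline mode + `k` times a
#' pooled SD. The pooled SD is the mean of the smoothed-baseline SDs of all
#' traces in the same genotype group: an artifact inflates the individual
#' trace's own SD (and mean), which would mask the artifact if used
#' directly.
#'
#' @param traces A list of `sensor_trace` objects with `dff`.
#' @param baseline Baseline `time_window` (default 0-10 s).
#' @param filter_width Smoothing width in seconds (default 0.5).
#' @param k SD multiplier (default 5).
#' @param mode_bin Histogram bin width for the baseline mode (default 0.01).
#' @param genotype Optional character vector of group labels, one per
#'   trace; defaults to each trace's own `genotype` field. The pooled SD is
#'   computed within each group.
#' @return A data.frame with one row per trace: `trace_id`, `genotype`,
#'   `baseline_max`, `mode`, `pooled_sd`, `keep`.
#' @export
gcamp_prestimulus_exclusion <- function(traces, baseline = c(0, 10),
                                        filter_width = 0.5, k = 5,
                                        mode_bin = 0.01, genotype = NULL) {
  stopifnot(length(traces) >= 1L)
  if (is.null(genotype))
    genotype <- vapply(traces, function(tr) tr$genotype, character(1))
  stopifnot(length(genotype) == length(traces))
  sm <- lapply(traces, moving_average, width = filter_width)
  bl <- lapply(sm, window_values, window = baseline, signal = "dff",
               min_n = 2L)
  sds <- vapply(bl, stats::sd, numeric(1))
  pooled <- stats::ave(sds, genotype, FUN = mean)
  maxs <- vapply(bl, max, numeric(1))
  modes <- vapply(bl, binned_mode, numeric(1), bin = mode_bin)
  data.frame(
    trace_id = vapply(traces, function(tr) tr$trace_id, character(1)),
    genotype = as.character(genotype),
    baseline_max = maxs, mode = modes, pooled_sd = pooled,
    keep = !(maxs > modes + k * pooled),
    stringsAsFactors = FALSE)
}

#' Expression-normalised baseline fluorescence
#'
#' Mean background-subtracted fluorescence over the pre-stimulus window,
#' divided by the excitation light intensity; used to compare sensor
#' expression levels between cells imaged at different illumination.
#'
#' @param trace A `sensor_trace` with raw `F` (background subtracted via
#'   `F_bg` when present).
#' @param baseline The pre-stimulus `time_window`.
#' @param excitation_intensity Excitation intensity (> 0); defaults to the
#'   trace's own `excitation` field.
#' @return A single numeric value (fluorescence per intensity unit).
#' @export
normalize_expression <- function(trace, baseline,
                                 excitation_intensity = trace$excitation) {
  if (!is.finite(excitation_intensity) || excitation_intensity <= 0)
    stop("excitation intensity must be positive")
  Fp <- window_values(trace, baseline, "F", min_n = 1L)
  if (!is.null(trace$F_bg))
    Fp <- Fp - trace$F_bg[window_index(trace$t, baseline)]
  mean(Fp) / excitation_intensity
}

#' Rank traces by mean dF/F over a window
#'
#' Stable descending order of the traces by their mean dF/F over the
#' window, as used to sort single-trial colormap rows; ties keep the input
#' order.
#'
#' @param traces A list of `sensor_trace` objects with `dff`.
#' @param window The ranking `time_window` (e.g. 10-15 s).
#' @return Integer permutation such that `traces[order]` is descending.
#' @export
rank_traces <- function(traces, window) {
  m <- vapply(traces, function(tr) mean(window_values(tr, window, "dff")),
              numeric(1))
  order(-m)  # base order() is stable; ties keep input order
}
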