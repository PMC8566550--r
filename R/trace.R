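#' Construct a sensor fluorescence trace
#'
#' A `sensor_trace` holds one uniformly sampled fluorescence time series for
#' a single region of interest (a synaptic punctum, a soma, or a neurite
#' segment), either as raw fluorescence `F` (arbitrary units) or as a
#' normalised `dff` (dF/F) signal. Exactly one of `F` and `dff` must be
#' supplied as the primary signal; an optional per-sample background trace
#' `F_bg` can accompany raw fluorescence.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing
#'   with constant spacing (default acquisition interval is 0.1 s).
#' @param F Raw fluorescence values (arbitrary units, non-negative), or
#'   `NULL` if `dff` is given.
#' @param dff dF/F values (dimensionless, may be negative), or `NULL` if
#'   `F` is given.
#' @param trace_id Identifier for the ROI/punctum.
#' @param genotype Genotype label (optional).
#' @param F_bg Optional per-sample background fluorescence, same length as
#'   `t`.
#' @param excitation Optional excitation light intensity (arbitrary units),
#'   used for expression normalisation.
#'
#' @return An object of class `sensor_trace`.
#' @export
#' @examples
#' tr <- sensor_trace(t = seq(0, 1, by = 0.1), F = rep(10, 11), trace_id = "p1")
#' tr
sensor_trace <- function(t, F = NULL, dff = NULL, trace_id = "trace",
                         genotype = NA_character_, F_bg = NULL,
                         excitation = NA_real_) {
  t <- as.numeric(t)
  if (length(t) < 2L)
    stop("trace '", trace_id, "': needs at least 2 samples")
  dt <- diff(t)
  if (any(dt <= 0))
    stop("trace '", trace_id, "': time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9)
    stop("trace '", trace_id, "': sampling must be uniform (ragged spacing)")
  if (is.null(F) == is.null(dff))
    stop("trace '", trace_id, "': exactly one of F and dff must be supplied")
  if (!is.null(F)) {
    F <- as.numeric(F)
    if (length(F) != length(t))
      stop("trace '", trace_id, "': F and t lengths differ")
    if (any(!is.finite(F)) || any(F < 0))
      stop("trace '", trace_id, "': F must be finite and non-negative")
  }
  if (!is.null(dff)) {
    dff <- as.numeric(dff)
    if (length(dff) != length(t))
      stop("trace '", trace_id, "': dff and t lengths differ")
    if (any(!is.finite(dff)))
      stop("trace '", trace_id, "': dff must be finite")
  }
  if (!is.null(F_bg)) {
    F_bg <- as.numeric(F_bg)
    if (length(F_bg) != length(t))
      stop("trace '", trace_id, "': F_bg and t lengths differ")
  }
  structure(
    list(trace_id = as.character(trace_id), genotype = as.character(genotype),
         t = t, F = F, dff = dff, F_bg = F_bg,
         excitation = as.numeric(excitation)),
    class = "sensor_trace")
}

#' @export
print.sensor_trace <- function(x, ...) {
  sig <- if (!is.null(x$F)) "raw F" else "dF/F"
  cat("<sensor_trace> ", x$trace_id,
      if (!is.na(x$genotype)) paste0(" [", x$genotype, "]") else "",
      "\n", sep = "")
  cat("  ", length(x$t), " samples, t = ", format(min(x$t)), "..",
      format(max(x$t)), " s (dt = ", format(signif(trace_dt(x), 6)),
      " s), signal: ", sig,
      if (!is.null(x$F_bg)) ", background present" else "", "\n", sep = "")
  invisible(x)
}

#' Sampling interval of a trace in seconds
#' @param trace A `sensor_trace`.
#' @return The (uniform) sampling interval in seconds.
#' @export
trace_dt <- function(trace) {
  stopifnot(inherits(trace, "sensor_trace"))
  (trace$t[length(trace$t)] - trace$t[1]) / (length(trace$t) - 1L)
}

#' Analysis window in seconds
#'
#' Trace analysis windows are half-open intervals `[start, end)` on the time
#' axis, so that adjacent windows (e.g. baseline 0-10 s and stimulus
#' 10-20 s) partition the samples without overlap.
#'
#' @param start Window start in seconds (inclusive).
#' @param end Window end in seconds (exclusive).
#' @return A numeric vector `c(start, end)` of class `time_window`.
#' @export
#' @examples
#' time_window(0, 10)   # baseline
#' time_window(10, 20)  # stimulus
time_window <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || !is.finite(start) ||
      !is.finite(end) || start >= end)
    stop("window requires finite start < end")
  structure(c(start = start, end = end), class = "time_window")
}

# Coerce c(start, end) to a validated window.
as_time_window <- function(w) {
  if (inherits(w, "time_window")) return(w)
  if (is.numeric(w) && length(w) == 2L) return(time_window(w[1], w[2]))
  stop("expected a time_window or numeric c(start, end)")
}

# Indices of samples falling in [start, end); closed = TRUE gives
# [start, end], used by the behavior module.
window_index <- function(t, window, closed = FALSE) {
  w <- as_time_window(window)
  if (closed) which(t >= w[1] & t <= w[2]) else which(t >= w[1] & t < w[2])
}

# Extract the primary signal values within a window; errors if empty.
window_values <- function(trace, window, signal = c("dff", "F"),
                          min_n = 1L) {
  signal <- match.arg(signal)
  x <- trace[[signal]]
  if (is.null(x))
    stop("trace '", trace$trace_id, "': ", signal, " is not populated")
  idx <- window_index(trace$t, window)
  if (length(idx) < min_n)
    stop("window [", as_time_window(window)[1], ", ",
         as_time_window(window)[2], ") holds ", length(idx),
         " sample(s) of trace '", trace$trace_id, "'; need >= ", min_n)
  x[idx]
}
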