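#' Read a trace table CSV into sensor traces
#'
#' Expected columns: `trace_id`, `t_s`, and `F` and/or `dff`; optional
#' `genotype`, `F_bg`, `excitation`. One trace per distinct `trace_id`;
#' the uniform-sampling invariant is enforced per trace and violations
#' are reported with the offending trace named.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @return A named list of `sensor_trace` objects.
#' @export
read_trace_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "t_s")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trace table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!any(c("F", "dff") %in% names(d)))
    stop("trace table ", path, " needs an 'F' or 'dff' column")
  ids <- unique(d$trace_id)
  out <- lapply(ids, function(id) {
    di <- d[d$trace_id == id, , drop = FALSE]
    di <- di[order(di$t_s), , drop = FALSE]
    if (anyDuplicated(di$t_s))
      stop("trace '", id, "': duplicated timestamp(s) in ", path)
    has_F <- "F" %in% names(di) && !all(is.na(di$F))
    has_dff <- "dff" %in% names(di) && !all(is.na(di$dff))
    sensor_trace(
      t = di$t_s,
      F = if (has_F) di$F else NULL,
      dff = if (!has_F && has_dff) di$dff else NULL,
      trace_id = id,
      genotype = if ("genotype" %in% names(di)) di$genotype[1] else NA,
      F_bg = if ("F_bg" %in% names(di) && !all(is.na(di$F_bg))) di$F_bg
             else NULL,
      excitation = if ("excitation" %in% names(di)) di$excitation[1]
                   else NA_real_)
  })
  names(out) <- ids
  out
}

#' Read a worm-track table CSV
#'
#' Expected columns: `track_id`, `t_s`, `x_px`, `y_px`; optional
#' `genotype`.
#'
#' @param path Path to a CSV file with a header row.
#' @return A named list of `worm_track` objects.
#' @export
read_track_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "t_s", "x_px", "y_px")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("track table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  ids <- unique(d$track_id)
  out <- lapply(ids, function(id) {
    di <- d[d$track_id == id, , drop = FALSE]
    di <- di[order(di$t_s), , drop = FALSE]
    worm_track(t = di$t_s, x = di$x_px, y = di$y_px, track_id = id,
               genotype = if ("genotype" %in% names(di)) di$genotype[1]
                          else NA)
  })
  names(out) <- ids
  out
}

#' Read a chemotaxis counts table CSV
#'
#' Expected columns: `trial_id`, `n_air`, `n_co2`; optional `genotype`.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data.frame of the validated counts.
#' @export
read_counts_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "n_air", "n_co2")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("counts table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(d$n_air < 0 | d$n_co2 < 0))
    stop("counts table ", path, " contains negative counts")
  if (any(d$n_air + d$n_co2 == 0))
    stop("counts table ", path, " contains an empty trial")
  d
}

#' Read a stimulus schedule from a JSON config
#'
#' The config maps window names to objects with `start` and `end` in
#' seconds, e.g. `{"baseline": {"start": 0, "end": 10}, ...}`.
#'
#' @param path Path to the JSON file.
#' @return A named list of `c(start, end)` numeric windows.
#' @export
read_schedule <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(cfg, function(w) {
    if (is.null(w$start) || is.null(w$end) || w$start >= w$end)
      stop("schedule ", path, ": each window needs start < end")
    c(start = as.numeric(w$start), end = as.numeric(w$end))
  })
}

#' Write tidy result tables
#'
#' Writes each data.frame in `objects` to `<dir>/<name>.csv`
#' (comma-separated, UTF-8, header row, numbers at 6 significant digits).
#'
#' @param objects Named list of data.frames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(objects, dir) {
  stopifnot(is.list(objects), !is.null(names(objects)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(objects), function(nm) {
    d <- objects[[nm]]
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], signif, digits = 6)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(d, p, row.names = FALSE, fileEncoding = "UTF-8")
    p
  }, character(1))
  invisible(paths)
}

#' Convert sensor traces to the long trace-table format
#'
#' Inverse of [read_trace_table()]: stacks traces into one data.frame in
#' the CSV dialect the readers consume.
#'
#' @param traces A list of `sensor_trace` objects.
#' @return A data.frame with columns `trace_id`, `genotype`, `t_s`, `F`,
#'   `dff`, `F_bg`, `excitation`.
#' @export
traces_to_table <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    n <- length(tr$t)
    data.frame(trace_id = tr$trace_id, genotype = tr$genotype, t_s = tr$t,
               F = if (is.null(tr$F)) NA_real_ else tr$F,
               dff = if (is.null(tr$dff)) NA_real_ else tr$dff,
               F_bg = if (is.null(tr$F_bg)) NA_real_ else tr$F_bg,
               excitation = tr$excitation, stringsAsFactors = FALSE)
  }))
}

#' Convert worm tracks to the long track-table format
#'
#' Inverse of [read_track_table()].
#'
#' @param tracks A list of `worm_track` objects.
#' @return A data.frame with columns `track_id`, `genotype`, `t_s`,
#'   `x_px`, `y_px`.
#' @export
tracks_to_table <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$track_id, genotype = tr$genotype, t_s = tr$t,
               x_px = tr$x, y_px = tr$y, stringsAsFactors = FALSE)))
}
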