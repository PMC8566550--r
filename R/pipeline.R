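#' Run the end-to-end analysis pipeline
#'
#' Executes whichever analysis branches the configuration provides inputs
#' for, writes tidy CSV outputs to the output directory, and records a
#' run log listing every constant used and every trace/track/punctum
#' excluded, with its rule.
#'
#' Branches:
#' \describe{
#'   \item{pHluorin calibration}{`config$traces` (CSV, raw `F`) plus a
#'     schedule naming `baseline`, `nh4` and `mes` windows. Traces are
#'     normalised to dF/F, gated as NH4Cl/MES responders (1 s filter,
#'     mean + 3 SD rule), measured for gamma and epsilon (5 s filter),
#'     solved for lumenal pH and surface fraction, and summarised per
#'     genotype; genotypes are compared by Kruskal-Wallis/Dunn when at
#'     least two are present.}
#'   \item{Behavior}{`config$tracks` (CSV) plus stimulus windows named
#'     `stim*` in the schedule. Tracks are quality-filtered, population
#'     speed/turn series computed, the extremum quantification window
#'     extracted per stimulus window, and per-track window means written.}
#'   \item{Chemotaxis}{`config$counts` (CSV); per-trial avoidance indices
#'     are written, with a genotype comparison when possible.}
#' }
#'
#' @param config A list (or path to a JSON file) with any of `traces`,
#'   `tracks`, `counts` (file paths), `schedule` (path to a JSON schedule
#'   or a named list of windows), `out_dir` (default `"sq_results"`),
#'   `pK`, `pH_external`, `pH_acid`, `pH_floor`, `microns_per_pixel`,
#'   `turn_threshold`, `seed`.
#' @return Invisibly, a list with `status` (0 on success), the computed
#'   tables, and the log lines.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  out_dir <- if (is.null(config$out_dir)) "sq_results" else config$out_dir
  constants <- ph_constants(
    pK = config$pK %||% 7.18,
    pH_external = config$pH_external %||% 7.2,
    pH_acid = config$pH_acid %||% 5.5,
    pH_floor = config$pH_floor %||% 5.0)
  mpp <- config$microns_per_pixel %||% MICRONS_PER_PIXEL
  turn_thr <- config$turn_threshold %||% 50
  log <- c(
    sprintf("pK = %g", constants$pK),
    sprintf("pH_external = %g (reference pH of the NH4Cl saline)",
            constants$pH_external),
    sprintf("pH_acid = %g (MES quench)", constants$pH_acid),
    sprintf("pH_floor = %g (probe dynamic-range floor)", constants$pH_floor),
    sprintf("microns_per_pixel = %g", mpp),
    sprintf("turn_threshold = %g deg/s", turn_thr),
    "note: pK 7.18 applied to all model equations, including the exocytosis factor",
    "note: track retention reads the speed criterion as mean track speed >= 1.17 px/s")
  schedule <- config$schedule
  if (is.character(schedule)) schedule <- read_schedule(schedule)
  results <- list()

  if (!is.null(config$traces)) {
    stopifnot(!is.null(schedule$baseline), !is.null(schedule$nh4),
              !is.null(schedule$mes))
    traces <- read_trace_table(config$traces)
    rows <- lapply(traces, function(tr) {
      tr_d <- delta_f_over_f(tr, schedule$baseline)
      nh4 <- classify_responder(tr_d, schedule$baseline, schedule$nh4,
                                direction = "increase")
      mes <- classify_responder(tr_d, schedule$baseline, schedule$mes,
                                direction = "decrease")
      data.frame(punctum_id = tr$trace_id, genotype = tr$genotype,
                 gamma = measure_gamma(tr_d, schedule$nh4),
                 epsilon = measure_epsilon(tr_d, schedule$mes),
                 nh4_responder = nh4$responder, mes_responder = mes$responder,
                 stringsAsFactors = FALSE)
    })
    cal <- do.call(rbind, rows)
    sol <- solve_calibration_table(cal, constants)
    for (i in which(sol$excluded))
      log <- c(log, sprintf("excluded punctum '%s': %s",
                            sol$punctum_id[i], sol$reason[i]))
    keep <- sol$converged & !sol$excluded
    summ <- do.call(rbind, lapply(split(sol[keep, ], sol$genotype[keep]),
      function(g) data.frame(genotype = g$genotype[1],
                             mean_pH = mean(g$pH), mean_SF = mean(g$SF),
                             n = nrow(g), sd_pH = stats::sd(g$pH),
                             sd_SF = stats::sd(g$SF),
                             stringsAsFactors = FALSE)))
    results$puncta <- sol
    if (!is.null(summ)) results$genotype_summary <- summ
    if (length(unique(sol$genotype[keep])) >= 2L) {
      kd <- kruskal_dunn(split(sol$pH[keep], sol$genotype[keep]))
      results$ph_comparison <- kd$comparisons
      log <- c(log, sprintf("pH comparison: Kruskal-Wallis H = %.4g, p = %.4g",
                            kd$H, kd$p_omnibus))
    }
  }

  if (!is.null(config$tracks)) {
    tracks <- read_track_table(config$tracks)
    kept <- filter_tracks(tracks, microns_per_pixel = mpp)
    dropped <- setdiff(names(tracks),
                       vapply(kept, `[[`, character(1), "track_id"))
    for (id in dropped)
      log <- c(log, sprintf(
        "excluded track '%s': shorter than 30 s or mean speed < 1.17 px/s", id))
    t0 <- min(vapply(kept, function(tr) tr$t[1], numeric(1)))
    t1 <- max(vapply(kept, function(tr) tr$t[length(tr$t)], numeric(1)))
    dt <- min(vapply(kept, function(tr) min(diff(tr$t)), numeric(1)))
    pop <- population_series(kept, seq(t0, t1, by = dt), mpp, turn_thr)
    results$population <- pop
    stim <- schedule[grepl("^stim", names(schedule))]
    if (length(stim)) {
      per <- do.call(rbind, lapply(names(stim), function(nm) {
        w_sp <- extremum_window(pop, stim[[nm]], "min_speed")
        w_tn <- extremum_window(pop, stim[[nm]], "max_turn")
        sp <- per_track_window_mean(kept, w_sp, "speed", mpp, turn_thr)
        tn <- per_track_window_mean(kept, w_tn, "turn", mpp, turn_thr)
        rbind(
          if (nrow(sp)) cbind(window = nm, metric = "speed", sp),
          if (nrow(tn)) cbind(window = nm, metric = "turn", tn))
      }))
      results$track_window_means <- per
    }
  }

  if (!is.null(config$counts)) {
    counts <- read_counts_table(config$counts)
    counts$ai <- avoidance_index(counts$n_air, counts$n_co2)
    results$avoidance <- counts
    if ("genotype" %in% names(counts) &&
        length(unique(counts$genotype)) >= 2L) {
      kd <- kruskal_dunn(split(counts$ai, counts$genotype))
      results$ai_comparison <- kd$comparisons
      log <- c(log, sprintf("AI comparison: Kruskal-Wallis H = %.4g, p = %.4g",
                            kd$H, kd$p_omnibus))
    }
  }

  if (length(results) == 0L)
    stop("config provides no inputs (traces, tracks or counts)")
  write_results(results, out_dir)
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(status = 0L, results = results, log = log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
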