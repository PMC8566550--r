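#' Constants of the pHluorin calibration model
#'
#' Superecliptic pHluorin fluorescence follows the deprotonation curve
#' `1 / (1 + 10^(pK - pH))`. During an NH4Cl pulse the vesicular pH
#' gradient collapses and all probe reports the external pH; during an
#' acidic MES pulse the surface-exposed probe is quenched at the acid pH.
#' These two manoeuvres give, per punctum, the fractional fluorescence
#' increase `gamma` and fractional decrease `epsilon`, which together
#' determine the resting lumenal pH and the probe surface fraction.
#'
#' @param pK Apparent pK of superecliptic pHluorin (default 7.18).
#' @param pH_external pH of the external / NH4Cl solution (default 7.2).
#' @param pH_acid pH of the MES quench solution (default 5.5).
#' @param pH_floor Lower bound of the probe's useful dynamic range
#'   (default 5.0); solutions below it are flagged as excluded.
#' @return A list of class `ph_constants`.
#' @export
ph_constants <- function(pK = 7.18, pH_external = 7.2, pH_acid = 5.5,
                         pH_floor = 5.0) {
  stopifnot(pH_acid < pH_external, pK > 0)
  structure(list(pK = pK, pH_external = pH_external, pH_acid = pH_acid,
                 pH_floor = pH_floor),
            class = "ph_constants")
}

# A(pH): scaled difference of protonation terms between lumenal and
# external pH; the gamma equation is gamma = A(1-SF)/(1+A*SF).
ph_A <- function(pH, k) {
  (10^(k$pK - pH) - 10^(k$pK - k$pH_external)) / (1 + 10^(k$pK - k$pH_external))
}

# C(pH): protonation ratio between lumenal and acid-quench pH.
ph_C <- function(pH, k) {
  (1 + 10^(k$pK - pH)) / (1 + 10^(k$pK - k$pH_acid))
}

#' Surface fraction implied by the NH4Cl response at a candidate pH
#'
#' Inverts the alkalinisation branch of the calibration model: given the
#' fractional increase `gamma` and a candidate lumenal pH, returns the
#' surface fraction `SF = (A - gamma) / (A * (gamma + 1))` with
#' `A = (10^(pK-pH) - 10^(pK-pHext)) / (1 + 10^(pK-pHext))`.
#'
#' @param pH Candidate lumenal pH (may be a vector).
#' @param gamma Fractional fluorescence increase under NH4Cl.
#' @param constants A [ph_constants()] object.
#' @return Surface fraction(s), same length as `pH`.
#' @export
sf_from_gamma <- function(pH, gamma, constants = ph_constants()) {
  A <- ph_A(pH, constants)
  if (any(abs(A) < .Machine$double.eps))
    stop("pH equals the external pH; the NH4Cl equation is undefined there")
  (A - gamma) / (A * (gamma + 1))
}

#' Surface fraction implied by the MES response at a candidate pH
#'
#' Inverts the acid-quench branch of the calibration model:
#' `SF = epsilon / (1 - C + (1 - epsilon) * A)` with `A` as in
#' [sf_from_gamma()] and `C = (1 + 10^(pK-pH)) / (1 + 10^(pK-pHacid))`.
#'
#' @param pH Candidate lumenal pH (may be a vector).
#' @param epsilon Fractional fluorescence decrease under MES (positive
#'   magnitude).
#' @param constants A [ph_constants()] object.
#' @return Surface fraction(s), same length as `pH`.
#' @export
sf_from_epsilon <- function(pH, epsilon, constants = ph_constants()) {
  den <- 1 - ph_C(pH, constants) + (1 - epsilon) * ph_A(pH, constants)
  if (any(abs(den) < .Machine$double.eps))
    stop("singular denominator in the MES equation at the requested pH")
  epsilon / den
}

#' Forward calibration model: (pH, SF) to (gamma, epsilon)
#'
#' Exact algebraic inverse of [sf_from_gamma()] and [sf_from_epsilon()]:
#' `gamma = A (1 - SF) / (1 + A SF)` and
#' `epsilon = SF (1 - C + A) / (1 + SF A)`. Used to generate synthetic
#' calibration data with known ground truth and for round-trip testing of
#' the solver.
#'
#' @param pH Lumenal pH, below `pH_external`.
#' @param SF Surface fraction in `[0, 1)`.
#' @param constants A [ph_constants()] object.
#' @return A list with `gamma` and `epsilon`.
#' @export
#' @examples
#' forward_calibration(6.2, 0.25)  # gamma ~ 1.571, epsilon ~ 0.617
forward_calibration <- function(pH, SF, constants = ph_constants()) {
  stopifnot(is.finite(pH), is.finite(SF))
  if (pH >= constants$pH_external)
    stop("pH must be below the external pH ", constants$pH_external)
  if (SF < 0 || SF >= 1)
    stop("SF must lie in [0, 1); SF = 1 is degenerate (gamma = 0 for any pH)")
  A <- ph_A(pH, constants)
  C <- ph_C(pH, constants)
  list(gamma = A * (1 - SF) / (1 + A * SF),
       epsilon = SF * (1 - C + A) / (1 + SF * A))
}

#' Measure gamma: maximal smoothed dF/F during NH4Cl application
#'
#' @param trace A `sensor_trace` with `dff` from an NH4Cl calibration
#'   recording that passed the responder gates.
#' @param window Application `time_window` (default 20-60 s).
#' @param filter_width Moving-average width in seconds (default 5); the
#'   heavy smoothing removes high-frequency fluctuations that would bias a
#'   max-based amplitude estimate.
#' @return gamma, the fractional fluorescence increase.
#' @export
measure_gamma <- function(trace, window = c(20, 60), filter_width = 5) {
  sm <- moving_average(trace, filter_width)
  max(window_values(sm, window, "dff"))
}

#' Measure epsilon: magnitude of the smoothed dF/F minimum during MES
#'
#' @param trace A `sensor_trace` with `dff` from a MES calibration
#'   recording that passed the responder gates.
#' @param window Application `time_window` (default 20-80 s).
#' @param filter_width Moving-average width in seconds (default 5).
#' @return epsilon, the (positive) fractional fluorescence decrease.
#' @export
measure_epsilon <- function(trace, window = c(20, 80), filter_width = 5) {
  sm <- moving_average(trace, filter_width)
  -min(window_values(sm, window, "dff"))
}

#' Solve the two-equation calibration model for lumenal pH and SF
#'
#' The NH4Cl and MES branches each express the surface fraction as a
#' function of the candidate lumenal pH; the punctum's (pH, SF) is the
#' intersection of the two curves. The difference
#' `sf_from_gamma(pH) - sf_from_epsilon(pH)` is evaluated on a fine pH
#' grid (step `grid_step`) across `bracket`; each sign change is refined
#' by bisection to a pH accuracy of about 1e-10. Solutions with pH below
#' `pH_floor` (default 5.0) are flagged excluded as outside the probe's
#' dynamic range. If several intersections exist the one with the smallest
#' residual is returned with a warning (the model is expected to have a
#' unique intersection for physiological inputs).
#'
#' @param gamma Fractional increase under NH4Cl.
#' @param epsilon Fractional decrease under MES (positive magnitude).
#' @param constants A [ph_constants()] object.
#' @param tol Convergence tolerance on the residual `|SF1 - SF2|`
#'   (default 1e-9).
#' @param bracket pH search interval; defaults to
#'   `c(4.5, pH_external - 1e-6)`, wide enough below the dynamic-range
#'   floor that out-of-range puncta are solved and then excluded rather
#'   than silently failing.
#' @param grid_step pH step of the sign-change scan (default 1e-3).
#' @param punctum_id Optional identifier carried into the result.
#' @return An object of class `ph_solution`: list with `punctum_id`, `pH`,
#'   `SF`, `converged`, `excluded`, `residual`, `reason`
#'   (`"none"`, `"below_dynamic_range"` or `"no_intersection"`).
#' @export
#' @examples
#' cal <- forward_calibration(6.2, 0.25)
#' solve_ph_sf(cal$gamma, cal$epsilon)
solve_ph_sf <- function(gamma, epsilon, constants = ph_constants(),
                        tol = 1e-9, bracket = NULL, grid_step = 1e-3,
                        punctum_id = NA_character_) {
  if (!is.finite(gamma) || !is.finite(epsilon))
    stop("gamma and epsilon must be finite")
  if (is.null(bracket))
    bracket <- c(4.5, constants$pH_external - 1e-6)
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  f <- function(pH) sf_from_gamma(pH, gamma, constants) -
    sf_from_epsilon(pH, epsilon, constants)
  grid <- seq(bracket[1], bracket[2], by = grid_step)
  if (grid[length(grid)] < bracket[2]) grid <- c(grid, bracket[2])
  fg <- suppressWarnings(f(grid))
  ok <- is.finite(fg)
  sgn <- sign(fg)
  # exact zeros on the grid, plus strict sign changes between finite values
  zeros <- grid[ok & fg == 0]
  flips <- which(ok[-length(ok)] & ok[-1] & sgn[-length(sgn)] * sgn[-1] < 0)
  no_root <- structure(
    list(punctum_id = punctum_id, pH = NA_real_, SF = NA_real_,
         converged = FALSE, excluded = FALSE, residual = NA_real_,
         reason = "no_intersection"),
    class = "ph_solution")
  if (length(flips) == 0L && length(zeros) == 0L) return(no_root)
  roots <- c(zeros, vapply(flips, function(i)
    stats::uniroot(f, lower = grid[i], upper = grid[i + 1],
                   f.lower = fg[i], f.upper = fg[i + 1],
                   tol = 1e-12)$root, numeric(1)))
  # a sign change through a pole of the MES branch is not an intersection;
  # genuine roots refine to a vanishing residual
  res <- abs(vapply(roots, f, numeric(1)))
  keep <- res < 1e-6
  if (!any(keep)) return(no_root)
  roots <- roots[keep]; res <- res[keep]
  distinct <- c(TRUE, diff(sort(roots)) > grid_step / 2)
  if (sum(distinct) > 1L)
    warning("multiple intersections of the calibration curves; ",
            "taking the one with the smallest residual")
  i_best <- which.min(res)
  pH_star <- roots[i_best]
  SF_star <- sf_from_gamma(pH_star, gamma, constants)
  excluded <- pH_star < constants$pH_floor
  structure(
    list(punctum_id = punctum_id, pH = pH_star, SF = SF_star,
         converged = res[i_best] < tol, excluded = excluded,
         residual = res[i_best],
         reason = if (excluded) "below_dynamic_range" else "none"),
    class = "ph_solution")
}

#' @export
print.ph_solution <- function(x, ...) {
  cat("<ph_solution>",
      if (!is.na(x$punctum_id)) paste0(" ", x$punctum_id) else "", "\n",
      sep = "")
  if (x$converged) {
    cat("  pH = ", signif(x$pH, 5), ", SF = ", signif(x$SF, 5),
        if (x$excluded) "  [excluded: below dynamic range]" else "",
        "\n", sep = "")
  } else {
    cat("  not converged (", x$reason, ")\n", sep = "")
  }
  invisible(x)
}

#' Solve calibration measurements for a table of puncta
#'
#' Convenience wrapper applying [solve_ph_sf()] to each row of a
#' per-punctum calibration table. Rows failing any responder flag are
#' marked excluded with reason `"non_responder"` and are not solved.
#'
#' @param measurements A data.frame with columns `punctum_id`, `genotype`,
#'   `gamma`, `epsilon`, and logical `kcl_responder`, `nh4_responder`,
#'   `mes_responder` (flag columns are optional; missing flags are treated
#'   as `TRUE`).
#' @param constants A [ph_constants()] object.
#' @param ... Passed to [solve_ph_sf()].
#' @return A data.frame with columns `punctum_id`, `genotype`, `gamma`,
#'   `epsilon`, `pH`, `SF`, `converged`, `excluded`, `reason`.
#' @export
solve_calibration_table <- function(measurements, constants = ph_constants(),
                                    ...) {
  need <- c("punctum_id", "gamma", "epsilon")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("calibration table lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(measurements)
  flag <- rep(TRUE, n)
  for (fl in c("kcl_responder", "nh4_responder", "mes_responder"))
    if (fl %in% names(measurements)) flag <- flag & measurements[[fl]]
  out <- data.frame(
    punctum_id = as.character(measurements$punctum_id),
    genotype = if ("genotype" %in% names(measurements))
      as.character(measurements$genotype) else NA_character_,
    gamma = measurements$gamma, epsilon = measurements$epsilon,
    pH = NA_real_, SF = NA_real_, converged = FALSE, excluded = !flag,
    reason = ifelse(flag, "none", "non_responder"),
    stringsAsFactors = FALSE)
  for (i in which(flag)) {
    s <- solve_ph_sf(out$gamma[i], out$epsilon[i], constants,
                     punctum_id = out$punctum_id[i], ...)
    out$pH[i] <- s$pH; out$SF[i] <- s$SF
    out$converged[i] <- s$converged; out$excluded[i] <- s$excluded
    out$reason[i] <- s$reason
  }
  out
}

#' Exocytosis signal factor for a vesicle fusing at lumenal pH pH_a
#'
#' Predicted fractional pHluorin signal increase when one vesicle's lumen
#' jumps from its resting pH `pH_a` to the external pH, given the probe
#' surface fraction `SF`:
#' `delta = (1/(1+10^(pK-pHext)) - 1/(1+10^(pK-pHa))) /
#'          (1/(1+10^(pK-pHa)) + SF / ((1-SF) (1+10^(pK-pHext))))`.
#' More acidic vesicles (lower `pH_a`) give larger `delta`: the same
#' fusion event produces a larger fractional signal.
#'
#' @param pH_a Resting lumenal pH (at or below `pH_external`).
#' @param SF Surface fraction in `[0, 1)`.
#' @param constants A [ph_constants()] object.
#' @return The (dimensionless) factor delta.
#' @export
delta_factor <- function(pH_a, SF, constants = ph_constants()) {
  if (any(pH_a > constants$pH_external))
    stop("pH_a must not exceed the external pH")
  if (any(SF >= 1) || any(SF < 0))
    stop("SF must lie in [0, 1)")
  k <- constants
  fe <- 1 / (1 + 10^(k$pK - k$pH_external))
  fa <- 1 / (1 + 10^(k$pK - pH_a))
  (fe - fa) / (fa + SF / ((1 - SF) * (1 + 10^(k$pK - k$pH_external))))
}

#' Cross-genotype exocytosis adjustment ratio
#'
#' A genotype with more alkaline vesicles shows a smaller fractional
#' pHluorin signal for the same number of fusion events. To compare evoked
#' responses across genotypes with different resting vesicular pH, each
#' mutant punctum's signal is multiplied by
#' `delta(pH_ref, SF_mut) / delta(pH_mut, SF_mut)`: both factors are
#' evaluated at the mutant's surface fraction, and only the resting pH is
#' swapped to the reference (wild-type) value — i.e. the counterfactual in
#' which everything about the mutant stays the same except its vesicular
#' pH.
#'
#' @param pH_ref Reference (wild-type) mean lumenal pH.
#' @param pH_mut Mutant mean lumenal pH.
#' @param SF_mut Mutant mean surface fraction.
#' @param constants A [ph_constants()] object.
#' @return The dimensionless adjustment ratio.
#' @export
#' @examples
#' delta_ratio(6.22, 6.33, 0.310)  # ~1.15
delta_ratio <- function(pH_ref, pH_mut, SF_mut, constants = ph_constants()) {
  d_mut <- delta_factor(pH_mut, SF_mut, constants)
  if (d_mut == 0)
    stop("delta for the mutant is zero; ratio undefined")
  delta_factor(pH_ref, SF_mut, constants) / d_mut
}

#' Apply the exocytosis adjustment to a response metric
#'
#' @param signal Per-punctum response metric(s) (e.g. peak dF/F under
#'   depolarisation).
#' @param ratio Adjustment ratio from [delta_ratio()] (> 0).
#' @return `signal * ratio`.
#' @export
adjust_exocytosis_signal <- function(signal, ratio) {
  stopifnot(is.numeric(ratio), all(ratio > 0))
  signal * ratio
}

#' Genotype-level summary of pH/SF solutions
#'
#' Arithmetic means over the converged, non-excluded solutions only.
#'
#' @param solutions A list of `ph_solution` objects, or a data.frame from
#'   [solve_calibration_table()].
#' @return A list with `mean_pH`, `mean_SF`, `n`, `sd_pH`, `sd_SF`.
#' @export
summarize_genotype <- function(solutions) {
  if (is.data.frame(solutions)) {
    keep <- solutions$converged & !solutions$excluded
    pH <- solutions$pH[keep]; SF <- solutions$SF[keep]
  } else {
    keep <- vapply(solutions, function(s) s$converged && !s$excluded,
                   logical(1))
    pH <- vapply(solutions[keep], `[[`, numeric(1), "pH")
    SF <- vapply(solutions[keep], `[[`, numeric(1), "SF")
  }
  if (length(pH) == 0L)
    stop("no converged, non-excluded solutions to summarise")
  list(mean_pH = mean(pH), mean_SF = mean(SF), n = length(pH),
       sd_pH = stats::sd(pH), sd_SF = stats::sd(SF))
}
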