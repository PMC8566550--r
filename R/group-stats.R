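#' Kruskal-Wallis test with Dunn's pairwise post-hoc comparisons
#'
#' Omnibus rank test across groups (tie-corrected H, via
#' [stats::kruskal.test()]) followed by Dunn's z-tests for the requested
#' group pairs. Dunn's statistic for groups i, j is
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' tie correction `T = sum(tau^3 - tau) / (12 (N - 1))` over tie groups of
#' size tau. Two-sided p-values are Bonferroni-adjusted by the number of
#' requested comparisons.
#'
#' @param groups Named list of numeric vectors (one per group), or a
#'   data.frame with columns `group` and `value`.
#' @param comparisons List of length-2 character vectors naming the group
#'   pairs to test; defaults to all pairs.
#' @return A list of class `kruskal_dunn` with `H`, `df`, `p_omnibus`,
#'   and a data.frame `comparisons` (`group1`, `group2`, `z`, `p`,
#'   `p_adjusted`).
#' @export
#' @examples
#' kruskal_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
kruskal_dunn <- function(groups, comparisons = NULL) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- utils::combn(nm, 2, simplify = FALSE)
  }
  for (cp in comparisons)
    if (!all(cp %in% names(groups)))
      stop("comparison references unknown group(s): ",
           paste(setdiff(cp, names(groups)), collapse = ", "))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1L) {
    # all observations identical: no evidence against the null by
    # construction (kruskal.test's tie correction is 0/0 here)
    kw <- list(statistic = 0, parameter = length(groups) - 1L, p.value = 1)
  } else {
    kw <- stats::kruskal.test(x, g)
  }
  r <- rank(x)
  N <- length(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  m <- length(comparisons)
  cmp <- do.call(rbind, lapply(comparisons, function(cp) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[cp[1]] + 1 / n[cp[2]]))
    z <- if (se == 0) 0 else (rbar[cp[1]] - rbar[cp[2]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = cp[1], group2 = cp[2], z = unname(z), p = unname(p),
               p_adjusted = unname(min(1, p * m)), stringsAsFactors = FALSE)
  }))
  structure(list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p_omnibus = kw$p.value, comparisons = cmp),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat("Kruskal-Wallis: H = ", signif(x$H, 5), ", df = ", x$df,
      ", p = ", signif(x$p_omnibus, 4), "\n", sep = "")
  cat("Dunn's comparisons (Bonferroni-adjusted):\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Standard one-way F-test followed by Dunnett's test of every non-control
#' group against the control, with single-step adjusted p-values (via
#' \pkg{multcomp}).
#'
#' @param groups Named list of numeric vectors (each of length >= 2), or a
#'   data.frame with columns `group` and `value`.
#' @param control Name of the control group.
#' @return A list of class `anova_dunnett` with `F`, `df`, `p_omnibus`,
#'   and a data.frame `comparisons` (`group`, `estimate`, `p_adjusted`).
#' @export
anova_dunnett <- function(groups, control) {
  groups <- as_group_list(groups)
  if (!control %in% names(groups))
    stop("control group '", control, "' not present")
  if (any(lengths(groups) < 2L))
    stop("every group needs at least 2 observations for ANOVA")
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = c(control, setdiff(names(groups), control))))
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(glht_fit)
  structure(
    list(F = an[["F value"]][1], df = c(an[["Df"]][1], an[["Df"]][2]),
         p_omnibus = an[["Pr(>F)"]][1],
         comparisons = data.frame(
           group = setdiff(levels(d$group), control),
           estimate = unname(sm$test$coefficients),
           p_adjusted = unname(as.numeric(sm$test$pvalues)),
           stringsAsFactors = FALSE)),
    class = "anova_dunnett")
}

#' @export
print.anova_dunnett <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df[1], ", ", x$df[2], ") = ", signif(x$F, 5),
      ", p = ", signif(x$p_omnibus, 4), "\n", sep = "")
  cat("Dunnett's comparisons vs control:\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

# Accept either a named list of numeric vectors or a long data.frame.
as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups)))
      stop("long-format data needs columns 'group' and 'value'")
    groups <- split(groups$value, as.character(groups$group))
  }
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  lapply(groups, as.numeric)
}
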