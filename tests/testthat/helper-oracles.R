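# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive re-derivations, kept free of package code
# paths wherever the package has a cleverer implementation.

# Naive centered boxcar mean with edge truncation, sample by sample.
oracle_boxcar <- function(x, n_tap) {
  n <- length(x)
  h <- (n_tap - 1L) %/% 2L
  vapply(seq_len(n), function(i) mean(x[max(1L, i - h):min(n, i + h)]),
         numeric(1))
}

# Brute-force re-derivation of the calcium pre-stimulus exclusion rule:
# smooth each dF/F vector (dt sampling), pool the baseline SDs per group,
# and flag traces whose smoothed baseline max exceeds mode + k * pooled SD.
oracle_gcamp_rule <- function(dff_list, group, dt, baseline = c(0, 10),
                              filter_width = 0.5, k = 5, mode_bin = 0.01) {
  n_tap <- floor(filter_width / dt + 1e-9)
  if (n_tap %% 2 == 0) n_tap <- n_tap - 1
  n_tap <- max(n_tap, 1)
  t <- (seq_along(dff_list[[1]]) - 1) * dt
  in_bl <- t >= baseline[1] & t < baseline[2]
  sm <- lapply(dff_list, oracle_boxcar, n_tap = n_tap)
  bl <- lapply(sm, function(x) x[in_bl])
  sds <- vapply(bl, sd, numeric(1))
  keep <- logical(length(bl))
  for (g in unique(group)) {
    ig <- which(group == g)
    pooled <- mean(sds[ig])
    for (i in ig) {
      x <- bl[[i]]
      rng <- range(x)
      m <- if (diff(rng) < 1e-300) rng[1] else {
        kbin <- pmin(floor((x - rng[1]) / mode_bin),
                     ceiling(diff(rng) / mode_bin) - 1)
        tab <- table(kbin)
        rng[1] + (as.numeric(names(tab)[which.max(tab)]) + 0.5) * mode_bin
      }
      keep[i] <- !(max(x) > m + k * pooled)
    }
  }
  keep
}

# Exact permutation distribution of Dunn's |z| for one pair of groups,
# enumerating all assignments of the pooled observations to group labels.
oracle_dunn_perm_p <- function(groups, pair) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  labs <- rep(names(groups), sizes)
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  zstat <- function(assign) {
    m1 <- mean(r[assign == pair[1]]); m2 <- mean(r[assign == pair[2]])
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / sizes[pair[1]] + 1 / sizes[pair[2]]))
    abs(m1 - m2) / se
  }
  z_obs <- zstat(labs)
  perms <- combn(N, sizes[1])
  count <- 0L; total <- 0L
  for (j in seq_len(ncol(perms))) {
    rest <- setdiff(seq_len(N), perms[, j])
    inner <- combn(rest, sizes[2])
    for (k in seq_len(ncol(inner))) {
      assign <- rep(names(groups)[3], N)
      assign[perms[, j]] <- names(groups)[1]
      assign[inner[, k]] <- names(groups)[2]
      total <- total + 1L
      if (zstat(assign) >= z_obs - 1e-12) count <- count + 1L
    }
  }
  count / total
}

# Convenience: a flat raw-F trace with a rectangular step.
make_step_trace <- function(base = 10, step = base, at = NULL, t_max = 2,
                            dt = 0.1, ...) {
  t <- seq(0, t_max, by = dt)
  F <- rep(base, length(t))
  if (!is.null(at)) F[which.min(abs(t - at))] <- step
  sensor_trace(t = t, F = F, ...)
}
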