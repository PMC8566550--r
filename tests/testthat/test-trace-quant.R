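test_that("dF/F normalisation follows the two-step subtract-then-divide rule", {
  # constant trace: identity case
  tr <- sensor_trace(t = seq(0, 2, 0.1), F = rep(10, 21))
  expect_equal(delta_f_over_f(tr, c(0, 1))$dff, rep(0, 21))

  # step from 10 to 25 with baseline F0 = 10
  F <- rep(10, 21); F[15] <- 25
  tr <- sensor_trace(t = seq(0, 2, 0.1), F = F)
  out <- delta_f_over_f(tr, c(0, 1))
  expect_equal(out$dff[15], 1.5)
  expect_identical(out$t, tr$t)

  # background subtraction happens before normalisation:
  # (22-2 - (12-2)) / (12-2) = 1.0
  F <- rep(12, 21); F[15] <- 22
  tr <- sensor_trace(t = seq(0, 2, 0.1), F = F, F_bg = rep(2, 21))
  expect_equal(delta_f_over_f(tr, c(0, 1))$dff[15], 1.0)
})

test_that("dF/F is invariant under rescaling of F and F_bg", {
  set.seed(11)
  t <- seq(0, 5, 0.1)
  for (c_scale in c(0.5, 3, 117)) {
    F <- 50 + cumsum(rnorm(length(t)))
    bg <- runif(length(t), 4, 6)
    tr1 <- sensor_trace(t = t, F = F, F_bg = bg)
    tr2 <- sensor_trace(t = t, F = c_scale * F, F_bg = c_scale * bg)
    expect_equal(delta_f_over_f(tr1, c(0, 2))$dff,
                 delta_f_over_f(tr2, c(0, 2))$dff, tolerance = 1e-12)
  }
})

test_that("dF/F errors on degenerate baselines", {
  tr <- sensor_trace(t = seq(0, 2, 0.1), F = rep(5, 21), F_bg = rep(5, 21))
  expect_error(delta_f_over_f(tr, c(0, 1)), "degenerate baseline")
  tr <- sensor_trace(t = seq(0, 2, 0.1), F = rep(5, 21))
  expect_error(delta_f_over_f(tr, c(10, 11)), "fewer than 2")
})

test_that("moving average is a centered truncated boxcar", {
  t <- seq(0, 2, 0.1)
  # constants pass through; width of one sample is the identity
  tr <- sensor_trace(t = t, dff = rep(0.7, 21))
  expect_equal(moving_average(tr, 1)$dff, rep(0.7, 21))
  x <- rnorm(21)
  tr <- sensor_trace(t = t, dff = x)
  expect_equal(moving_average(tr, 0.1)$dff, x)

  # unit impulse spread over a 3-sample window
  imp <- rep(0, 21); imp[11] <- 1
  tr <- sensor_trace(t = t, dff = imp)
  sm <- moving_average(tr, 0.3)$dff
  expect_equal(sm[10:12], rep(1 / 3, 3))
  expect_equal(sum(sm > 0), 3)

  # agrees with the naive per-sample oracle, including edge shrinkage
  set.seed(21)
  x <- rnorm(41)
  tr <- sensor_trace(t = seq(0, 4, 0.1), dff = x)
  expect_equal(moving_average(tr, 1)$dff, oracle_boxcar(x, 9),
               tolerance = 1e-12)

  # never extends the input's range
  for (w in c(0.3, 0.9, 2)) {
    sm <- moving_average(tr, w)$dff
    expect_gte(min(sm), min(x))
    expect_lte(max(sm), max(x))
  }
  expect_error(moving_average(tr, 0.01), "below the sampling interval")
})

test_that("baseline statistics: mean, sample SD, histogram mode", {
  tr <- sensor_trace(t = seq(0, 1, 0.1), dff = rep(0.3, 11))
  s <- baseline_stats(tr, c(0, 2))
  expect_equal(s$mean, 0.3)
  expect_equal(s$sd, 0)
  expect_equal(s$mode, 0.3)

  tr <- sensor_trace(t = seq(0, 0.3, 0.1), dff = c(0, 0, 0, 1))
  s <- baseline_stats(tr, c(0, 1))
  expect_equal(s$mean, 0.25)
  expect_equal(s$sd, 0.5)
  expect_equal(s$mode, 0.005)  # center of the lowest 0.01-wide bin

  # majority bin wins; ties go to the lowest bin
  tr <- sensor_trace(t = seq(0, 0.8, 0.1), dff = c(rep(0, 5), rep(0.5, 4)))
  expect_lt(baseline_stats(tr, c(0, 1))$mode, 0.01)
  tr <- sensor_trace(t = seq(0, 0.7, 0.1), dff = c(rep(0, 4), rep(0.5, 4)))
  expect_lt(baseline_stats(tr, c(0, 1))$mode, 0.01)
})

test_that("background gate keeps only traces above mean + 3 SD, excluding ties", {
  t <- seq(0, 10, 0.1)
  set.seed(5)
  bg_vals <- rnorm(length(t), 10, 1)
  bg <- sensor_trace(t = t, F = bg_vals)
  thr <- mean(bg_vals[t < 10]) + 3 * sd(bg_vals[t < 10])

  hi <- sensor_trace(t = t, F = rep(100, length(t)))
  lo <- sensor_trace(t = t, F = rep(10, length(t)))
  at <- sensor_trace(t = t, F = rep(thr, length(t)))  # boundary: excluded
  expect_true(above_background_gate(hi, bg, c(0, 10)))
  expect_false(above_background_gate(lo, bg, c(0, 10)))
  expect_false(above_background_gate(at, bg, c(0, 10)))
})

test_that("responder classification thresholds at baseline mean + 3 SD", {
  t <- seq(0, 20, 0.1)
  set.seed(7)
  # clean step far above threshold
  dff <- ifelse(t >= 10 & t < 20, 1, 0) + rnorm(length(t), sd = 0.01)
  tr <- sensor_trace(t = t, dff = dff)
  call <- classify_responder(tr, c(0, 10), c(10, 20))
  expect_true(call$responder)
  expect_equal(call$peak_value, 1, tolerance = 0.1)
  expect_gte(call$peak_time, 10)

  # flat noise-free trace: 0 > 0 is false
  tr0 <- sensor_trace(t = t, dff = rep(0, length(t)))
  expect_false(classify_responder(tr0, c(0, 10), c(10, 20))$responder)

  # threshold arithmetic with a known baseline: single-sample filter so the
  # smoothed trace equals the input
  base <- rep(c(0.1, -0.1), 50)
  thr <- mean(base) + 3 * sd(base)
  for (eps in c(-0.01, 0.01)) {
    dff <- c(base, rep(thr + eps, 101))
    tr <- sensor_trace(t = t, dff = dff)
    call <- classify_responder(tr, c(0, 10), c(10, 20), filter_width = 0.1)
    expect_identical(call$responder, eps > 0)
  }

  # decrease direction mirrors the rule with the sign flipped
  dff <- c(base, rep(-thr - 0.01, 101))
  tr <- sensor_trace(t = t, dff = dff)
  expect_true(classify_responder(tr, c(0, 10), c(10, 20), filter_width = 0.1,
                                 direction = "decrease")$responder)

  # failing the upstream background gate vetoes the call
  dff <- c(base, rep(1, 101))
  tr <- sensor_trace(t = t, dff = dff)
  call <- classify_responder(tr, c(0, 10), c(10, 20),
                             above_background = FALSE)
  expect_false(call$responder)
  expect_identical(call$reason, "below_background")
})

test_that("responder calls are monotone in the response amplitude", {
  set.seed(13)
  t <- seq(0, 20, 0.1)
  for (i in 1:10) {
    dff <- rnorm(length(t), sd = 0.05)
    tr <- sensor_trace(t = t, dff = dff)
    up <- dff + ifelse(t >= 10 & t < 20, runif(1, 0.01, 0.5), 0)
    tr_up <- sensor_trace(t = t, dff = up)
    if (classify_responder(tr, c(0, 10), c(10, 20))$responder)
      expect_true(classify_responder(tr_up, c(0, 10), c(10, 20))$responder)
  }
})

test_that("window metrics: trapezoidal AUC and extrema on the raw trace", {
  t <- seq(0, 10, 0.1)
  tr <- sensor_trace(t = t, dff = rep(1, length(t)))
  expect_equal(window_metric(tr, c(0, 11), "auc"), 10)
  tr0 <- sensor_trace(t = t, dff = rep(0, length(t)))
  expect_equal(window_metric(tr0, c(0, 11), "auc"), 0)

  # triangular ramp 0 -> 1 -> 0 over 10 s: area 5, trapezoid rule is exact
  tri <- 1 - abs(t - 5) / 5
  trt <- sensor_trace(t = t, dff = tri)
  expect_equal(window_metric(trt, c(0, 11), "auc"), 5)
  expect_equal(window_metric(trt, c(0, 11), "max"), 1)
  expect_equal(window_metric(trt, c(0, 11), "min"), 0)

  # additivity over adjacent windows sharing a boundary sample
  set.seed(31)
  x <- rnorm(length(t))
  trx <- sensor_trace(t = t, dff = x)
  expect_equal(
    window_metric(trx, c(0, 5.05), "auc") +
      window_metric(trx, c(5, 11), "auc"),
    window_metric(trx, c(0, 11), "auc"),
    tolerance = 1e-12)
  expect_error(window_metric(trx, c(50, 60), "auc"), "no samples")
})

test_that("calcium pre-stimulus exclusion matches a brute-force oracle", {
  t <- seq(0, 30, 0.1)
  # all-flat traces: none excluded
  flat <- lapply(1:3, function(i)
    sensor_trace(t = t, dff = rep(0, length(t)), trace_id = paste0("f", i),
                 genotype = "wt"))
  expect_true(all(gcamp_prestimulus_exclusion(flat)$keep))

  # a large transient among flat-ish traces: exactly that trace excluded
  set.seed(41)
  mk <- function(id, bump = 0) {
    dff <- rnorm(length(t), sd = 0.05)
    if (bump > 0) dff <- dff + bump * exp(-((t - 5) / 0.5)^2 / 2)
    sensor_trace(t = t, dff = dff, trace_id = id, genotype = "wt")
  }
  trs <- list(mk("a"), mk("b"), mk("c"), mk("d", bump = 10))
  flags <- gcamp_prestimulus_exclusion(trs)
  expect_identical(flags$keep, c(TRUE, TRUE, TRUE, FALSE))

  # random synthetic groups agree with the independent re-derivation
  for (rep_i in 1:4) {
    dff_list <- lapply(1:6, function(i)
      rnorm(length(t), sd = 0.05) +
        if (i == 1) 0.4 * exp(-((t - 4) / 0.5)^2 / 2) else 0)
    group <- rep(c("g1", "g2"), each = 3)
    trs <- Map(function(x, i, g)
      sensor_trace(t = t, dff = x, trace_id = paste0("r", i), genotype = g),
      dff_list, seq_along(dff_list), group)
    flags <- gcamp_prestimulus_exclusion(trs)
    expect_identical(flags$keep,
                     oracle_gcamp_rule(dff_list, group, dt = 0.1))
  }
})

test_that("expression normalisation divides mean baseline F' by intensity", {
  t <- seq(0, 10, 0.1)
  tr <- sensor_trace(t = t, F = rep(100, length(t)), excitation = 50)
  expect_equal(normalize_expression(tr, c(0, 10)), 2)
  tr <- sensor_trace(t = t, F = rep(12, length(t)), F_bg = rep(2, length(t)))
  expect_equal(normalize_expression(tr, c(0, 10), excitation_intensity = 5), 2)
  tr <- sensor_trace(t = t, F = rep(3, length(t)), F_bg = rep(3, length(t)))
  expect_equal(normalize_expression(tr, c(0, 10), excitation_intensity = 5), 0)
  expect_error(normalize_expression(tr, c(0, 10), excitation_intensity = 0),
               "positive")
})

test_that("trace ranking is a stable descending sort on window means", {
  t <- seq(0, 20, 0.1)
  mk <- function(m) sensor_trace(t = t, dff = rep(m, length(t)))
  expect_identical(rank_traces(list(mk(0.5), mk(0.1), mk(0.9)), c(10, 15)),
                   c(3L, 1L, 2L))
  expect_identical(rank_traces(list(mk(0.2), mk(0.2), mk(0.2)), c(10, 15)),
                   1:3)
  # exact comparison semantics: 1e-12 apart is still distinct
  expect_identical(rank_traces(list(mk(0.2 - 1e-12), mk(0.2)), c(10, 15)),
                   c(2L, 1L))
})
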