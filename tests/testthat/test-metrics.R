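test_that("plateau detection recovers flat tops, levels and drifts", {
  tr <- trapezoid_trace(n_tops = 3, level = 20, top_s = 6.5)
  pl <- detect_plateaus(tr, min_duration = 5)
  expect_equal(nrow(pl), 3L)
  expect_equal(pl$mean_amplitude, rep(20, 3), tolerance = 1e-9)
  expect_equal(pl$drift, rep(0, 3), tolerance = 1e-9)
  # noise-free corners recovered to within one sample interval
  expect_equal(pl$duration, rep(6.5, 3), tolerance = 1 / 50 + 1e-12)

  tilted <- trapezoid_trace(n_tops = 3, level = 20, top_s = 6.5, tilt = -0.4)
  pl2 <- detect_plateaus(tilted, min_duration = 5)
  expect_equal(pl2$drift, rep(-0.4, 3), tolerance = 1e-6)

  # featureless trace: no qualifying segment, empty result (not an error)
  flat_sine <- sinusoid_trace(duration = 30, A = 4)
  expect_equal(nrow(detect_plateaus(flat_sine, min_duration = 5)), 0L)
})

test_that("plateau detection survives tracker-level noise", {
  set.seed(61)
  tr <- trapezoid_trace(n_tops = 3, level = 20, top_s = 6.5)
  tr$samples$amplitude <- tr$samples$amplitude +
    rnorm(length(tr$samples$amplitude), sd = 0.06 * sqrt(2))
  noisy <- breathing_trace(tr$samples$t, tr$samples$amplitude)
  pl <- detect_plateaus(noisy, min_duration = 5)
  expect_equal(nrow(pl), 3L)
  expect_equal(pl$mean_amplitude, rep(20, 3), tolerance = 0.01)
  expect_equal(pl$duration, rep(6.5, 3), tolerance = 0.3)
  expect_equal(pl$drift, rep(0, 3), tolerance = 0.05)
})

test_that("plateau drift is the OLS slope and handles degenerate input", {
  t <- seq(0, 5, 0.02)
  expect_equal(plateau_drift(t, rep(7, length(t))), 0, tolerance = 1e-12)
  expect_equal(plateau_drift(t, 3 - 0.8 * t), -0.8, tolerance = 1e-12)
  # offset invariance
  expect_equal(plateau_drift(t, 100 + 3 - 0.8 * t), -0.8, tolerance = 1e-10)

  expect_error(plateau_drift(rep(1, 5), rnorm(5)), class = "bt_degenerate_fit")
  expect_error(plateau_drift(1, 1), class = "bt_validation_error")

  # seeded Monte-Carlo: estimated slope falls inside its own 99% CI of b
  set.seed(21)
  b <- -0.4
  inside <- vapply(1:50, function(i) {
    y <- 5 + b * t + rnorm(length(t), sd = 0.3)
    fit <- stats::lm(y ~ t)
    ci <- stats::confint(fit, "t", level = 0.99)
    b >= ci[1] && b <= ci[2]
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("baseline shift matches closed forms and is translation-equivariant", {
  sine <- sinusoid_trace(duration = 60, f = 0.2, A = 20)
  expect_equal(baseline_shift(sine), 0, tolerance = 1e-9)

  # ramp r*t adds r * (t_last_min - t_first_min); oracle from a dense grid
  r <- -0.02
  ramped <- sinusoid_trace(duration = 60, f = 0.2, A = 20, ramp = r)
  # brute-force minima on a dense grid; the window [1, 59] excludes the
  # near-zero-prominence dimple the ramp creates right at the boundary
  tg <- seq(1, 59, 1e-4)
  xg <- 10 * (1 - cos(2 * pi * 0.2 * tg)) + r * tg
  loc <- which(diff(sign(diff(xg))) > 0) + 1L
  oracle <- xg[loc[length(loc)]] - xg[loc[1]]
  expect_equal(baseline_shift(ramped), oracle, tolerance = 0.02)

  # adding a constant changes nothing
  shifted <- sinusoid_trace(duration = 60, f = 0.2, A = 20, ramp = r,
                            offset = 140)
  expect_equal(baseline_shift(shifted), baseline_shift(ramped),
               tolerance = 1e-9)

  mono <- breathing_trace(seq(0, 30, 0.02), seq(0, 30, 0.02) * 0.5)
  expect_error(baseline_shift(mono), class = "bt_undefined_metric")
})

test_that("cycle segmentation recovers period and amplitude of periodic signals", {
  sine <- sinusoid_trace(duration = 30, f = 0.2, A = 20)
  cy <- segment_cycles(sine)
  expect_gte(nrow(cy), 4L)
  expect_equal(cy$duration, rep(5, nrow(cy)), tolerance = 1 / 50 + 1e-12)
  expect_equal(cy$amplitude, rep(20, nrow(cy)), tolerance = 1e-6)

  # cos^6 guidance waveform: maxima T apart
  t <- seq(0, 30, 0.02)
  g <- breathing_trace(t, guidance_waveform(t, guidance_params(A = 30, T = 10)))
  cyg <- segment_cycles(g)
  expect_equal(cyg$duration, rep(10, nrow(cyg)), tolerance = 1 / 50 + 1e-12)

  # period recovery holds down to modest sampling rates (>= 20 f)
  for (rate in c(5, 10, 25)) {
    s <- sinusoid_trace(duration = 40, f = 0.2, A = 20, rate = rate)
    cyr <- segment_cycles(s)
    expect_equal(cyr$duration, rep(5, nrow(cyr)), tolerance = 1 / rate + 1e-12)
  }

  expect_equal(nrow(segment_cycles(breathing_trace(0:20, rep(0, 21)))), 0L)
})

test_that("DIBH report aggregates plateau statistics with sample SDs", {
  # direct arithmetic oracle on three plateau levels
  tr <- trapezoid_trace(n_tops = 3, level = 1, top_s = 6.5)
  # scale the three tops to 10.9, 10.7, 11.1 by piecewise multiplication
  lvls <- c(10.9, 10.7, 11.1)
  s <- tr$samples
  block <- 2 * 1 + 6.5 + 5
  top_idx <- findInterval(s$t, 5 + (0:2) * block)
  s$amplitude <- s$amplitude * lvls[pmax(1, pmin(3, top_idx))]
  tr2 <- breathing_trace(s$t, s$amplitude)
  rep2 <- dibh_report(tr2, min_duration = 5)
  expect_equal(rep2$amplitude_mean, mean(lvls), tolerance = 1e-9)
  expect_equal(rep2$amplitude_sd, stats::sd(lvls), tolerance = 1e-9)
  expect_equal(rep2$amplitude_sd, 0.2, tolerance = 1e-9)

  # identical plateaus: SD exactly 0
  rep3 <- dibh_report(trapezoid_trace(n_tops = 3, level = 20), min_duration = 5)
  expect_equal(rep3$amplitude_sd, 0, tolerance = 1e-9)
  expect_equal(rep3$amplitude_mean, 20, tolerance = 1e-9)

  # single plateau: SDs undefined, flagged
  one <- dibh_report(trapezoid_trace(n_tops = 1, level = 20), min_duration = 5)
  expect_false(one$sd_defined)
  expect_true(is.na(one$amplitude_sd))
})

test_that("4DCT report summarises cycles and propagates baseline shift", {
  sine <- sinusoid_trace(duration = 60, f = 0.2, A = 20)
  rep4 <- fourd_report(sine)
  expect_equal(rep4$amplitude_mean, 20, tolerance = 1e-6)
  expect_equal(rep4$duration_mean, 5, tolerance = 1 / 50)
  expect_equal(rep4$baseline_shift, 0, tolerance = 1e-9)

  # amplitude-modulated breathing has positive amplitude SD
  t <- seq(0, 60, 0.02)
  am <- breathing_trace(t, (10 + 2 * sin(2 * pi * t / 60)) *
                          (1 - cos(2 * pi * 0.2 * t)))
  repam <- fourd_report(am)
  expect_gt(repam$amplitude_sd, 0)

  expect_error(fourd_report(breathing_trace(seq(0, 3, 0.02),
                                            rep(0, 151))),
               class = "bt_undefined_metric")
})

test_that("sample SDs follow the n-1 convention (brute-force check)", {
  x <- c(10.9, 10.7, 11.1, 12.0)
  brute <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  cs <- cohort_summary(x, rep(1, 4))
  expect_equal(cs$sd_total, brute, tolerance = 1e-12)
})

test_that("cohort aggregation reproduces the published volunteer table rows", {
  rhu <- function(x) round_report(x, 1)
  dibh <- volunteer_summaries("dibh")
  fdct <- volunteer_summaries("4dct")
  agg <- function(df, scen, mcol, scol) {
    d <- df[df$scenario == scen, ]
    cohort_summary(d[[mcol]], d[[scol]])
  }

  # DIBH amplitude columns
  a <- agg(dibh, "audio", "amplitude_mean_mm", "amplitude_sd_mm")
  expect_identical(rhu(c(a$mean_total, a$sd_total, a$mean_of_sds, a$sd_of_sds)),
                   c(12.6, 6.5, 1.1, 0.7))
  v <- agg(dibh, "visual", "amplitude_mean_mm", "amplitude_sd_mm")
  expect_identical(rhu(c(v$mean_total, v$sd_total, v$mean_of_sds, v$sd_of_sds)),
                   c(11.0, 2.9, 0.5, 0.5))
  vt <- agg(dibh, "visual_table", "amplitude_mean_mm", "amplitude_sd_mm")
  expect_identical(rhu(c(vt$mean_total, vt$sd_total, vt$mean_of_sds, vt$sd_of_sds)),
                   c(14.9, 4.3, 0.4, 0.3))

  # DIBH drift columns
  ad <- agg(dibh, "audio", "drift_mean_mm_s", "drift_sd_mm_s")
  expect_identical(rhu(c(ad$mean_total, ad$sd_total, ad$mean_of_sds, ad$sd_of_sds)),
                   c(-0.4, 0.3, 0.2, 0.1))
  vd <- agg(dibh, "visual", "drift_mean_mm_s", "drift_sd_mm_s")
  expect_identical(rhu(c(vd$mean_total, vd$sd_total)), c(-0.2, 0.2))
  vtd <- agg(dibh, "visual_table", "drift_mean_mm_s", "drift_sd_mm_s")
  expect_identical(rhu(c(vtd$mean_total, vtd$sd_total)), c(-0.2, 0.2))

  # 4DCT duration columns
  du_a <- agg(fdct, "audio", "duration_mean_s", "duration_sd_s")
  expect_identical(rhu(c(du_a$mean_total, du_a$sd_total,
                         du_a$mean_of_sds, du_a$sd_of_sds)),
                   c(5.5, 2.0, 0.5, 0.4))
  du_v <- agg(fdct, "visual", "duration_mean_s", "duration_sd_s")
  expect_identical(rhu(c(du_v$mean_total, du_v$sd_total,
                         du_v$mean_of_sds, du_v$sd_of_sds)),
                   c(9.7, 1.1, 1.3, 0.9))
  du_vt <- agg(fdct, "visual_table", "duration_mean_s", "duration_sd_s")
  expect_identical(rhu(c(du_vt$mean_total, du_vt$sd_total,
                         du_vt$mean_of_sds, du_vt$sd_of_sds)),
                   c(9.7, 0.5, 0.8, 0.8))

  # 4DCT amplitude columns (all three scenarios aggregate cleanly too)
  am_a <- agg(fdct, "audio", "amplitude_mean_mm", "amplitude_sd_mm")
  expect_identical(rhu(c(am_a$mean_total, am_a$sd_total,
                         am_a$mean_of_sds, am_a$sd_of_sds)),
                   c(16.2, 9.5, 1.3, 0.7))
  am_v <- agg(fdct, "visual", "amplitude_mean_mm", "amplitude_sd_mm")
  expect_identical(rhu(c(am_v$mean_total, am_v$sd_total,
                         am_v$mean_of_sds, am_v$sd_of_sds)),
                   c(29.1, 5.2, 2.8, 1.8))

  # two identical subjects: zero spread
  two <- cohort_summary(c(5, 5), c(1, 1))
  expect_equal(two$sd_total, 0)
  expect_error(cohort_summary(5, 1), class = "bt_undefined_metric")
})

test_that("scenario comparison follows the normality-gated decision rule", {
  set.seed(31)
  a <- rnorm(10, mean = 10, sd = 1)
  b <- a + rnorm(10, sd = 0.5)
  res <- compare_scenarios(a, b)
  expect_equal(res$test, "paired_t")
  expect_equal(res$p_value, stats::t.test(a, b, paired = TRUE)$p.value,
               tolerance = 1e-12)

  # large shift: clearly significant
  res2 <- compare_scenarios(a, a + 5 + rnorm(10, sd = 0.3))
  expect_lt(res2$p_value, 0.05)

  # exactly constant shift leaves the paired t-test undefined
  expect_error(compare_scenarios(a, a + 5), class = "bt_degenerate_test")

  # non-normal input routes to Mann-Whitney U
  skewed_a <- exp(rnorm(20, sd = 1.5))
  skewed_b <- exp(rnorm(20, sd = 1.5)) + 1
  res3 <- compare_scenarios(skewed_a, skewed_b)
  expect_equal(res3$test, "mann_whitney_u")
  expect_equal(res3$p_value,
               suppressWarnings(stats::wilcox.test(skewed_a, skewed_b))$p.value,
               tolerance = 1e-12)

  # unpaired mode uses the independent t-test when normality holds
  res4 <- compare_scenarios(a, b, paired = FALSE)
  expect_equal(res4$test, "independent_t")

  expect_error(compare_scenarios(a, a), class = "bt_degenerate_test")
})
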