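test_that("disk membership by pixel-center distance gives the expected counts", {
  # pixel 0.1 um, centroid on a pixel center: 250 nm disk -> 21 pixels
  a <- array(100, dim = c(12, 21, 21))
  st <- time_lapse_stack(a, 0.25, 0.1)
  pair <- extract_traces(st, list(centroid_x_um = 1.0, centroid_y_um = 1.0,
                                  t_onset_s = 1))
  expect_equal(pair$n_inner, 21)
  # brute-force enumeration over integer offsets
  n_in <- sum(outer((-5:5)^2, (-5:5)^2, `+`) <= 2.5^2)
  n_out <- sum(outer((-6:6)^2, (-6:6)^2, `+`) <= 5^2)
  expect_equal(pair$n_inner, n_in)
  expect_equal(pair$n_annulus, n_out - n_in)
  # uniform image: border equals center in per-pixel mean
  expect_equal(pair$center, pair$border)
})

test_that("edge-clipped annuli are unclassifiable", {
  a <- array(100, dim = c(12, 21, 21))
  st <- time_lapse_stack(a, 0.25, 0.1)
  pair <- extract_traces(st, list(centroid_x_um = 0.2, centroid_y_um = 1.0))
  expect_false(pair$valid)
  expect_identical(pair$reason, "edge_clipped")
})

test_that("alignment re-zeroes time at the center maximum", {
  pair <- structure(list(times_s = (0:15) * 0.25,
                         center = c(1:8, 7:0) * 1.0 + 10,
                         border = rnorm(16), valid = TRUE, reason = ""),
                    class = "trace_pair")
  al <- align_to_peak(pair)
  expect_equal(al$times_s[1], 0)
  expect_equal(al$center[1], max(pair$center))
  expect_equal(length(al$center), 9)  # samples 8..16
  al2 <- align_to_peak(al)
  expect_equal(al2$times_s, al$times_s)

  # max at the final frame -> nothing to fit
  pair$center <- seq_len(16) * 1.0
  expect_false(align_to_peak(pair)$valid)
})

test_that("exponential decay fits recover analytic half-lives", {
  t <- seq(0, 10, by = 0.25)
  for (tau in c(0.5, 1, 2, 5)) {
    f <- fit_decay(t, 10 * exp(-t / tau) + 1)
    expect_true(f$valid)
    expect_lt(abs(f$tau_s - tau) / tau, 1e-6)
    expect_lt(abs(f$half_life_s - tau * log(2)), 1e-5)
    expect_lt(abs(f$offset - 1), 1e-5)
  }
  expect_false(fit_decay(t, rep(3, length(t)))$valid)
  expect_false(fit_decay(t[1:3], c(3, 2, 1))$valid)
})

test_that("noisy decay fits recover tau within 5% in the median", {
  t <- seq(0, 8, by = 0.25)
  set.seed(42)
  taus <- vapply(1:100, function(i) {
    y <- 10 * exp(-t / 1.5) + 1 + rnorm(length(t), 0, 1)  # SNR 10
    f <- fit_decay(t, y)
    if (f$valid) f$tau_s else NA_real_
  }, numeric(1))
  expect_lt(abs(median(taus, na.rm = TRUE) - 1.5) / 1.5, 0.05)
})

test_that("border decay ratio is 1 for identical traces and propagates invalids", {
  t <- seq(0, 8, by = 0.25)
  y <- 10 * exp(-t / 2) + 1
  pair <- structure(list(times_s = t, center = y, border = y,
                         valid = TRUE, reason = ""), class = "trace_pair")
  bd <- border_decay_ratio(pair)
  expect_true(bd$valid)
  expect_equal(bd$ratio, 1, tolerance = 1e-6)
  expect_identical(classify_fusion(bd$ratio), "full_fusion")

  pair$border <- rep(5, length(t))
  bd <- border_decay_ratio(pair)
  expect_false(bd$valid)
  expect_match(bd$reason, "^border_")
})

test_that("classification boundary follows the 3-SD rule inclusively", {
  m <- ratio_model()
  expect_identical(classify_fusion(0.89, m), "full_fusion")
  expect_identical(classify_fusion(0.47, m), "full_fusion")   # mu - 3 sigma
  expect_identical(classify_fusion(0.47 - 1e-12, m), "kiss_and_run")
  expect_identical(classify_fusion(0.20, m), "kiss_and_run")
  expect_identical(classify_fusion(Inf, m), "unclassifiable")
  expect_identical(classify_fusion(2.5, m, two_sided = TRUE), "unclassifiable")
  expect_identical(classify_fusion(2.5, m, two_sided = FALSE), "full_fusion")
})

test_that("classification is invariant to intensity rescaling", {
  pair <- align_to_peak(event_trace_pair("full_fusion", seed = 77))
  r1 <- border_decay_ratio(pair)
  pair2 <- pair
  pair2$center <- pair2$center * 25
  pair2$border <- pair2$border * 25
  r2 <- border_decay_ratio(pair2)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-6)
})

test_that("the ratio mixture is recovered and falls back sensibly", {
  set.seed(8)
  ratios <- c(rnorm(1000, 0.89, 0.14), rnorm(1000, 0.25, 0.08))
  m <- fit_ratio_population(ratios)
  expect_identical(m$source, "fitted")
  expect_lt(abs(m$mu - 0.89), 0.02)
  expect_lt(abs(m$sigma - 0.14), 0.02)

  # too few ratios -> reference defaults
  m5 <- fit_ratio_population(c(0.9, 0.8, 0.85, 0.7, 0.95))
  expect_identical(m5$source, "paper_default")
  expect_equal(m5$mu, 0.89)
  expect_equal(m5$sigma, 0.14)

  # degenerate (constant) ratios -> defaults with a warning
  expect_warning(md <- fit_ratio_population(rep(0.9, 50)), "defaults")
  expect_identical(md$source, "paper_default")
})

test_that("simulated fusion modes are classified correctly end to end", {
  n <- 25
  calls_full <- vapply(seq_len(n), function(s)
    classify_simulated("full_fusion", 400 + s), character(1))
  calls_kiss <- vapply(seq_len(n), function(s)
    classify_simulated("kiss_and_run", 900 + s), character(1))
  acc <- (sum(calls_full == "full_fusion") +
            sum(calls_kiss == "kiss_and_run")) / (2 * n)
  expect_gte(acc, 0.9)
})

test_that("classify_events augments a detected table with fusion calls", {
  ms <- separated_event_stack(seed = 55, n_ev = 5, amplitude_sd = 20)
  det <- accepted_events(detect_events(ms$sim$stack, detection_params(),
                                       ms$geom))
  out <- classify_events(ms$sim$stack, det, use_population_fit = FALSE)
  expect_true(all(c("border_decay_ratio", "fusion_mode", "t_half_center_s",
                    "model_source") %in% names(out)))
  expect_identical(unique(out$model_source), "paper_default")
  classified <- out[!is.na(out$fusion_mode) &
                      out$fusion_mode != "unclassifiable", ]
  for (i in seq_len(nrow(classified))) {
    d <- sqrt((ms$sim$truth$x_um - classified$centroid_x_um[i])^2 +
                (ms$sim$truth$y_um - classified$centroid_y_um[i])^2)
    j <- which.min(d)
    if (d[j] <= 0.3)
      expect_identical(classified$fusion_mode[i], ms$sim$truth$mode[j])
  }
})
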