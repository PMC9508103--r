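test_that("a constant noiseless stack yields zero events", {
  geom <- square_geometry(32L)
  a <- array(100, dim = c(20, 32, 32))
  det <- detect_events(time_lapse_stack(a, 0.25, 0.1), detection_params(),
                       geom)
  expect_equal(sum(det$accepted), 0)
})

test_that("implanted well-separated events are recovered with matching truth", {
  ms <- separated_event_stack(seed = 21, n_ev = 6, amplitude_sd = 10)
  det <- accepted_events(detect_events(ms$sim$stack, detection_params(),
                                       ms$geom))
  m <- match_detections(det, ms$sim$truth)
  expect_gte(m["tp"], 5)          # >= 5/6 on a single stack
  expect_equal(unname(m["fp"]), 0)
  # positions within 1 px, onsets within 1 frame of the matched truth
  for (i in seq_len(nrow(ms$sim$truth))) {
    d <- sqrt((det$centroid_x_um - ms$sim$truth$x_um[i])^2 +
                (det$centroid_y_um - ms$sim$truth$y_um[i])^2)
    j <- which.min(d)
    if (d[j] > 0.5) next
    expect_lt(d[j], 0.1 + 1e-9)
    expect_lte(abs(det$t_onset_s[j] - ms$sim$truth$t_start_s[i]), 0.25 + 1e-9)
  }
})

test_that("detection is invariant to a positive intensity rescaling", {
  ms <- separated_event_stack(seed = 5, n_ev = 4, amplitude_sd = 10)
  det1 <- detect_events(ms$sim$stack, detection_params(), ms$geom)
  scaled <- ms$sim$stack
  scaled$data <- scaled$data * 11.3
  det2 <- detect_events(scaled, detection_params(), ms$geom)
  expect_equal(det1$centroid_x_um, det2$centroid_x_um, tolerance = 1e-6)
  expect_equal(det1$accepted, det2$accepted)
})

test_that("low-amplitude events are not detected (SD criterion sanity)", {
  ms <- separated_event_stack(seed = 9, n_ev = 4, amplitude_sd = 1)
  det <- accepted_events(detect_events(ms$sim$stack, detection_params(),
                                       ms$geom))
  m <- match_detections(det, ms$sim$truth)
  expect_lte(m["tp"], 1)
})

test_that("a drifting punctum is rejected as motile", {
  geom <- square_geometry(64L)
  params <- acquisition_params(n_frames = 60L, image_shape = c(64L, 64L),
                               noise_sd = 2, background_level = 100)
  # emulate drift: chain of short kiss events stepping 0.2 um per frame
  steps <- 0:9
  ev <- do.call(rbind, lapply(steps, function(s)
    single_event(2.15 + 0.2 * s, 3.15, 3 + 0.25 * s, "kiss_and_run",
                 amplitude_sd = 12, decay_tau_s = 0.45)))
  sim <- render_stack(params, geom, ev, seed = 13)
  det <- detect_events(sim$stack, detection_params(), geom)
  hits <- det[det$centroid_y_um > 2.5 & det$centroid_y_um < 3.8 &
                det$t_peak_s < 8, ]
  expect_true(nrow(hits) >= 1)
  expect_false(any(hits$accepted))
})

test_that("compartment assignment follows the soma mask", {
  geom <- square_geometry(48L, soma_radius_px = 8)
  ev <- data.frame(event_id = 1:2,
                   centroid_x_um = c(2.35, 0.4),  # center vs corner
                   centroid_y_um = c(2.35, 0.4),
                   accepted = TRUE, stringsAsFactors = FALSE)
  out <- assign_compartment(ev, geom, pixel_size_um = 0.1)
  expect_identical(out$compartment, c("soma", "processes_sheet"))

  ms <- separated_event_stack(seed = 31, n_ev = 5, amplitude_sd = 10)
  det <- accepted_events(detect_events(ms$sim$stack, detection_params(),
                                       ms$geom))
  det <- assign_compartment(det, ms$geom)
  truth_comp <- with(ms$sim$truth, ifelse(
    ms$geom$soma_mask[cbind(round(y_um / 0.1) + 1, round(x_um / 0.1) + 1)],
    "soma", "processes_sheet"))
  for (i in seq_len(nrow(det))) {
    d <- sqrt((ms$sim$truth$x_um - det$centroid_x_um[i])^2 +
                (ms$sim$truth$y_um - det$centroid_y_um[i])^2)
    j <- which.min(d)
    if (d[j] <= 0.3)
      expect_identical(det$compartment[i], truth_comp[j])
  }
})

test_that("event frequency arithmetic and Poisson recovery", {
  ev <- data.frame(accepted = rep(TRUE, 12),
                   compartment = rep(c("soma", "processes_sheet"), 6))
  expect_equal(event_frequency(ev, 60), 12)
  expect_equal(event_frequency(ev[0, ], 60), 0)
  by <- event_frequency(ev, 120, by_compartment = TRUE)
  expect_equal(by$overall, 6)
  expect_equal(by$soma, 3)

  geom <- square_geometry(16L)
  counts <- vapply(1:2000, function(s)
    nrow(sample_events(23, 0.8, 60, geom, seed = 1000 + s)), numeric(1))
  rate <- counts / 1  # per minute
  se <- sd(rate) / sqrt(length(rate))
  expect_lt(abs(mean(rate) - 23), 3 * se)
})
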