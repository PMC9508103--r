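test_that("event sampling is Poisson with the requested rate and mix", {
  geom <- square_geometry(16L)
  expect_equal(nrow(sample_events(0, 0.8, 60, geom, seed = 1)), 0)

  counts <- vapply(1:3000, function(s)
    nrow(sample_events(60, 0.8, 60, geom, seed = s)), numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 60), 3 * se)
  # variance should match the mean (Poisson), loosely
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.1)

  ev <- sample_events(23, 0.8, 2880 * 60, geom, seed = 7)
  frac <- mean(ev$mode == "full_fusion")
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / nrow(ev)))
})

test_that("event placement respects the mask and records the compartment", {
  geom <- square_geometry(32L, soma_radius_px = 6)
  ev <- sample_events(120, 0.5, 60, geom, seed = 3, pixel_size_um = 0.1)
  px <- cbind(round(ev$y_um / 0.1) + 1, round(ev$x_um / 0.1) + 1)
  expect_true(all(geom$cell_mask[px]))
  expect_identical(ev$compartment, ifelse(geom$soma_mask[px], "soma",
                                          "processes_sheet"))
  empty <- cell_geometry(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8))
  expect_error(sample_events(60, 0.5, 60, empty, seed = 1), "empty")
})

test_that("rendering is deterministic and static without events", {
  geom <- square_geometry(24L)
  params <- acquisition_params(n_frames = 12L, image_shape = c(24L, 24L),
                               noise_sd = 2)
  ev <- single_event(1.2, 1.2, 1)
  s1 <- render_stack(params, geom, ev, seed = 11)
  s2 <- render_stack(params, geom, ev, seed = 11)
  expect_identical(s1$stack$data, s2$stack$data)

  quiet <- acquisition_params(n_frames = 12L, image_shape = c(24L, 24L),
                              noise_sd = 0, bleach_tau_s = Inf,
                              background_level = 50)
  s0 <- render_stack(quiet, geom, single_event(1, 1, 1)[0, ], seed = 1)
  for (k in 1:12)
    expect_equal(s0$stack$data[k, , ], 50 * (geom$cell_mask + 0),
                 ignore_attr = TRUE)
})

test_that("render validates event positions and parameters", {
  geom <- square_geometry(24L)
  params <- acquisition_params(n_frames = 12L, image_shape = c(24L, 24L))
  expect_error(render_stack(params, geom, single_event(99, 1, 1), seed = 1),
               "outside")
  expect_error(render_stack(params, geom, single_event(NaN, 1, 1), seed = 1),
               "non-finite")
})

test_that("full-fusion spreading conserves summed intensity while the peak falls", {
  geom <- square_geometry(64L)
  params <- acquisition_params(n_frames = 30L, image_shape = c(64L, 64L),
                               noise_sd = 0, bleach_tau_s = Inf,
                               background_level = 100)
  ev <- single_event(3.15, 3.15, 1, "full_fusion", decay_tau_s = Inf,
                     rise_tau_s = 0)
  sim <- render_stack(params, geom, ev, seed = 1)
  above <- vapply(1:30, function(k) sum(sim$stack$data[k, , ] - 100),
                  numeric(1))
  onset <- 5
  expect_gt(above[onset + 1], 0)
  expect_lt(max(abs(above[(onset + 1):30] / above[onset + 1] - 1)), 0.005)
  peak_px <- vapply((onset + 1):30, function(k) max(sim$stack$data[k, , ]),
                    numeric(1))
  expect_true(all(diff(peak_px) < 0))
})

test_that("kiss-and-run events keep a fixed width while the amplitude decays", {
  geom <- square_geometry(48L)
  params <- acquisition_params(n_frames = 24L, image_shape = c(48L, 48L),
                               noise_sd = 0, background_level = 100)
  ev <- single_event(2.35, 2.35, 1, "kiss_and_run", rise_tau_s = 0)
  sim <- render_stack(params, geom, ev, seed = 1, kiss_halo_fraction = 0)
  widths <- c(); amps <- c()
  for (k in 6:14) {
    patch <- sim$stack$data[k, 17:31, 17:31] - 100
    g <- oligoexo:::fit_gaussian2d(patch, 8, 8)
    widths <- c(widths, g$sigma); amps <- c(amps, max(patch))
  }
  expect_lt(max(abs(widths / widths[1] - 1)), 0.01)
  expect_true(all(diff(amps) < 0))
})

test_that("kiss-and-run border gain stays below 5% of the center peak", {
  pair <- event_trace_pair("kiss_and_run", seed = 1, noise_sd = 0)
  geom <- square_geometry(48L)
  params <- acquisition_params(n_frames = 60L, image_shape = c(48L, 48L),
                               noise_sd = 0, background_level = 100)
  sim <- render_stack(params, geom, single_event(2.35, 2.35, 3,
                                                 "kiss_and_run"), seed = 1)
  peak <- max(sim$stack$data) - 100
  expect_lt((max(pair$border) - 100) / peak, 0.05)
})

test_that("sheath layouts reproduce the closed-form paranodal fraction", {
  # margins covering the whole sheath
  sh <- make_sheath_layout(6, enrichment = 1, n_events_per_sheath = 200,
                           seed = 2)
  expect_equal(paranodal_fraction(sh[[1]]), 1)

  # uniform: L = 12, margin 3 on each side -> expected 1/2
  sh <- make_sheath_layout(12, enrichment = 1, n_events_per_sheath = 1e5,
                           seed = 3)
  p <- paranodal_fraction(sh[[1]])
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 1e5))

  # enrichment 3, L = 30: p = 3*6 / (3*6 + 24)
  sh <- make_sheath_layout(30, enrichment = 3, n_events_per_sheath = 1e5,
                           seed = 4)
  p_exp <- 18 / 42
  p <- paranodal_fraction(sh[[1]])
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e5))
  expect_true(all(sh[[1]]$event_positions_um >= 0 &
                    sh[[1]]$event_positions_um <= 30))
})

test_that("node profiles have the class-defining peak structure", {
  m <- make_node_profile("mature", noise_sd = 0, seed = 1)
  expect_equal(count_local_maxima(m$caspr, 0), 2)
  expect_equal(count_local_maxima(m$ankg, 0), 1)

  h <- make_node_profile("heminode", noise_sd = 0, seed = 1)
  expect_equal(count_local_maxima(h$caspr, 0), 1)
  expect_equal(count_local_maxima(h$ankg, 0), 1)

  cl <- make_node_profile("cluster", noise_sd = 0, seed = 1,
                          cluster_channel = "caspr")
  expect_equal(count_local_maxima(cl$caspr, 0), 1)
  expect_identical(unique(cl$ankg), 0)
})
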