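# Shared fixtures: all synthetic, built in code at test time.

# Uniform square geometry: every pixel is cell, central disk is soma.
square_geometry <- function(n = 48L, soma_radius_px = 8) {
  rows <- cols <- n
  d <- sqrt(outer((seq_len(rows) - (rows + 1) / 2)^2,
                  (seq_len(cols) - (cols + 1) / 2)^2, `+`))
  cell_geometry(matrix(TRUE, rows, cols), d <= soma_radius_px)
}

# One event of the given mode, ready for render_stack().
single_event <- function(x_um, y_um, t_start_s, mode = "full_fusion",
                         amplitude_sd = 20, decay_tau_s = 1.5,
                         diffusion_um2_s = if (mode == "full_fusion") 0.025 else 0,
                         rise_tau_s = 0.2) {
  data.frame(x_um = x_um, y_um = y_um, t_start_s = t_start_s, mode = mode,
             amplitude_sd = amplitude_sd, diffusion_um2_s = diffusion_um2_s,
             decay_tau_s = decay_tau_s, rise_tau_s = rise_tau_s,
             stringsAsFactors = FALSE)
}

# A stack with n_ev well-separated implanted events (>= 3 um apart,
# >= 12 frames apart) on an oligodendrocyte-shaped mask, with truth.
separated_event_stack <- function(seed, n_ev = 6, amplitude_sd = 10,
                                  n_frames = 120L, shape = c(100L, 100L),
                                  mode_cycle = c("full_fusion", "kiss_and_run")) {
  geom <- make_oligo_geometry(shape, 0.1, soma_radius_um = 2.5,
                              sheet_inner_um = 3.2, sheet_outer_um = 4.8)
  params <- acquisition_params(n_frames = n_frames, image_shape = shape,
                               noise_sd = 2, background_level = 100)
  ok <- which(geom$cell_mask, arr.ind = TRUE)
  ok <- ok[ok[, 1] > 8 & ok[, 1] < shape[1] - 7 &
             ok[, 2] > 8 & ok[, 2] < shape[2] - 7, ]
  set.seed(seed)
  pos <- ok[sample(nrow(ok), 1), , drop = FALSE]
  tries <- 0
  while (nrow(pos) < n_ev && tries < 1000) {
    tries <- tries + 1
    cand <- ok[sample(nrow(ok), 1), ]
    if (all(sqrt(colSums((t(pos) - cand)^2)) >= 31)) pos <- rbind(pos, cand)
  }
  n <- nrow(pos)
  ev <- data.frame(x_um = (pos[, 2] - 1) * 0.1, y_um = (pos[, 1] - 1) * 0.1,
                   t_start_s = (seq_len(n) * 12 + 3) * 0.25,
                   mode = rep(mode_cycle, length.out = n),
                   amplitude_sd = amplitude_sd, diffusion_um2_s = 0.025,
                   decay_tau_s = 1.5, rise_tau_s = 0.2,
                   stringsAsFactors = FALSE)
  ev$diffusion_um2_s[ev$mode == "kiss_and_run"] <- 0
  list(sim = render_stack(params, geom, ev, seed = seed), geom = geom,
       params = params)
}

# Match detections to truth; returns c(tp, fn, fp).
match_detections <- function(detected, truth, dist_um = 0.5, dt_s = 1.0) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0; fn <- 0
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((detected$centroid_x_um - truth$x_um[i])^2 +
                (detected$centroid_y_um - truth$y_um[i])^2)
    ok <- which(d <= dist_um & abs(detected$t_peak_s - truth$t_start_s[i]) <= dt_s &
                  !used)
    if (length(ok)) { tp <- tp + 1; used[ok[1]] <- TRUE } else fn <- fn + 1
  }
  c(tp = tp, fn = fn, fp = sum(!used))
}

# Render a single event in a small stack and return its aligned trace pair.
event_trace_pair <- function(mode, seed, amplitude_sd = 20, noise_sd = 2) {
  geom <- square_geometry(48L)
  params <- acquisition_params(n_frames = 60L, image_shape = c(48L, 48L),
                               noise_sd = noise_sd, background_level = 100)
  ev <- single_event(2.35, 2.35, 3, mode, amplitude_sd = amplitude_sd)
  sim <- render_stack(params, geom, ev, seed = seed)
  extract_traces(sim$stack,
                 list(centroid_x_um = 2.35, centroid_y_um = 2.35, t_onset_s = 3))
}

# Classify one simulated event the way classify_events() does.
classify_simulated <- function(mode, seed, model = ratio_model(),
                               amplitude_sd = 20) {
  bd <- border_decay_ratio(align_to_peak(event_trace_pair(mode, seed,
                                                          amplitude_sd)))
  if (bd$valid) return(classify_fusion(bd$ratio, model))
  if (grepl("^border_", bd$reason) && !is.null(bd$fit_center) &&
        bd$fit_center$valid) return("kiss_and_run")
  "unclassifiable"
}

# Brute-force prominence-based maxima count (quadratic scan), the
# independent oracle for count_local_maxima() with no smoothing.
brute_force_maxima <- function(x, min_prominence_fraction = 0.2) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (rng == 0) return(0L)
  count <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    is_interior <- i > 1 && j < n
    if (is_interior && x[i - 1] < x[i] && x[j + 1] < x[i]) {
      h <- x[i]
      left_base <- h
      if (any(x[1:(i - 1)] > h)) {
        k <- max(which(x[1:(i - 1)] > h))
        left_base <- min(x[k:(i - 1)])
      } else left_base <- min(x[1:(i - 1)])
      right_base <- h
      if (any(x[(j + 1):n] > h)) {
        k <- j + min(which(x[(j + 1):n] > h))
        right_base <- min(x[(j + 1):k])
      } else right_base <- min(x[(j + 1):n])
      if (h - max(left_base, right_base) >= min_prominence_fraction * rng)
        count <- count + 1L
    }
    i <- j + 1L
  }
  count
}
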