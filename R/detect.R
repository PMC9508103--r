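#' Correct global photobleaching by exponential curve fitting
#'
#' Fits `mean(t) = A * exp(-t / tau) + C` to the frame-wise spatial mean
#' intensity by least squares and divides every frame by the fitted
#' curve normalised to its value at `t = 0`, removing the slow global
#' decay of fluorescence under continuous illumination while preserving
#' the intensity scale of the first frame. If the whole-field mean shows
#' no decay, or the fit does not converge from any starting point, the
#' stack is returned unchanged with `tau_s = Inf` and a warning.
#'
#' @param stack A `TimeLapseStack` (raw reference).
#' @return A list of class `bleach_correction`: `stack` (corrected),
#'   `A`, `tau_s`, `C`, `curve` (the fitted frame-wise means) and
#'   `corrected` (logical).
#' @export
correct_bleaching <- function(stack) {
  stopifnot(inherits(stack, "TimeLapseStack"))
  m <- apply(stack$data, 1, mean)
  if (any(m <= 0)) stop("whole-field mean must be positive in every frame")
  tvec <- frame_times(stack)
  span <- max(tvec)
  flat <- (max(m) - min(m)) <= 1e-10 * max(m)
  if (!flat) {
    # no-decay pre-test: require a detectable monotone decline of the
    # frame means before attempting the exponential fit
    lin <- stats::lm(m ~ tvec)
    decline <- -stats::coef(lin)[[2]] * span
    if (decline < 2 * stats::sd(stats::resid(lin))) flat <- TRUE
  }
  fit <- NULL
  if (!flat) {
    df <- data.frame(t = tvec, y = m)
    for (tau0 in span * c(1 / 3, 1, 1 / 10, 3)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C, data = df,
                          start = list(A = max(m[1] - min(m), 1e-6 * m[1]),
                                       tau = tau0, C = min(m)),
                          lower = c(A = 0, tau = 1e-9, C = 0),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
  }
  if (flat || is.null(fit)) {
    if (!flat) warning("bleach fit did not converge; returning uncorrected stack")
    return(structure(list(stack = stack, A = 0, tau_s = Inf,
                          C = mean(m), curve = rep(mean(m), length(m)),
                          corrected = FALSE),
                     class = "bleach_correction"))
  }
  cf <- stats::coef(fit)
  curve <- cf[["A"]] * exp(-tvec / cf[["tau"]]) + cf[["C"]]
  norm <- curve / curve[1]
  data <- stack$data
  for (k in seq_along(norm)) data[k, , ] <- data[k, , ] / norm[k]
  structure(list(stack = time_lapse_stack(data, stack$frame_interval_s,
                                          stack$pixel_size_um),
                 A = cf[["A"]], tau_s = cf[["tau"]], C = cf[["C"]],
                 curve = curve, corrected = TRUE),
            class = "bleach_correction")
}

#' Delta-F-over-F normalisation against the all-time average
#'
#' `out(t, p) = (F(t, p) - Fbar(p)) / Fbar(p)` with `Fbar` the per-pixel
#' temporal mean, expressing each pixel's trace as a proportional change
#' over its all-time average intensity. Pixels whose temporal mean is not
#' positive (outside the cell) are set to 0 and counted in the
#' `n_zero_mean_pixels` attribute.
#'
#' @param stack A `TimeLapseStack` (raw reference).
#' @return A `TimeLapseStack` with `reference = "dff"`.
#' @export
compute_dff <- function(stack) {
  stopifnot(inherits(stack, "TimeLapseStack"))
  fbar <- apply(stack$data, c(2, 3), mean)
  bad <- !(fbar > 0)
  safe <- ifelse(bad, 1, fbar)
  data <- stack$data
  for (k in seq_len(n_frames(stack)))
    data[k, , ] <- ifelse(bad, 0, (stack$data[k, , ] - safe) / safe)
  out <- time_lapse_stack(data, stack$frame_interval_s, stack$pixel_size_um,
                          reference = "dff")
  attr(out, "n_zero_mean_pixels") <- sum(bad)
  out
}

#' Detection parameters
#'
#' Houses the acceptance thresholds of the event-detection criterion:
#' peak at least `sd_threshold` baseline standard deviations above the
#' baseline mean (the mean over the `baseline_window_frames` frames
#' preceding the event), supra-threshold for at least
#' `min_persistence_frames` consecutive frames, an event ROI grown as the
#' connected region above `roi_fraction_of_max` of the peak, a 2-D
#' Gaussian shape check at the peak frame, and exclusion of motile
#' puncta whose centroid moves more than `max_displacement_um`.
#'
#' @param sd_threshold Peak threshold in multiples of the baseline SD.
#' @param baseline_window_frames Frames used for the baseline mean/SD.
#' @param min_persistence_frames Minimum supra-threshold run length.
#' @param roi_fraction_of_max ROI growth threshold as a fraction of peak.
#' @param gaussian_fit_min_r2 Minimum R-squared of the 2-D Gaussian fit.
#' @param max_displacement_um Maximum centroid displacement, micrometres.
#' @param min_separation_um Candidates closer than this are merged
#'   (the brighter one is kept).
#' @param gauss_patch_halfwidth_um Half-width of the patch used for the
#'   2-D Gaussian shape check; sized to the punctum so the fit R2 is
#'   not dominated by background pixels.
#' @param candidate_threshold_sd Pre-filter for candidate maxima, in
#'   robust SDs of the dF/F stack; candidates must still pass the full
#'   baseline-SD criterion.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(sd_threshold = 4,
                             baseline_window_frames = 4L,
                             min_persistence_frames = 3L,
                             roi_fraction_of_max = 1 / 3,
                             gaussian_fit_min_r2 = 0.7,
                             max_displacement_um = 0.5,
                             min_separation_um = 1,
                             gauss_patch_halfwidth_um = 0.3,
                             candidate_threshold_sd = 5) {
  stopifnot(sd_threshold > 0, baseline_window_frames >= 1,
            min_persistence_frames >= 1,
            roi_fraction_of_max > 0, roi_fraction_of_max < 1)
  structure(list(sd_threshold = sd_threshold,
                 baseline_window_frames = as.integer(baseline_window_frames),
                 min_persistence_frames = as.integer(min_persistence_frames),
                 roi_fraction_of_max = roi_fraction_of_max,
                 gaussian_fit_min_r2 = gaussian_fit_min_r2,
                 max_displacement_um = max_displacement_um,
                 min_separation_um = min_separation_um,
                 gauss_patch_halfwidth_um = gauss_patch_halfwidth_um,
                 candidate_threshold_sd = candidate_threshold_sd),
            class = "detection_params")
}

# Local maxima of a matrix (8-neighborhood, >= all neighbors, not flat).
local_maxima_matrix <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  nb_max <- matrix(-Inf, nr, nc)
  flat <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    nb_max <- pmax(nb_max, nb)
    flat <- flat & (nb == m)
  }
  which(m >= nb_max & !flat, arr.ind = TRUE)
}

# 8-connected flood fill from (r0, c0) over pixels of `m` >= thr,
# limited to a window of `max_px` around the seed. Returns an index
# matrix (row, col).
flood_fill <- function(m, r0, c0, thr, max_px = 15L, mask = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  rlo <- max(1, r0 - max_px); rhi <- min(nr, r0 + max_px)
  clo <- max(1, c0 - max_px); chi <- min(nc, c0 + max_px)
  sub <- m[rlo:rhi, clo:chi, drop = FALSE]
  ok <- sub >= thr
  if (!is.null(mask)) ok <- ok & mask[rlo:rhi, clo:chi, drop = FALSE]
  lab <- matrix(FALSE, nrow(sub), ncol(sub))
  queue <- matrix(c(r0 - rlo + 1, c0 - clo + 1), ncol = 2)
  lab[queue] <- TRUE
  while (nrow(queue) > 0) {
    nxt <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      cand <- cbind(queue[, 1] + dr, queue[, 2] + dc)
      keep <- cand[, 1] >= 1 & cand[, 1] <= nrow(sub) &
        cand[, 2] >= 1 & cand[, 2] <= ncol(sub)
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) == 0) next
      new <- ok[cand] & !lab[cand]
      cand <- cand[new, , drop = FALSE]
      if (nrow(cand) == 0) next
      lab[cand] <- TRUE
      nxt <- rbind(nxt, cand)
    }
    queue <- if (is.null(nxt)) matrix(numeric(0), ncol = 2)
      else unique(nxt)
  }
  w <- which(lab, arr.ind = TRUE)
  cbind(row = w[, 1] + rlo - 1, col = w[, 2] + clo - 1)
}

# Symmetric 2-D Gaussian fit on a patch; returns list(x0, y0, sigma, r2)
# in patch pixel coordinates, or NULL on failure.
fit_gaussian2d <- function(patch, r0, c0) {
  z <- as.vector(patch)
  if (max(z) <= min(z)) return(NULL)
  rr <- as.vector(row(patch)); cc <- as.vector(col(patch))
  df <- data.frame(z = z, rr = rr, cc = cc)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ a * exp(-((rr - y0)^2 + (cc - x0)^2) / (2 * s^2)) + c0f,
      data = df,
      start = list(a = max(z) - min(z), y0 = r0, x0 = c0,
                   s = 1.3, c0f = min(z)),
      lower = c(a = 0, y0 = r0 - 3, x0 = c0 - 3, s = 0.3, c0f = -Inf),
      upper = c(a = Inf, y0 = r0 + 3, x0 = c0 + 3, s = 10, c0f = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  ssr <- sum(stats::resid(fit)^2)
  sst <- sum((z - mean(z))^2)
  list(x0 = cf[["x0"]], y0 = cf[["y0"]], sigma = cf[["s"]],
       r2 = if (sst > 0) 1 - ssr / sst else 0)
}

#' Detect exocytotic events in a bleach-corrected time-lapse stack
#'
#' Implements the criterion for pHluorin exocytosis: candidate local
#' maxima on the dF/F stack inside the cell mask are grown into a
#' connected ROI above a third (by default) of the peak intensity; the
#' baseline F0 and SD are the mean and SD of the ROI trace over the four
#' frames preceding the event; an event is accepted when its peak reaches
#' `sd_threshold` (default 4) SDs above F0, stays supra-threshold for at
#' least `min_persistence_frames` (default 3) consecutive frames, is
#' Gaussian-shaped at its peak frame, and is non-motile (total centroid
#' displacement below `max_displacement_um`). Candidates within
#' `min_separation_um` are merged keeping the brighter. Events whose
#' supra-threshold run starts within the first baseline window are
#' rejected with reason `"early_onset"`; rejected candidates are retained
#' in the output with `accepted = FALSE` and a `reject_reason`.
#'
#' Detection is invariant to multiplying the stack by a positive
#' constant: every threshold is expressed in SD or dF/F units.
#'
#' @param stack A bleach-corrected `TimeLapseStack` (raw reference).
#' @param params A `detection_params`.
#' @param geometry A `cell_geometry` aligned to the stack.
#' @return A data.frame of class `detected_events`, one row per candidate
#'   event, with centroid (um), onset/peak times (s), `amplitude_sd`,
#'   `baseline_F0`, persistence, Gaussian-fit R2, displacement,
#'   `motile_flag`, `accepted` and `reject_reason`; ROI traces are
#'   attached as the `traces` attribute (one `data.frame(times_s, value)`
#'   per row).
#' @export
detect_events <- function(stack, params = detection_params(), geometry) {
  stopifnot(inherits(stack, "TimeLapseStack"),
            inherits(params, "detection_params"),
            inherits(geometry, "cell_geometry"))
  if (!identical(dim(geometry$cell_mask), dim(stack$data)[2:3]))
    stop("mask and stack shapes do not match")
  px <- stack$pixel_size_um
  dt <- stack$frame_interval_s
  nf <- n_frames(stack)
  dff <- compute_dff(stack)
  mask <- geometry$cell_mask

  # zero dF/F outside the cell mask: pixels with near-zero temporal mean
  # produce meaningless (huge) dF/F values that would otherwise shadow
  # real maxima at the mask edge
  flat_dff <- matrix(dff$data, nrow = nf)  # frames x pixels, pixel-major cols
  flat_dff[, which(!mask)] <- 0
  dff$data <- array(flat_dff, dim = dim(dff$data))
  sigma_hat <- stats::mad(flat_dff[, which(mask)])
  pre_thr <- max(params$candidate_threshold_sd * sigma_hat, 1e-9)

  cands <- NULL
  for (k in seq_len(nf)) {
    fr <- dff$data[k, , ]
    mx <- local_maxima_matrix(fr)
    if (nrow(mx) == 0) next
    keep <- mask[mx] & fr[mx] > pre_thr
    mx <- mx[keep, , drop = FALSE]
    if (nrow(mx) == 0) next
    cands <- rbind(cands, cbind(frame = k, mx, val = fr[mx]))
  }
  if (is.null(cands) || nrow(cands) == 0)
    return(empty_detected_events())

  cands <- as.data.frame(cands)
  ord <- order(-cands$val)
  assigned <- rep(FALSE, nrow(cands))
  sep_px <- params$min_separation_um / px
  gap_frames <- 3L
  clusters <- list()
  for (i in ord) {
    if (assigned[i]) next
    d <- sqrt((cands$row - cands$row[i])^2 + (cands$col - cands$col[i])^2)
    near <- which(!assigned & d <= sep_px)
    # keep the temporally contiguous run (allowing small gaps) around the seed
    fr <- sort(unique(cands$frame[near]))
    runs <- split(fr, cumsum(c(1, diff(fr) > gap_frames)))
    run <- runs[[which(vapply(runs, function(r) cands$frame[i] %in% r,
                              logical(1)))[1]]]
    mem <- near[cands$frame[near] %in% run]
    assigned[mem] <- TRUE
    clusters[[length(clusters) + 1]] <- cands[mem, , drop = FALSE]
  }

  bw <- params$baseline_window_frames
  rows_out <- list()
  traces <- list()
  for (cl in clusters) {
    pk <- cl[which.max(cl$val), ]
    pf <- pk$frame; pr <- pk$row; pc <- pk$col
    roi <- flood_fill(dff$data[pf, , ], pr, pc,
                      thr = params$roi_fraction_of_max * pk$val,
                      max_px = as.integer(ceiling(1.5 / px)), mask = mask)
    tr <- vapply(seq_len(nf), function(k) mean(stack$data[k, , ][roi]),
                 numeric(1))
    # provisional onset: walk back from the peak over clearly elevated frames
    med <- stats::median(tr)
    rob_sd <- max(stats::mad(tr), 1e-12)
    onset0 <- pf
    while (onset0 > 1 && tr[onset0 - 1] >= med + 2 * rob_sd)
      onset0 <- onset0 - 1

    rec <- list(centroid_x_um = (pc - 1) * px, centroid_y_um = (pr - 1) * px,
                t_onset_s = (onset0 - 1) * dt, t_peak_s = (pf - 1) * dt,
                amplitude_sd = NA_real_, baseline_F0 = NA_real_,
                persistence_frames = NA_integer_, fit_r2 = NA_real_,
                displacement_um = NA_real_, motile_flag = FALSE,
                compartment = "unassigned",
                accepted = FALSE, reject_reason = "")

    if (onset0 <= bw) {
      rec$reject_reason <- "early_onset"
      rows_out[[length(rows_out) + 1]] <- rec
      traces[[length(traces) + 1]] <- data.frame(times_s = frame_times(stack),
                                                 value = tr)
      next
    }
    f0 <- mean(tr[(onset0 - bw):(onset0 - 1)])
    bsd <- stats::sd(tr[(onset0 - bw):(onset0 - 1)])
    bsd <- max(bsd, 1e-9 * max(abs(f0), 1))
    thr <- f0 + params$sd_threshold * bsd
    supra <- tr >= thr
    if (!supra[pf]) {
      rec$baseline_F0 <- f0
      rec$amplitude_sd <- (tr[pf] - f0) / bsd
      rec$reject_reason <- "below_sd_threshold"
      rows_out[[length(rows_out) + 1]] <- rec
      traces[[length(traces) + 1]] <- data.frame(times_s = frame_times(stack),
                                                 value = tr)
      next
    }
    run_start <- pf; while (run_start > 1 && supra[run_start - 1])
      run_start <- run_start - 1
    run_end <- pf; while (run_end < nf && supra[run_end + 1])
      run_end <- run_end + 1
    rec$t_onset_s <- (run_start - 1) * dt
    rec$baseline_F0 <- f0
    rec$amplitude_sd <- (tr[pf] - f0) / bsd
    rec$persistence_frames <- run_end - run_start + 1L

    if (run_start <= bw || rec$persistence_frames < params$min_persistence_frames) {
      rec$reject_reason <- if (run_start <= bw) "early_onset"
        else "short_persistence"
      rows_out[[length(rows_out) + 1]] <- rec
      traces[[length(traces) + 1]] <- data.frame(times_s = frame_times(stack),
                                                 value = tr)
      next
    }

    # Gaussian shape at the peak frame, on the baseline-subtracted raw
    # patch so static cell structure (mask edges, processes) cancels
    half <- as.integer(ceiling(params$gauss_patch_halfwidth_um / px))
    rlo <- max(1, pr - half); rhi <- min(nrow(mask), pr + half)
    clo <- max(1, pc - half); chi <- min(ncol(mask), pc + half)
    base_patch <- apply(stack$data[(onset0 - bw):(onset0 - 1),
                                   rlo:rhi, clo:chi, drop = FALSE],
                        c(2, 3), mean)
    patch <- stack$data[pf, rlo:rhi, clo:chi] - base_patch
    g <- fit_gaussian2d(patch, pr - rlo + 1, pc - clo + 1)
    rec$fit_r2 <- if (is.null(g)) 0 else g$r2
    if (!is.null(g)) {
      rec$centroid_x_um <- (clo - 1 + g$x0 - 1) * px
      rec$centroid_y_um <- (rlo - 1 + g$y0 - 1) * px
    }

    # motion: intensity-weighted centroid over the supra-threshold run,
    # on baseline-subtracted raw frames over a window wide enough to see
    # displacements beyond the acceptance limit
    half_m <- as.integer(ceiling((params$max_displacement_um + 0.5) / px))
    rloM <- max(1, pr - half_m); rhiM <- min(nrow(mask), pr + half_m)
    cloM <- max(1, pc - half_m); chiM <- min(ncol(mask), pc + half_m)
    base_m <- apply(stack$data[(onset0 - bw):(onset0 - 1),
                               rloM:rhiM, cloM:chiM, drop = FALSE],
                    c(2, 3), mean)
    cent <- matrix(NA_real_, run_end - run_start + 1, 2)
    for (j in seq_len(nrow(cent))) {
      fr_k <- stack$data[run_start + j - 1, rloM:rhiM, cloM:chiM] - base_m
      w <- pmax(fr_k - params$roi_fraction_of_max * max(fr_k), 0)
      if (sum(w) <= 0) next
      cent[j, 1] <- sum(col(fr_k) * w) / sum(w)
      cent[j, 2] <- sum(row(fr_k) * w) / sum(w)
    }
    cent <- cent[stats::complete.cases(cent), , drop = FALSE]
    disp <- if (nrow(cent) > 1)
      max(sqrt((cent[, 1] - cent[1, 1])^2 + (cent[, 2] - cent[1, 2])^2)) * px
      else 0
    rec$displacement_um <- disp
    rec$motile_flag <- disp > params$max_displacement_um

    if (rec$fit_r2 < params$gaussian_fit_min_r2) {
      rec$reject_reason <- "not_gaussian"
    } else if (rec$motile_flag) {
      rec$reject_reason <- "motile"
    } else {
      rec$accepted <- TRUE
    }
    rows_out[[length(rows_out) + 1]] <- rec
    traces[[length(traces) + 1]] <- data.frame(times_s = frame_times(stack),
                                               value = tr)
  }

  out <- do.call(rbind, lapply(rows_out, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out$event_id <- seq_len(nrow(out))
  out <- out[, c("event_id", setdiff(names(out), "event_id"))]

  # final duplicate merge among accepted events
  acc <- which(out$accepted)
  if (length(acc) > 1) {
    ordA <- acc[order(-out$amplitude_sd[acc])]
    for (i in seq_along(ordA)) {
      a <- ordA[i]
      if (!out$accepted[a]) next
      for (b in ordA[-seq_len(i)]) {
        if (!out$accepted[b]) next
        d <- sqrt((out$centroid_x_um[a] - out$centroid_x_um[b])^2 +
                    (out$centroid_y_um[a] - out$centroid_y_um[b])^2)
        overlap <- abs(out$t_peak_s[a] - out$t_peak_s[b]) <= gap_frames * dt
        if (d <= params$min_separation_um && overlap) {
          out$accepted[b] <- FALSE
          out$reject_reason[b] <- "duplicate"
        }
      }
    }
  }
  class(out) <- c("detected_events", "data.frame")
  attr(out, "traces") <- traces
  attr(out, "pixel_size_um") <- px
  attr(out, "frame_interval_s") <- dt
  out
}

empty_detected_events <- function() {
  out <- data.frame(event_id = integer(), centroid_x_um = numeric(),
                    centroid_y_um = numeric(), t_onset_s = numeric(),
                    t_peak_s = numeric(), amplitude_sd = numeric(),
                    baseline_F0 = numeric(), persistence_frames = integer(),
                    fit_r2 = numeric(), displacement_um = numeric(),
                    motile_flag = logical(), compartment = character(),
                    accepted = logical(), reject_reason = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("detected_events", "data.frame")
  attr(out, "traces") <- list()
  out
}

#' Keep only accepted detections
#'
#' @param events A `detected_events` data.frame.
#' @return The accepted subset (attributes preserved and subset).
#' @export
accepted_events <- function(events) {
  keep <- which(events$accepted)
  out <- events[keep, , drop = FALSE]
  attr(out, "traces") <- attr(events, "traces")[keep]
  attr(out, "pixel_size_um") <- attr(events, "pixel_size_um")
  attr(out, "frame_interval_s") <- attr(events, "frame_interval_s")
  class(out) <- class(events)
  out
}

#' Assign each event to soma or processes/sheet
#'
#' An event whose centroid pixel falls inside the soma mask is designated
#' `soma`; inside the cell mask but outside the soma, `processes_sheet`;
#' outside the cell mask, `unassigned` (with a warning).
#'
#' @param events A `detected_events` data.frame.
#' @param geometry A `cell_geometry`.
#' @param pixel_size_um Pixel size used to map centroids to mask pixels;
#'   defaults to the value recorded by `detect_events()`.
#' @return `events` with the `compartment` column set.
#' @export
assign_compartment <- function(events, geometry,
                               pixel_size_um = attr(events, "pixel_size_um")) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (nrow(events) == 0) return(events)
  px <- pixel_size_um
  r <- pmin(pmax(round(events$centroid_y_um / px) + 1, 1),
            nrow(geometry$cell_mask))
  c_ <- pmin(pmax(round(events$centroid_x_um / px) + 1, 1),
             ncol(geometry$cell_mask))
  ij <- cbind(r, c_)
  comp <- ifelse(geometry$soma_mask[ij], "soma",
                 ifelse(geometry$cell_mask[ij], "processes_sheet",
                        "unassigned"))
  if (any(comp == "unassigned"))
    warning(sum(comp == "unassigned"),
            " event(s) fell outside the cell mask; left unassigned")
  events$compartment <- comp
  events
}

#' Exocytotic event frequency per cell per minute
#'
#' @param events A `detected_events` data.frame (accepted events are
#'   counted; pass the output of [accepted_events()] or a full table).
#' @param duration_s Movie duration in seconds (> 0).
#' @param by_compartment If `TRUE`, also return per-compartment rates.
#' @return A single rate (events/min), or a named list with `overall`
#'   and per-compartment rates.
#' @export
event_frequency <- function(events, duration_s, by_compartment = FALSE) {
  assert_scalar_pos(duration_s, "duration_s")
  acc <- if ("accepted" %in% names(events)) events[events$accepted, ] else events
  per_min <- nrow(acc) / (duration_s / 60)
  if (!by_compartment) return(per_min)
  comps <- c("soma", "processes_sheet")
  by <- vapply(comps, function(cp)
    sum(acc$compartment == cp) / (duration_s / 60), numeric(1))
  c(list(overall = per_min), as.list(by))
}
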