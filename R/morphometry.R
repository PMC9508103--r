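#' Genotype-level inputs for the myelin-coverage model
#'
#' @param n_oligodendrocytes Total oligodendrocyte count `N`.
#' @param mean_sheath_length_um Mean sheath (internode) length `L`, um.
#' @param mean_sheaths_per_cell Mean sheaths per oligodendrocyte `I`.
#' @param label Genotype label.
#' @return A list of class `coverage_inputs`.
#' @export
coverage_inputs <- function(n_oligodendrocytes, mean_sheath_length_um,
                            mean_sheaths_per_cell, label = "") {
  assert_scalar_pos(n_oligodendrocytes, "n_oligodendrocytes")
  assert_scalar_pos(mean_sheath_length_um, "mean_sheath_length_um")
  assert_scalar_pos(mean_sheaths_per_cell, "mean_sheaths_per_cell")
  structure(list(n_oligodendrocytes = n_oligodendrocytes,
                 mean_sheath_length_um = mean_sheath_length_um,
                 mean_sheaths_per_cell = mean_sheaths_per_cell,
                 label = label),
            class = "coverage_inputs")
}

#' Approximated myelin coverage: N x L x I
#'
#' Total myelin coverage in a region of white matter is approximated by
#' the product of the number of oligodendrocytes (N), the mean sheath
#' length (L) and the mean number of sheaths per oligodendrocyte (I),
#' assuming a fixed axon population.
#'
#' @param inputs A `coverage_inputs`.
#' @return The product `N * L * I` (um-scaled coverage units).
#' @export
myelin_coverage <- function(inputs) {
  stopifnot(inherits(inputs, "coverage_inputs"))
  inputs$n_oligodendrocytes * inputs$mean_sheath_length_um *
    inputs$mean_sheaths_per_cell
}

#' Relative myelin coverage between two genotypes
#'
#' The ratio of the N x L x I products; invariant under any common
#' rescaling of both genotypes (including a change of length units).
#'
#' @param test,reference `coverage_inputs` for the two genotypes.
#' @return The ratio `coverage(test) / coverage(reference)`.
#' @export
relative_coverage <- function(test, reference) {
  ref <- myelin_coverage(reference)
  if (ref == 0) stop("reference coverage is zero")
  myelin_coverage(test) / ref
}

#' Relative myelination from cross-sectional EM counts
#'
#' Ratio of the number of myelinated axons (ensheathed plus
#' wrapping/wrapped) per unit area between two genotypes.
#'
#' @param test_count,reference_count Myelinated-axon counts per area.
#' @return `test_count / reference_count`.
#' @export
relative_myelination_em <- function(test_count, reference_count) {
  if (test_count < 0 || reference_count < 0) stop("counts must be >= 0")
  if (reference_count == 0) stop("reference count is zero")
  test_count / reference_count
}

#' Parameters of the vesicle membrane-area budget
#'
#' Defaults follow the regime measured in pre-myelinating oligodendrocyte
#' cultures: 23 exocytotic events/min, 80% full-vesicle fusion, a 48 h
#' window of rapid expansion, spherical vesicles of 100-200 nm diameter,
#' and 6000 um^2 of membrane added per cell over those 48 h as the
#' reference.
#'
#' @param events_per_min Exocytotic event rate (per min).
#' @param full_fusion_fraction Proportion of events that are full fusion.
#' @param duration_h Budget window, hours.
#' @param vesicle_diameter_nm_min,vesicle_diameter_nm_max Vesicle
#'   diameter range, nm.
#' @param reference_added_area_um2 Measured membrane area added over the
#'   window, um^2.
#' @return A list of class `budget_params`.
#' @export
budget_params <- function(events_per_min = 23,
                          full_fusion_fraction = 0.8,
                          duration_h = 48,
                          vesicle_diameter_nm_min = 100,
                          vesicle_diameter_nm_max = 200,
                          reference_added_area_um2 = 6000) {
  stopifnot(events_per_min >= 0, duration_h >= 0,
            full_fusion_fraction >= 0, full_fusion_fraction <= 1,
            vesicle_diameter_nm_min > 0,
            vesicle_diameter_nm_min <= vesicle_diameter_nm_max,
            reference_added_area_um2 > 0)
  structure(list(events_per_min = events_per_min,
                 full_fusion_fraction = full_fusion_fraction,
                 duration_h = duration_h,
                 vesicle_diameter_nm_min = vesicle_diameter_nm_min,
                 vesicle_diameter_nm_max = vesicle_diameter_nm_max,
                 reference_added_area_um2 = reference_added_area_um2),
            class = "budget_params")
}

#' Spherical-vesicle membrane-area budget
#'
#' Each full-vesicle fusion deposits the surface area of one spherical
#' vesicle, `pi * d^2` (= `4 pi r^2`; the diameter is the configured
#' unit to avoid radius/diameter confusion). The number of full-fusion
#' events over the window is
#' `events_per_min * full_fusion_fraction * duration_h * 60`, and the
#' area bounds are evaluated at the minimum and maximum vesicle
#' diameters. Percentages express the bounds relative to the measured
#' membrane area added over the same window. Outputs are exact
#' (unrounded); `printed` carries a presentation rounding (areas to 3
#' significant figures, percentages truncated to whole percent).
#'
#' The budget is linear in rate, fusion fraction and duration, and
#' quadratic in vesicle diameter.
#'
#' @param params A `budget_params`.
#' @return A list of class `membrane_budget`: `n_full_fusion_events`,
#'   `area_min_um2`, `area_max_um2`, `percent_min`, `percent_max`,
#'   `printed`.
#' @export
membrane_budget <- function(params = budget_params()) {
  stopifnot(inherits(params, "budget_params"))
  n <- params$events_per_min * params$full_fusion_fraction *
    params$duration_h * 60
  area_per <- function(d_nm) pi * (d_nm / 1000)^2   # sphere surface, um^2
  a_min <- n * area_per(params$vesicle_diameter_nm_min)
  a_max <- n * area_per(params$vesicle_diameter_nm_max)
  p_min <- 100 * a_min / params$reference_added_area_um2
  p_max <- 100 * a_max / params$reference_added_area_um2
  structure(list(n_full_fusion_events = n,
                 area_min_um2 = a_min, area_max_um2 = a_max,
                 percent_min = p_min, percent_max = p_max,
                 printed = list(area_min_um2 = signif(a_min, 3),
                                area_max_um2 = signif(a_max, 3),
                                percent_min = floor(p_min),
                                percent_max = floor(p_max))),
            class = "membrane_budget")
}

#' @export
print.membrane_budget <- function(x, ...) {
  cat(sprintf("Membrane budget: %.0f full-fusion events\n",
              x$n_full_fusion_events))
  cat(sprintf("  area added: %.0f-%.0f um^2 (%.1f-%.1f%% of reference)\n",
              x$area_min_um2, x$area_max_um2, x$percent_min, x$percent_max))
  invisible(x)
}

#' Count local intensity maxima in a line-scan profile
#'
#' The profile is optionally Gaussian-smoothed, then interior local
#' maxima are counted; a plateau of equal values flanked by lower
#' neighbours counts once, at its center. A maximum qualifies when its
#' topographic prominence is at least `min_prominence_fraction` of the
#' profile range (max minus baseline, the baseline being the profile
#' minimum). A flat profile has no maxima.
#'
#' @param profile Numeric intensity values (>= 5 samples).
#' @param smoothing_sigma_points Gaussian smoothing sigma in samples
#'   (0 = none).
#' @param min_prominence_fraction Prominence threshold as a fraction of
#'   the profile range.
#' @param reference_range Intensity range used to scale the prominence
#'   threshold; defaults to this profile's own range. Supply a common
#'   value when comparing channels on a shared intensity scale, so that
#'   a channel containing only noise does not have its threshold shrunk
#'   to the noise floor.
#' @return Integer count of qualifying maxima.
#' @export
count_local_maxima <- function(profile, smoothing_sigma_points = 0,
                               min_prominence_fraction = 0.2,
                               reference_range = NULL) {
  if (length(profile) < 5) stop("profile needs at least 5 samples")
  x <- gaussian_smooth(profile, smoothing_sigma_points)
  rng <- reference_range %||% (max(x) - min(x))
  if (rng == 0 || max(x) == min(x)) return(0L)
  peaks <- plateau_maxima(x)
  if (length(peaks) == 0) return(0L)
  prom <- vapply(peaks, function(i) peak_prominence(x, i), numeric(1))
  sum(prom >= min_prominence_fraction * rng)
}

# Gaussian smoothing with edge replication.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

# Indices of interior local maxima; plateaus counted once at their center.
plateau_maxima <- function(x) {
  n <- length(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- integer(0)
  for (j in seq_along(r$values)) {
    if (starts[j] == 1 || ends[j] == n) next  # interior only
    if (x[starts[j] - 1] < r$values[j] && x[ends[j] + 1] < r$values[j])
      out <- c(out, starts[j] + (r$lengths[j] - 1) %/% 2)
  }
  out
}

# Topographic prominence of the peak at index i: on each side, walk to
# the first point higher than the peak (or the boundary) and record the
# minimum en route; prominence = peak - max(left base, right base).
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (i == 1) h else {
    j <- i - 1; lo <- x[j]
    while (j >= 1 && x[j] <= h) { lo <- min(lo, x[j]); j <- j - 1 }
    lo
  }
  right <- if (i == length(x)) h else {
    j <- i + 1; lo <- x[j]
    while (j <= length(x) && x[j] <= h) { lo <- min(lo, x[j]); j <- j + 1 }
    lo
  }
  h - max(left, right)
}

# Peaks with their prominences, ordered by decreasing prominence.
ranked_peaks <- function(x, smoothing_sigma_points, min_prominence_fraction) {
  xs <- gaussian_smooth(x, smoothing_sigma_points)
  rng <- max(xs) - min(xs)
  if (rng == 0) return(data.frame(index = integer(), prominence = numeric()))
  idx <- plateau_maxima(xs)
  prom <- vapply(idx, function(i) peak_prominence(xs, i), numeric(1))
  keep <- prom >= min_prominence_fraction * rng
  out <- data.frame(index = idx[keep], prominence = prom[keep])
  out[order(-out$prominence), , drop = FALSE]
}

#' Classify a node of Ranvier from a dual-channel line scan
#'
#' Counts local maxima in the Caspr and AnkG channels and applies the
#' rule table: two Caspr maxima and one AnkG maximum is a mature node;
#' one of each is a heminode; a maximum in exactly one channel is a
#' cluster; anything else is `none` (flagged for review).
#'
#' @param profile A `node_profile` data.frame (`position_um`, `caspr`,
#'   `ankg`) or any data.frame with those columns.
#' @param smoothing_sigma_points,min_prominence_fraction Passed to
#'   [count_local_maxima()].
#' @return A list of class `node_class`: `value`, `n_caspr_maxima`,
#'   `n_ankg_maxima`.
#' @export
classify_node <- function(profile, smoothing_sigma_points = 2,
                          min_prominence_fraction = 0.2) {
  stopifnot(all(c("caspr", "ankg") %in% names(profile)))
  # both channels share one acquisition scale: threshold prominences
  # against the joint range so an empty channel reports no maxima
  ref <- max(profile$caspr, profile$ankg) - min(profile$caspr, profile$ankg)
  nc <- count_local_maxima(profile$caspr, smoothing_sigma_points,
                           min_prominence_fraction, reference_range = ref)
  na_ <- count_local_maxima(profile$ankg, smoothing_sigma_points,
                            min_prominence_fraction, reference_range = ref)
  value <- if (nc == 2 && na_ == 1) "mature"
    else if (nc == 1 && na_ == 1) "heminode"
    else if (xor(nc >= 1, na_ >= 1)) "cluster"
    else "none"
  structure(list(value = value, n_caspr_maxima = nc, n_ankg_maxima = na_),
            class = "node_class")
}

#' Sheath diameter from a perpendicular line scan
#'
#' A line scan crossing a myelinated fiber perpendicular to its axis
#' shows two parallel tracks of membrane signal; the distance between the
#' two most prominent local maxima measures the sheath diameter. With
#' fewer than two qualifying maxima the diameter is undefined; with more
#' than two, the two most prominent are used and the measurement is
#' flagged ambiguous (robust to shoulder noise).
#'
#' @param positions_um Sample positions, micrometres.
#' @param intensity Intensity values (same length).
#' @param smoothing_sigma_points,min_prominence_fraction Peak detection
#'   settings.
#' @return A list: `diameter_um` (NA when undefined), `n_maxima`,
#'   `ambiguous`, `reason`.
#' @export
sheath_diameter <- function(positions_um, intensity,
                            smoothing_sigma_points = 2,
                            min_prominence_fraction = 0.2) {
  stopifnot(length(positions_um) == length(intensity))
  pk <- ranked_peaks(intensity, smoothing_sigma_points,
                     min_prominence_fraction)
  if (nrow(pk) < 2)
    return(list(diameter_um = NA_real_, n_maxima = nrow(pk),
                ambiguous = FALSE, reason = "fewer_than_two_maxima"))
  top2 <- pk$index[1:2]
  list(diameter_um = abs(positions_um[top2[1]] - positions_um[top2[2]]),
       n_maxima = nrow(pk), ambiguous = nrow(pk) > 2, reason = "")
}
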