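#' Time-lapse fluorescence stack
#'
#' Container for a single-channel fluorescence movie: a 3-D array of
#' intensities (frames x rows x cols, arbitrary units) together with the
#' physical calibration needed to interpret it (frame interval in seconds,
#' pixel size in micrometres). Frame `k` is taken at time
#' `(k - 1) * frame_interval_s`; physical coordinates are micrometres from
#' the top-left pixel center, x along columns and y along rows.
#'
#' @param data Numeric 3-D array, frames x rows x cols, finite values.
#' @param frame_interval_s Frame interval in seconds (> 0).
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @param reference `"raw"` for camera-scale intensities, `"dff"` for
#'   a delta-F-over-F normalised stack.
#' @return An object of class `TimeLapseStack`.
#' @export
time_lapse_stack <- function(data, frame_interval_s, pixel_size_um,
                             reference = c("raw", "dff")) {
  reference <- match.arg(reference)
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a 3-D array (frames x rows x cols)")
  if (dim(data)[1] < 8)
    stop("a time-lapse stack needs at least 8 frames")
  if (!all(is.finite(data)))
    stop("stack contains non-finite values")
  assert_scalar_pos(frame_interval_s, "frame_interval_s")
  assert_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(data = data,
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um,
                 reference = reference),
            class = "TimeLapseStack")
}

#' @export
print.TimeLapseStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "TimeLapseStack: %d frames of %d x %d px (%.3g s/frame, %.3g um/px, %s)\n",
    d[1], d[2], d[3], x$frame_interval_s, x$pixel_size_um, x$reference))
  invisible(x)
}

#' @rdname time_lapse_stack
#' @param x A `TimeLapseStack`.
#' @export
n_frames <- function(x) dim(x$data)[1]

#' @rdname time_lapse_stack
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1) * x$frame_interval_s

#' Read / write a time-lapse stack as multi-page TIFF with a JSON sidecar
#'
#' The TIFF holds one 16-bit page per frame; because TIFF pages are stored
#' as values in `[0, 1]`, the intensity scale (arbitrary units per unit
#' value) is recorded in a JSON sidecar next to the image along with the
#' physical calibration, so that `read_stack_tiff()` round-trips the stack
#' up to 16-bit quantisation.
#'
#' @param stack A `TimeLapseStack`.
#' @param path Path of the TIFF file to write/read.
#' @param sidecar_path Path of the JSON sidecar; defaults to `path` with a
#'   `.json` extension appended.
#' @return `write_stack_tiff()` returns `path` invisibly;
#'   `read_stack_tiff()` returns a `TimeLapseStack`.
#' @export
write_stack_tiff <- function(stack, path, sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(stack, "TimeLapseStack"))
  lo <- min(stack$data)
  hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(n_frames(stack)), function(k)
    (stack$data[k, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(frame_interval_s = stack$frame_interval_s,
         pixel_size_um = stack$pixel_size_um,
         intensity_offset = lo,
         intensity_scale = scale,
         reference = stack$reference),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, sidecar_path = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  data <- array(0, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages))
    data[k, , ] <- pages[[k]] * meta$intensity_scale + meta$intensity_offset
  time_lapse_stack(data, meta$frame_interval_s, meta$pixel_size_um,
                   reference = meta$reference %||% "raw")
}
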