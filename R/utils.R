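#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a top-level seed
#'
#' One top-level seed spawns independent, label-keyed substreams so that
#' each simulation stage (event sampling, rendering, noise, layouts) is
#' reproducible on its own. The derived seed is always a valid 32-bit
#' integer.
#'
#' @param seed Integer top-level seed.
#' @param label Character label naming the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Physical x/y coordinates (um) of pixel centers; 0-based physical origin
# at the top-left pixel center, x along columns, y along rows.
pixel_x_um <- function(cols, pixel_size_um) (seq_len(cols) - 1) * pixel_size_um
pixel_y_um <- function(rows, pixel_size_um) (seq_len(rows) - 1) * pixel_size_um

assert_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok && !(is.numeric(x) && length(x) == 1 && is.infinite(x) && x > 0))
    stop(sprintf("`%s` must be a %s finite number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  invisible(x)
}
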