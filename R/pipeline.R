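#' Write an events table to CSV
#'
#' Comma-separated, UTF-8, header row, '.' decimal; floats are
#' serialized with 17 significant digits so that write -> read -> write
#' round-trips byte-identically.
#'
#' @param events A data.frame of events.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  df <- as.data.frame(events)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v)
        if (is.na(v)) "" else formatC(v, digits = 17, format = "g"),
        character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

# FNV-1a 32-bit hash of a character string, as 8 hex digits.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    # xor affects only the low byte (b < 256); stay in double precision
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit multiply by 16777619, piecewise
    lo <- h %% 65536; hi <- h %/% 65536
    h <- ((lo * 16777619) %% 4294967296 +
            ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

pipeline_default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "detect", "classify", "spatial", "budget"),
    simulate = list(n_frames = 120L, image_shape = c(96L, 96L),
                    frame_interval_s = 0.25, pixel_size_um = 0.1,
                    background_level = 100, noise_sd = 2,
                    bleach_tau_s = Inf, rate_per_min = 23,
                    full_fraction = 0.8),
    detect = list(),
    classify = list(use_population_fit = FALSE),
    spatial = list(n_sheaths = 25L, length_um = 18, enrichment = 1,
                   n_events_per_sheath = 8L),
    budget = list())
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order -- simulate (seeded synthetic
#' stack with ground truth), detect (bleach correction + event
#' detection + compartment assignment), classify (border-decay-ratio
#' fusion modes), spatial (sheath layout + paranodal summary) and budget
#' (membrane-area budget) -- writing each stage's artifacts under
#' `out_dir` and a run manifest (config hash, package version, per-file
#' MD5 checksums, timestamp) last. Unknown configuration keys are
#' rejected. A stage failure halts the run with the failing stage named;
#' files written before the failure are left with a `.partial` suffix.
#'
#' @param config A configuration list (see
#'   `oligoexo:::pipeline_default_config()` for the shape) or the path
#'   to a JSON file holding one. Omitted entries take defaults.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- pipeline_default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  written <- character(0)
  pending <- character(0)
  partial <- function(path) { pending <<- c(pending, path); paste0(path, ".partial") }
  commit <- function() {
    for (p in pending) if (file.exists(paste0(p, ".partial")))
      file.rename(paste0(p, ".partial"), p)
    written <<- c(written, pending)
    pending <<- character(0)
  }
  run_stage <- function(name, fun) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    tryCatch({ fun(); commit() },
             error = function(e)
               stop(sprintf("pipeline stage '%s' failed: %s", name,
                            conditionMessage(e)), call. = FALSE))
  }

  env <- new.env()
  run_stage("simulate", function() {
    sc <- cfg$simulate
    params <- acquisition_params(
      frame_interval_s = sc$frame_interval_s, n_frames = sc$n_frames,
      pixel_size_um = sc$pixel_size_um, image_shape = sc$image_shape,
      background_level = sc$background_level, noise_sd = sc$noise_sd,
      bleach_tau_s = sc$bleach_tau_s)
    geometry <- make_oligo_geometry(sc$image_shape, sc$pixel_size_um)
    duration <- sc$frame_interval_s * sc$n_frames
    events <- sample_events(sc$rate_per_min, sc$full_fraction, duration,
                            geometry, seed = seed,
                            pixel_size_um = sc$pixel_size_um)
    sim <- render_stack(params, geometry, events, seed = seed)
    env$sim <- sim; env$geometry <- geometry; env$params <- params
    write_stack_tiff(sim$stack, partial(file.path(out_dir, "stack.tif")),
                     sidecar_path = partial(file.path(out_dir, "stack.tif.json")))
    write_events_csv(sim$truth, partial(file.path(out_dir, "truth.csv")))
  })

  run_stage("detect", function() {
    bc <- correct_bleaching(env$sim$stack)
    env$corrected <- bc$stack
    ev <- detect_events(bc$stack, detection_params(), env$geometry)
    ev <- assign_compartment(ev, env$geometry)
    env$events <- ev
    write_events_csv(ev, partial(file.path(out_dir, "events.csv")))
  })

  run_stage("classify", function() {
    cc <- cfg$classify
    ev <- classify_events(env$corrected, env$events,
                          use_population_fit = isTRUE(cc$use_population_fit))
    write_events_csv(ev, partial(file.path(out_dir, "events_classified.csv")))
  })

  run_stage("spatial", function() {
    sp <- cfg$spatial
    sheaths <- make_sheath_layout(rep(sp$length_um, sp$n_sheaths),
                                  enrichment = sp$enrichment,
                                  n_events_per_sheath = sp$n_events_per_sheath,
                                  seed = seed)
    write_sheaths_csv(sheaths, partial(file.path(out_dir, "sheaths.csv")))
    sm <- summarize_spatial(sheaths)
    jsonlite::write_json(unclass(sm),
                         partial(file.path(out_dir, "summary.json")),
                         auto_unbox = TRUE, digits = NA)
  })

  run_stage("budget", function() {
    b <- membrane_budget(do.call(budget_params, cfg$budget))
    jsonlite::write_json(unclass(b), partial(file.path(out_dir, "budget.json")),
                         auto_unbox = TRUE, digits = NA)
  })

  manifest <- list(
    config_hash = fnv1a32(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                        digits = NA))),
    package_version = as.character(utils::packageVersion("oligoexo")),
    seed = seed,
    checksums = {
      ck <- tools::md5sum(sort(written[file.exists(written)]))
      names(ck) <- basename(names(ck))
      as.list(ck)
    },
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
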