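# One-command pipeline: crop -> tube probability -> centerline -> seeded
# segmentation -> metrics, with named parameter presets and a structured log.

#' Load parameter presets
#'
#' Presets are plain-text INI-style files (`[name]` sections, `key = value`
#' lines) shipped in `inst/presets/presets.cfg`. Comma-separated values parse
#' to numeric vectors.
#'
#' @param path Preset file; defaults to the file shipped with the package.
#' @return Named list of presets (each a named list of parameters).
#' @export
load_presets <- function(path = system.file("presets", "presets.cfg",
                                            package = "airtree")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  presets <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      cur <- gsub("^\\[|\\]$", "", ln)
      presets[[cur]] <- list()
    } else if (grepl("=", ln) && !is.null(cur)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      val <- trimws(paste(kv[-1L], collapse = "="))
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1L]]))
      presets[[cur]][[key]] <- if (any(is.na(num))) val else num
    }
  }
  presets
}

#' Fetch one named preset
#'
#' @param name Preset name, e.g. `"lung-airways"`.
#' @param path Optional preset file path.
#' @return Named list of parameters.
#' @export
get_preset <- function(name = "lung-airways", path = NULL) {
  presets <- if (is.null(path)) load_presets() else load_presets(path)
  if (!name %in% names(presets))
    stop("unknown preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  presets[[name]]
}

#' Run the full segmentation pipeline
#'
#' `auto_crop` -> `tube_probability` -> `extract_centerline` ->
#' `segment_from_centerline` -> tree metrics. The mask is mapped back to the
#' uncropped grid; centerline points are world coordinates and need no
#' remapping. Deterministic for a fixed configuration.
#'
#' @param volume A [volume_image()], or a path to a MetaImage header.
#' @param preset Preset name (see [load_presets()]).
#' @param ... Named parameter overrides (any preset key).
#' @param verbose Print stage progress.
#' @return An object of class `airway_pipeline_result`: list with `mask`
#'   ([binary_mask()] on the original grid), `tree` ([centerline_tree()]),
#'   `metrics` (from [tree_metrics_table()]) and `log` (per-stage parameters
#'   and timings).
#' @export
run_pipeline <- function(volume, preset = "lung-airways", ..., verbose = FALSE) {
  if (is.character(volume)) {
    if (!file.exists(volume)) stop("input volume not found: ", volume)
    volume <- read_metaimage(volume)
  }
  stopifnot(inherits(volume, "volume_image"))
  p <- get_preset(preset)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown pipeline parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(over)] <- over

  log <- list()
  stage <- function(name, params, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed (%s): %s", name,
                   paste(sprintf("%s=%s", names(params),
                                 vapply(params, function(v)
                                   paste(format(v), collapse = ","), "")),
                         collapse = ", "),
                   conditionMessage(e)), call. = FALSE))
    log[[name]] <<- list(params = params,
                         seconds = proc.time()[["elapsed"]] - t0)
    if (verbose) message(sprintf("[%s] %.2f s", name, log[[name]]$seconds))
    out
  }

  crop <- stage("auto_crop", list(air_threshold_hu = p$air_threshold_hu),
                auto_crop(volume, air_threshold_hu = p$air_threshold_hu))
  tpm <- stage("tube_probability",
               list(scales_mm = p$scales_mm, contrast_hu = p$contrast_hu),
               tube_probability(crop$volume, radii_mm = p$scales_mm,
                                contrast_hu = p$contrast_hu))
  tree <- stage("extract_centerline",
                list(probability_threshold = p$probability_threshold,
                     hu_air_max = p$hu_air_max, prune_mm = p$prune_mm),
                extract_centerline(tpm, crop$volume,
                                   probability_threshold = p$probability_threshold,
                                   hu_air_max = p$hu_air_max,
                                   prune_mm = if (p$prune_mm > 0) p$prune_mm else NULL))
  mask <- stage("segment_from_centerline",
                list(dilation_radius_mm = p$dilation_radius_mm,
                     hu_ceiling = p$hu_ceiling,
                     gradient_factor = p$gradient_factor),
                segment_from_centerline(crop$volume, tree,
                                        dilation_radius_mm = p$dilation_radius_mm,
                                        hu_ceiling = p$hu_ceiling,
                                        gradient_factor = p$gradient_factor))
  full_mask <- uncrop_mask(mask, crop, original_origin = volume$origin)
  metrics <- tree_metrics_table(tree, full_mask)
  structure(list(mask = full_mask, tree = tree, metrics = metrics,
                 preset = preset, parameters = p, log = log),
            class = "airway_pipeline_result")
}

#' @export
print.airway_pipeline_result <- function(x, ...) {
  cat(sprintf("<airway_pipeline_result> preset '%s'\n", x$preset))
  print(x$tree)
  cat(sprintf("segmented volume: %.1f mm3\n", attr(x$metrics, "volume_mm3")))
  for (nm in names(x$log))
    cat(sprintf("  %-24s %6.2f s\n", nm, x$log[[nm]]$seconds))
  invisible(x)
}
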