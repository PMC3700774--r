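#' Construct a movie stack
#'
#' The in-memory container for a grayscale time-lapse movie: a
#' `height x width x frames` array of non-negative intensities plus the
#' acquisition frame rate and optional pixel calibration. The frame rate is
#' always supplied explicitly (from simulation or a sidecar file), never
#' inferred from image metadata.
#'
#' @param frames Numeric array `H x W x T` (or `H x W` matrix for a single
#'   frame).
#' @param fps Frames per second (> 0).
#' @param bit_depth Quantization depth, 8 or 16.
#' @param pixel_size Optional pixel size in micrometres (metadata only; all
#'   analysis is in pixel units).
#' @param source Provenance string: a file path or `"synthetic"`.
#' @return A list of class `movie_stack` with elements `frames`, `fps`,
#'   `bit_depth`, `pixel_size`, `source`.
#' @export
movie_stack <- function(frames, fps, bit_depth = 16L, pixel_size = NULL,
                        source = "synthetic") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1))
  if (length(dim(frames)) != 3) abort_input("frames must be an H x W x T array")
  if (fps <= 0) abort_input("fps must be > 0")
  if (any(frames < 0)) abort_input("frame intensities must be >= 0")
  structure(list(frames = frames, fps = fps, bit_depth = as.integer(bit_depth),
                 pixel_size = pixel_size, source = source),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %d frame(s) of %dx%d px, %g fps (%.3g s), %d-bit, source: %s\n",
              d[3], d[2], d[1], x$fps, d[3] / x$fps, x$bit_depth, x$source))
  invisible(x)
}

movie_n_frames <- function(movie) dim(movie$frames)[3]
movie_duration <- function(movie) movie_n_frames(movie) / movie$fps

default_sidecar <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a movie as multi-frame TIFF plus JSON sidecar
#'
#' Pixel data go to an uncompressed grayscale multi-page TIFF; acquisition
#' metadata (frame rate, pixel size, bit depth) go to a JSON sidecar, because
#' TIFF frame-interval tags are dialect-ridden and explicit beats inferred.
#'
#' @param movie A [movie_stack()].
#' @param path Output TIFF path.
#' @param sidecar_path Sidecar JSON path; defaults to `path` with a `.json`
#'   extension.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, sidecar_path = default_sidecar(path)) {
  if (!inherits(movie, "movie_stack")) abort_input("movie must be a movie_stack")
  write_tiff_stack(movie$frames, path, movie$bit_depth)
  meta <- list(schema_version = "1.0",
               fps = movie$fps,
               pixel_size_um = movie$pixel_size,
               bit_depth = movie$bit_depth,
               n_frames = movie_n_frames(movie),
               source = movie$source)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a movie from multi-frame TIFF plus JSON sidecar
#'
#' Intensities are preserved bit-exactly. The frame rate must come from the
#' sidecar; a missing sidecar or missing `fps` field is an error, never a
#' default. Single-frame files are accepted but flagged unusable for motion
#' analysis (attribute `usable_for_motion`).
#'
#' @param path TIFF path.
#' @param sidecar_path Sidecar JSON path; defaults to `path` with a `.json`
#'   extension.
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, sidecar_path = default_sidecar(path)) {
  tif <- read_tiff_stack(path)
  if (!file.exists(sidecar_path)) {
    abort_input(sprintf(
      "frame rate unknown: sidecar JSON '%s' not found (fps is required, never inferred)",
      sidecar_path), class = "ciliamotion_error_sidecar")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$fps)) {
    abort_input("sidecar JSON has no 'fps' field; fps is required, never defaulted",
                class = "ciliamotion_error_sidecar")
  }
  mv <- movie_stack(tif$frames, fps = meta$fps, bit_depth = tif$bit_depth,
                    pixel_size = meta$pixel_size_um, source = path)
  attr(mv, "usable_for_motion") <- movie_n_frames(mv) > 1
  if (movie_n_frames(mv) == 1) {
    warn("single-frame movie: unusable for motion analysis",
         class = "ciliamotion_warning_single_frame")
  }
  mv
}

#' Write ground-truth or estimated angle traces as CSV
#'
#' Columns: `frame`, `time_s`, `cilium_id`, `angle_deg`, `quality`.
#'
#' @param traces A single `angle_trace` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "angle_trace")) traces <- list(traces)
  tb <- purrr::map_dfr(seq_along(traces), function(i) {
    tr <- traces[[i]]
    tibble::tibble(frame = tr$frame, time_s = tr$time_s,
                   cilium_id = attr(tr, "cilium_id") %||% i,
                   angle_deg = tr$angle_deg, quality = tr$quality)
  })
  readr::write_csv(tb, path)
  invisible(path)
}

#' Read angle traces from CSV
#'
#' @param path CSV written by [write_traces()].
#' @return A named list of `angle_trace` tibbles, one per `cilium_id`.
#' @export
read_traces <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "time_s", "cilium_id", "angle_deg", "quality")
  if (!all(need %in% names(tb))) {
    abort_input(sprintf("trace CSV must have columns %s",
                        paste(need, collapse = ", ")))
  }
  ids <- sort(unique(tb$cilium_id))
  out <- lapply(ids, function(id) {
    s <- dplyr::arrange(dplyr::filter(tb, .data$cilium_id == id), .data$frame)
    fps <- 1 / median(diff(s$time_s))
    angle_trace_tbl(s$angle_deg, fps, quality = s$quality, cilium_id = id)
  })
  names(out) <- as.character(ids)
  out
}

scenario_field_names <- function() {
  names(formals(cilium_scenario))
}

#' Load a scenario or analysis configuration from JSON
#'
#' A scenario config is merged onto the defaults of the
#' `renal_anesthetized` preset (or the preset named by its optional
#' `preset` key), validated against all scenario invariants, and returned as
#' a [cilium_scenario()]. Unknown keys are rejected. The names of fields
#' filled from defaults are recorded in the `defaults_filled` attribute for
#' provenance. A config with `"type": "analysis"` is returned as a validated
#' analysis-option list instead (see [cmd_analyze()]).
#'
#' @param path JSON config path.
#' @return A `cilium_scenario` or an analysis-config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- cfg$type %||% "scenario"
  cfg$type <- NULL
  cfg$schema_version <- NULL
  if (identical(type, "analysis")) {
    return(validate_analysis_config(cfg))
  }
  preset <- cfg$preset %||% "renal_anesthetized"
  cfg$preset <- NULL
  known <- scenario_field_names()
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort_input(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")),
                class = "ciliamotion_error_config")
  }
  if (!is.null(cfg$base_positions)) {
    cfg$base_positions <- matrix(unlist(cfg$base_positions), ncol = 2,
                                 byrow = !is.matrix(cfg$base_positions))
  }
  sc <- do.call(scenario_preset, c(list(name = preset), cfg))
  attr(sc, "preset") <- preset
  attr(sc, "defaults_filled") <- setdiff(known, names(cfg))
  sc
}

#' Save a scenario configuration as JSON
#'
#' @param scenario A [cilium_scenario()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(scenario, path) {
  x <- unclass(scenario)
  x$base_positions <- unname(apply(scenario$base_positions, 1, as.list,
                                   simplify = FALSE))
  out <- c(list(schema_version = "1.0", type = "scenario"), x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

validate_analysis_config <- function(cfg) {
  defaults <- list(movie = NULL, sidecar = NULL, rois = NULL,
                   hinge_hint = NULL, n_path_bins = 100L, dwell_bins = 10L,
                   sweep_method = "minmax", snr_threshold = 5,
                   out_dir = NULL, seed = 1L)
  unknown <- setdiff(names(cfg), c(names(defaults)))
  if (length(unknown) > 0) {
    abort_input(sprintf("unknown analysis config key(s): %s",
                        paste(unknown, collapse = ", ")),
                class = "ciliamotion_error_config")
  }
  cfg <- modifyList(defaults, cfg)
  if (!is.null(cfg$movie) && !file.exists(cfg$movie)) {
    abort_input(sprintf("movie file not found: %s", cfg$movie))
  }
  if (cfg$n_path_bins < 2) abort_input("n_path_bins must be >= 2")
  if (cfg$dwell_bins < 1) abort_input("dwell_bins must be >= 1")
  if (!cfg$sweep_method %in% c("minmax", "percentile")) {
    abort_input("sweep_method must be 'minmax' or 'percentile'")
  }
  structure(cfg, class = "analysis_config")
}

#' Write a kymograph as CSV (and optionally 32-bit TIFF is out of scope;
#' CSV keeps the deliverable plain-text)
#'
#' Long format with columns `bin`, `angle_deg` (bin centre), `frame`,
#' `intensity`.
#'
#' @param kymo A [extract_kymograph()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kymograph_csv <- function(kymo, path) {
  readr::write_csv(tidy_kymograph(kymo), path)
  invisible(path)
}
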