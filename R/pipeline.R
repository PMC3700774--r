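#' Simulate a scenario and write all artifacts
#'
#' Writes the movie (multi-frame TIFF + JSON sidecar), the ground-truth
#' angle traces (CSV) and a JSON manifest holding the fully resolved
#' scenario, seed and package version, so reruns are reproducible and
#' auditable. Idempotent for a fixed seed; refuses to overwrite existing
#' outputs unless `force = TRUE`.
#'
#' @param scenario A [cilium_scenario()], a preset name, or a JSON config
#'   path.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with `movie_path`, `sidecar_path`,
#'   `truth_path`, `manifest_path`, and the in-memory `simulation`.
#' @export
cmd_simulate <- function(scenario = "renal_anesthetized", out_dir,
                         seed = NULL, force = FALSE) {
  sc <- resolve_scenario(scenario)
  if (!is.null(seed)) {
    sc$seed <- as.integer(seed)
    sc <- validate_scenario(sc)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(movie_path = file.path(out_dir, "movie.tif"),
                sidecar_path = file.path(out_dir, "movie.json"),
                truth_path = file.path(out_dir, "truth_traces.csv"),
                manifest_path = file.path(out_dir, "manifest.json"))
  exists <- file.exists(unlist(paths))
  if (any(exists) && !force) {
    abort_input(sprintf("output exists (%s); use force = TRUE to overwrite",
                        paste(basename(unlist(paths)[exists]), collapse = ", ")))
  }
  sim <- simulate_field(sc)
  write_movie(sim$movie, paths$movie_path, paths$sidecar_path)
  write_traces(sim$traces, paths$truth_path)
  manifest <- list(
    schema_version = "1.0",
    tool = "ciliamotion",
    version = as.character(packageVersion("ciliamotion")),
    seed = sc$seed,
    scenario = jsonlite::fromJSON(jsonlite::toJSON(
      save_config_list(sc), auto_unbox = TRUE, digits = NA)),
    n_frames = movie_n_frames(sim$movie),
    saturated_pixels = attr(sim$movie, "saturated_pixels")
  )
  jsonlite::write_json(manifest, paths$manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(c(paths, list(simulation = sim)))
}

save_config_list <- function(sc) {
  x <- unclass(sc)
  attributes(x) <- list(names = names(x))
  x$base_positions <- unname(apply(sc$base_positions, 1, as.list,
                                   simplify = FALSE))
  x
}

resolve_scenario <- function(scenario) {
  if (inherits(scenario, "cilium_scenario")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1) {
    if (file.exists(scenario)) {
      sc <- load_config(scenario)
      if (!inherits(sc, "cilium_scenario")) {
        abort_input("config file does not describe a scenario")
      }
      return(sc)
    }
    return(scenario_preset(scenario))
  }
  abort_input("scenario must be a cilium_scenario, preset name, or config path")
}

crop_movie <- function(movie, roi) {
  # roi: list/vector xmin, xmax, ymin, ymax in zero-based pixel coords
  r <- as.list(roi)
  f <- movie$frames[(r$ymin:r$ymax) + 1, (r$xmin:r$xmax) + 1, , drop = FALSE]
  movie_stack(f, fps = movie$fps, bit_depth = movie$bit_depth,
              pixel_size = movie$pixel_size, source = movie$source)
}

#' Analyze a movie end to end
#'
#' Runs the full chain — range-of-motion projection, arc-path fit (unless an
#' arc or hinge hint is supplied), kymograph line-scan, tip-angle trace, and
#' all oscillation statistics — for one or more regions of interest, and
#' optionally persists every intermediate. Stage failures are re-raised with
#' the stage name and a remediation hint.
#'
#' @param movie A [movie_stack()], a TIFF path, or an analysis config (JSON
#'   path or [load_config()] result with `type = "analysis"`).
#' @param rois Optional list of ROIs (`list(xmin, xmax, ymin, ymax)`,
#'   zero-based), one cilium each; default: the whole frame as one ROI.
#' @param arc Optional [arc_path()] (single ROI only) bypassing the fit.
#' @param hinge_hint Optional `(x, y)` hinge hint for the fit.
#' @param out_dir Optional directory; when given, the report JSON, trace
#'   CSV and kymograph CSV are written there.
#' @param n_path_bins Kymograph path bins.
#' @param dwell_bins Dwell-fraction bins.
#' @param sweep_method Passed to [sweep_angle()].
#' @param snr_threshold Passed to [dominant_frequency()].
#' @return An [oscillation_report()] with attribute `traces` (the estimated
#'   `angle_trace` per ROI) and `kymographs`.
#' @export
cmd_analyze <- function(movie, rois = NULL, arc = NULL, hinge_hint = NULL,
                        out_dir = NULL, n_path_bins = 100L, dwell_bins = 10L,
                        sweep_method = "minmax", snr_threshold = 5) {
  if (is.character(movie)) {
    if (grepl("\\.json$", movie)) {
      cfg <- load_config(movie)
      if (!inherits(cfg, "analysis_config")) {
        abort_input("JSON config must have \"type\": \"analysis\"")
      }
      return(cmd_analyze(cfg$movie, rois = cfg$rois,
                         hinge_hint = cfg$hinge_hint, out_dir = cfg$out_dir,
                         n_path_bins = cfg$n_path_bins,
                         dwell_bins = cfg$dwell_bins,
                         sweep_method = cfg$sweep_method,
                         snr_threshold = cfg$snr_threshold))
    }
    movie <- read_movie(movie)
  }
  if (!inherits(movie, "movie_stack")) abort_input("movie must be a movie_stack or path")
  if (movie_n_frames(movie) < 4) abort_input("movie too short: fewer than 4 frames")

  stage <- function(name, hint, expr) {
    tryCatch(expr, ciliamotion_error = function(e) {
      abort_stage(sprintf("stage '%s' failed: %s (%s)", name,
                          conditionMessage(e), hint),
                  class = class(e)[1], parent = e)
    })
  }

  if (is.null(rois)) {
    d <- dim(movie$frames)
    rois <- list(list(xmin = 0, xmax = d[2] - 1, ymin = 0, ymax = d[1] - 1))
  }
  traces <- list()
  kymos <- list()
  for (i in seq_along(rois)) {
    sub <- crop_movie(movie, rois[[i]])
    rom <- stage("range_of_motion", "check the movie is non-empty",
                 range_of_motion(sub))
    a <- if (!is.null(arc) && length(rois) == 1) arc else {
      stage("fit_arc_path",
            "supply an arc_path or hinge_hint if auto-fitting fails",
            fit_arc_path(rom, movie = sub, hinge_hint = hinge_hint,
                         n_bins = n_path_bins))
    }
    kym <- stage("extract_kymograph", "check the arc lies inside the ROI",
                 extract_kymograph(sub, a))
    tr <- stage("tip_angle_trace", "increase signal or ROI size",
                tip_angle_trace(kym))
    attr(tr, "cilium_id") <- i
    traces[[i]] <- tr
    kymos[[i]] <- kym
  }
  report <- stage("oscillation_stats", "check trace quality",
                  oscillation_report(traces, dwell_bins = dwell_bins,
                                     sweep_method = sweep_method,
                                     snr_threshold = snr_threshold))
  attr(report, "traces") <- traces
  attr(report, "kymographs") <- kymos
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.json"),
                 extra = list(source = movie$source,
                              fps = movie$fps,
                              n_frames = movie_n_frames(movie)))
    write_traces(traces, file.path(out_dir, "estimated_traces.csv"))
    for (i in seq_along(kymos)) {
      write_kymograph_csv(kymos[[i]],
                          file.path(out_dir, sprintf("kymograph_%02d.csv", i)))
    }
  }
  report
}

#' Compare an analysis against ground truth
#'
#' Per matching cilium id: frequency error (Hz), sweep error (degrees),
#' per-frame angle RMS error (degrees), and the total-variation distance
#' between estimated and true dwell-fraction vectors.
#'
#' @param report An [cmd_analyze()] result (must carry its `traces`
#'   attribute).
#' @param truth A list of ground-truth `angle_trace` tibbles (as from
#'   [simulate_field()] or [read_traces()]).
#' @param dwell_bins Bins for the dwell comparison.
#' @return A tibble with one row per cilium: `cilium_id`, `frequency_error_hz`,
#'   `sweep_error_deg`, `angle_rmse_deg`, `dwell_tv_distance`.
#' @export
cmd_compare <- function(report, truth, dwell_bins = 10L) {
  est_traces <- attr(report, "traces")
  if (is.null(est_traces)) abort_input("report lacks estimated traces")
  if (inherits(truth, "angle_trace")) truth <- list(truth)
  est_ids <- vapply(est_traces, function(t) as.integer(attr(t, "cilium_id") %||% 1L), 1L)
  tru_ids <- vapply(seq_along(truth),
                    function(i) as.integer(attr(truth[[i]], "cilium_id") %||% i), 1L)
  if (!all(est_ids %in% tru_ids)) {
    abort_input(sprintf("cilium id(s) %s missing from ground truth",
                        paste(setdiff(est_ids, tru_ids), collapse = ", ")))
  }
  purrr::map_dfr(seq_along(est_traces), function(i) {
    est <- est_traces[[i]]
    tru <- truth[[match(est_ids[i], tru_ids)]]
    if (nrow(est) != nrow(tru)) {
      abort_input("estimated and true traces differ in length")
    }
    fe_est <- dominant_frequency(est)
    fe_tru <- dominant_frequency(tru)
    dw_est <- dwell_fractions(est, n_bins = dwell_bins)$fraction
    dw_tru <- dwell_fractions(tru, n_bins = dwell_bins)$fraction
    tibble::tibble(
      cilium_id = est_ids[i],
      frequency_error_hz = abs(fe_est$frequency - fe_tru$frequency),
      sweep_error_deg = abs(sweep_angle(est) - sweep_angle(tru)),
      angle_rmse_deg = sqrt(mean((est$angle_deg - tru$angle_deg)^2)),
      dwell_tv_distance = 0.5 * sum(abs(dw_est - dw_tru))
    )
  })
}
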