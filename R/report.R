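#' Full oscillation report for a field of angle traces
#'
#' Runs every per-cilium statistic (dominant frequency, sweep angle, dwell
#' fractions, motion class) and, for fields of two or more cilia, the
#' pairwise phase synchrony.
#'
#' @param traces A single `angle_trace` or a list of them.
#' @param dwell_bins Number of path bins for dwell fractions.
#' @param sweep_method Passed to [sweep_angle()].
#' @param snr_threshold Passed to [dominant_frequency()].
#' @return A list of class `oscillation_report`: `per_cilium` tibble
#'   (`cilium_id`, `frequency_hz`, `resolution_hz`, `snr`, `freq_valid`,
#'   `sweep_deg`, `motion_class`, `dwell` list-column), `synchrony` (or
#'   `NULL` for a single cilium), `schema_version`.
#' @export
oscillation_report <- function(traces, dwell_bins = 10L,
                               sweep_method = "minmax", snr_threshold = 5) {
  if (inherits(traces, "angle_trace")) traces <- list(traces)
  per <- purrr::map_dfr(seq_along(traces), function(i) {
    tr <- traces[[i]]
    fe <- dominant_frequency(tr, snr_threshold = snr_threshold)
    dw <- tryCatch(dwell_fractions(tr, n_bins = dwell_bins),
                   ciliamotion_error = function(e) NULL)
    tibble::tibble(
      cilium_id = attr(tr, "cilium_id") %||% i,
      frequency_hz = fe$frequency,
      resolution_hz = fe$resolution,
      snr = fe$snr,
      freq_valid = fe$valid,
      aliasing_possible = fe$aliasing_possible,
      sweep_deg = sweep_angle(tr, method = sweep_method),
      motion_class = classify_motion(tr, fe),
      dwell = list(dw)
    )
  })
  sync <- if (length(traces) >= 2) {
    tryCatch(synchrony(traces), ciliamotion_error = function(e) NULL)
  } else NULL
  structure(list(per_cilium = per, synchrony = sync,
                 n_cilia = length(traces), schema_version = "1.0"),
            class = "oscillation_report")
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat(sprintf("<oscillation_report> %d cilium/cilia\n", x$n_cilia))
  print(dplyr::select(x$per_cilium, -"dwell"))
  if (!is.null(x$synchrony)) {
    off <- x$synchrony$plv[upper.tri(x$synchrony$plv)]
    cat(sprintf("field synchrony: mean PLV %.3f at consensus %.3f Hz\n",
                mean(off), x$synchrony$consensus_frequency))
  }
  invisible(x)
}

#' Tidy an oscillation report into one row per cilium
#'
#' @param x An [oscillation_report()].
#' @param ... Unused.
#' @return The `per_cilium` tibble without the `dwell` list-column.
#' @method tidy oscillation_report
#' @export
tidy.oscillation_report <- function(x, ...) {
  dplyr::select(x$per_cilium, -"dwell")
}

#' One-row field summary of an oscillation report
#'
#' @param x An [oscillation_report()].
#' @param ... Unused.
#' @return A tibble with `n_cilia`, `n_oscillating`, `consensus_frequency_hz`,
#'   `mean_sweep_deg`, `mean_plv`.
#' @method glance oscillation_report
#' @export
glance.oscillation_report <- function(x, ...) {
  per <- x$per_cilium
  valid_f <- per$frequency_hz[per$freq_valid]
  tibble::tibble(
    n_cilia = x$n_cilia,
    n_oscillating = sum(per$motion_class == "oscillating"),
    consensus_frequency_hz = if (length(valid_f)) median(valid_f) else NA_real_,
    mean_sweep_deg = mean(per$sweep_deg),
    mean_plv = if (!is.null(x$synchrony)) {
      mean(x$synchrony$plv[upper.tri(x$synchrony$plv)])
    } else NA_real_
  )
}

#' @method tidy frequency_estimate
#' @export
tidy.frequency_estimate <- function(x, ...) {
  tibble::tibble(frequency_hz = x$frequency, peak_power = x$peak_power,
                 resolution_hz = x$resolution, snr = x$snr, valid = x$valid,
                 reason = x$reason %||% NA_character_,
                 aliasing_possible = x$aliasing_possible)
}

#' @method tidy synchrony
#' @export
tidy.synchrony <- function(x, ...) {
  m <- nrow(x$plv)
  pairs <- which(upper.tri(x$plv), arr.ind = TRUE)
  tibble::tibble(cilium_a = pairs[, 1], cilium_b = pairs[, 2],
                 plv = x$plv[pairs],
                 phase_diff_deg = x$phase_diff_deg[pairs])
}

#' @method tidy angle_trace
#' @export
tidy.angle_trace <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method tidy kymograph
#' @export
tidy.kymograph <- function(x, ...) tidy_kymograph(x)

report_to_json_list <- function(report) {
  per <- report$per_cilium
  per$dwell <- lapply(per$dwell, function(d) {
    if (is.null(d)) NULL else as.list(d)
  })
  out <- list(schema_version = report$schema_version,
              n_cilia = report$n_cilia,
              per_cilium = per)
  if (!is.null(report$synchrony)) {
    out$synchrony <- list(
      plv = report$synchrony$plv,
      phase_diff_deg = report$synchrony$phase_diff_deg,
      consensus_frequency = report$synchrony$consensus_frequency
    )
  }
  out
}

#' Write an oscillation report as JSON
#'
#' @param report An [oscillation_report()].
#' @param path Output JSON path.
#' @param extra Optional named list (e.g. provenance manifest) merged into
#'   the top level.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, extra = NULL) {
  out <- c(report_to_json_list(report), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
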