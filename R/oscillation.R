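hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

check_uniform_times <- function(trace) {
  dt <- diff(trace$time_s)
  if (length(dt) > 0 && (max(dt) - min(dt)) > 1e-9) {
    abort_input("trace timestamps are not uniformly spaced")
  }
}

#' Dominant oscillation frequency of an angle trace
#'
#' Mean-subtracted, Hann-windowed discrete Fourier transform of the angle
#' series; the spectral peak is sought above `max(0.2 Hz, 2 / duration)` and
#' refined by parabolic interpolation of log power over the peak and its two
#' neighbours, giving sub-bin precision well beyond the raw resolution of
#' `1 / duration` Hz. The estimate is flagged valid only when the peak power
#' exceeds `snr_threshold` times the median non-DC power, the record holds
#' at least two cycles, and the peak is sustained — the four quarters of the
#' record, analysed separately, must peak at the same frequency (within
#' their own resolution). The sustainment check rejects one-off transients
#' such as a single posture reversal, whose boxcar spectrum otherwise
#' masquerades as a high-SNR low-frequency peak. Invalid estimates are
#' returned (with a `reason`), never silently dropped. Peaks within two resolution steps of
#' the Nyquist frequency additionally raise the `aliasing_possible` flag.
#'
#' @param trace An `angle_trace` (uniformly sampled; checked).
#' @param snr_threshold Peak-power / median-power validity threshold.
#' @return A list of class `frequency_estimate`: `frequency` (Hz),
#'   `peak_power`, `resolution` (Hz), `snr`, `valid`, `reason`,
#'   `aliasing_possible`, plus the full `spectrum` tibble (`frequency`,
#'   `power`) for plotting.
#' @export
#' @examples
#' tr <- angle_trace_tbl(90 + 40 * sin(2 * pi * 2 * (0:1039) / 26), fps = 26)
#' dominant_frequency(tr)$frequency
dominant_frequency <- function(trace, snr_threshold = 5) {
  n <- nrow(trace)
  if (n < 4) abort_input("need at least 4 frames for frequency estimation")
  check_uniform_times(trace)
  fps <- trace_fps(trace)
  duration <- n / fps
  res <- 1 / duration
  out <- structure(list(frequency = NA_real_, peak_power = NA_real_,
                        resolution = res, snr = NA_real_, valid = FALSE,
                        reason = NULL, aliasing_possible = FALSE,
                        spectrum = NULL, fps = fps),
                   class = "frequency_estimate")
  x <- trace$angle_deg - mean(trace$angle_deg)
  if (sd(x) < 1e-12) {
    out$reason <- "no spectral peak"
    return(out)
  }
  xw <- x * hann_window(n)
  sp <- fft(xw)
  half <- floor(n / 2)
  power <- Mod(sp[2:(half + 1)])^2  # drop DC
  freqs <- (1:half) * fps / n
  f_lo <- max(0.2, 2 / duration)
  search <- which(freqs > f_lo & freqs <= fps / 2)
  out$spectrum <- tibble::tibble(frequency = freqs, power = power)
  if (length(search) < 3) {
    out$reason <- "record too short for spectral search"
    return(out)
  }
  k <- search[which.max(power[search])]
  pk <- power[k]
  med <- median(power[search])
  out$snr <- if (med > 0) pk / med else Inf
  # parabolic interpolation on log power
  delta <- 0
  if (k > 1 && k < half && power[k - 1] > 0 && power[k + 1] > 0) {
    y0 <- log(power[k - 1]); y1 <- log(pk); y2 <- log(power[k + 1])
    den <- y0 - 2 * y1 + y2
    if (den < 0) delta <- 0.5 * (y0 - y2) / den
    delta <- max(-0.5, min(0.5, delta))
  }
  out$frequency <- (k + delta) * fps / n
  out$peak_power <- pk
  out$aliasing_possible <- out$frequency >= fps / 2 - 2 * res
  if (out$snr < snr_threshold) {
    out$reason <- "no spectral peak"
  } else if (duration < 2 / out$frequency) {
    out$reason <- "too few cycles"
  } else if (!peak_sustained(x, fps)) {
    out$reason <- "peak not sustained"
  } else {
    out$valid <- TRUE
  }
  out
}

# raw spectral peak (no interpolation) of one segment, same search floor as
# the full-record estimator
segment_peak <- function(x, fps) {
  n <- length(x)
  if (sd(x) < 1e-12) return(NA_real_)
  xw <- (x - mean(x)) * hann_window(n)
  half <- floor(n / 2)
  power <- Mod(fft(xw)[2:(half + 1)])^2
  freqs <- (1:half) * fps / n
  search <- which(freqs > max(0.2, 2 * fps / n) & freqs <= fps / 2)
  if (length(search) < 3) return(NA_real_)
  freqs[search[which.max(power[search])]]
}

# a genuine oscillation peaks at the same frequency throughout the record:
# all four quarters, analysed separately, must agree. Lone transients
# (posture reversals), switching noise, and white noise all fail.
peak_sustained <- function(x, fps) {
  n <- length(x)
  if (n < 32) return(TRUE)  # segments too short to resolve anything
  h <- n %/% 4
  fs <- vapply(0:3, function(q) segment_peak(x[(q * h + 1):((q + 1) * h)], fps), 0)
  if (anyNA(fs)) return(FALSE)
  max(fs) - min(fs) <= 2 * fps / h  # two quarter-record resolution steps
}

#' @export
print.frequency_estimate <- function(x, ...) {
  if (is.na(x$frequency)) {
    cat(sprintf("<frequency_estimate> invalid (%s)\n", x$reason))
  } else {
    cat(sprintf("<frequency_estimate> %.3f Hz (resolution %.4g Hz, SNR %.3g, %s)%s\n",
                x$frequency, x$resolution, x$snr,
                if (x$valid) "valid" else paste0("invalid: ", x$reason),
                if (x$aliasing_possible) " [aliasing possible]" else ""))
  }
  invisible(x)
}

#' Total sweep angle of a trace
#'
#' The total angle travelled: either the min-max span of the angles over
#' quality-ok frames (default) or a robust 1st-to-99th percentile span.
#'
#' @param trace An `angle_trace`.
#' @param method `"minmax"` or `"percentile"`.
#' @return Sweep in degrees.
#' @export
sweep_angle <- function(trace, method = c("minmax", "percentile")) {
  method <- match.arg(method)
  if (nrow(trace) < 2) abort_input("need at least 2 frames")
  a <- trace$angle_deg[trace$quality == "ok"]
  if (length(a) == 0) abort_input("all frames are low_signal; sweep undefined")
  switch(method,
    minmax = diff(range(a)),
    percentile = diff(quantile(a, c(0.01, 0.99), names = FALSE))
  )
}

#' Dwell-time fractions per path bin
#'
#' Partitions the observed angular span (min to max over quality-ok frames)
#' into `n_bins` equal-angle bins — on a circular tip path equal angle is
#' equal arc length, so these are equal tenths of the path for
#' `n_bins = 10` — and reports the fraction of quality-ok frames falling in
#' each. Bin 1 is wall-proximal (lowest angle). Fractions sum to 1 exactly.
#'
#' @param trace An `angle_trace`.
#' @param n_bins Number of path bins (default 10).
#' @return A tibble of class `dwell_fractions`: `bin`, `angle_lo`,
#'   `angle_hi`, `fraction`.
#' @export
dwell_fractions <- function(trace, n_bins = 10L) {
  a <- trace$angle_deg[trace$quality == "ok"]
  if (length(a) == 0) abort_input("all frames are low_signal")
  lo <- min(a); hi <- max(a)
  if (hi - lo <= 0) abort_input("zero angular span; dwell fractions undefined")
  wdt <- (hi - lo) / n_bins
  idx <- pmin(floor((a - lo) / wdt) + 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    angle_lo = lo + (seq_len(n_bins) - 1) * wdt,
    angle_hi = lo + seq_len(n_bins) * wdt,
    fraction = counts / length(a)
  )
  class(out) <- c("dwell_fractions", class(out))
  out
}

analytic_phase <- function(x, keep) {
  n <- length(x)
  sp <- fft(x - mean(x))
  mask <- rep(0, n)
  mask[keep] <- 2  # positive-frequency bins only, doubled (analytic signal)
  z <- fft(sp * mask, inverse = TRUE) / n
  Arg(z)
}

#' Pairwise phase synchrony of a field of traces
#'
#' Band-passes every trace around the field's consensus dominant frequency
#' (median of the per-trace spectral peaks), extracts the instantaneous
#' phase by the analytic-signal (FFT) method, and reports for every pair the
#' phase-locking value `PLV = |mean(exp(i * dphi))|` together with the
#' circular-mean phase difference. The pass band is `+/- max(2 / duration,
#' 0.15 * f0)`: at least two resolution steps, widened proportionally so the
#' null PLV of independent records (roughly `1 / sqrt(2 * bandwidth *
#' duration)`) stays small.
#'
#' @param traces List of `angle_trace` tibbles of equal length and frame
#'   rate (at least 2).
#' @param band_halfwidth Optional pass-band half-width in Hz.
#' @return A list of class `synchrony`: `plv` (symmetric matrix, unit
#'   diagonal), `phase_diff_deg` (circular-mean differences, antisymmetric),
#'   `consensus_frequency`.
#' @export
synchrony <- function(traces, band_halfwidth = NULL) {
  if (length(traces) < 2) abort_input("need at least 2 traces")
  n <- nrow(traces[[1]])
  fps <- trace_fps(traces[[1]])
  for (tr in traces) {
    if (nrow(tr) != n) abort_input("traces must all have the same length")
    if (abs(trace_fps(tr) - fps) > 1e-9) abort_input("traces must share fps")
  }
  duration <- n / fps
  peaks <- vapply(traces, function(tr) {
    fe <- dominant_frequency(tr)
    if (is.na(fe$frequency)) NA_real_ else fe$frequency
  }, 0)
  if (all(is.na(peaks))) abort_input("no trace has a spectral peak; synchrony undefined")
  f0 <- median(peaks, na.rm = TRUE)
  hw <- band_halfwidth %||% max(2 / duration, 0.15 * f0)
  freqs <- (0:(n - 1)) * fps / n
  half <- floor(n / 2)
  keep <- which(freqs > 0 & freqs <= fps / 2 & abs(freqs - f0) <= hw)
  keep <- keep[keep <= half + 1]
  if (length(keep) == 0) abort_input("empty pass band")
  phases <- vapply(traces, function(tr) analytic_phase(tr$angle_deg, keep),
                   numeric(n))
  m <- length(traces)
  plv <- diag(1, m)
  pd <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      z <- mean(exp(1i * (phases[, i] - phases[, j])))
      plv[i, j] <- plv[j, i] <- Mod(z)
      pd[i, j] <- Arg(z) * 180 / pi
      pd[j, i] <- -pd[i, j]
    }
  }
  structure(list(plv = plv, phase_diff_deg = pd, consensus_frequency = f0,
                 band_halfwidth = hw),
            class = "synchrony")
}

circular_mean_deg <- function(a) {
  (Arg(mean(exp(1i * a * pi / 180))) * 180 / pi) %% 360
}

#' Classify the motion state of a cilium
#'
#' `oscillating` when the frequency estimate is valid and the sweep is at
#' least 10 degrees; otherwise `static_perpendicular` when the circular-mean
#' angle lies in `[70, 110]` degrees (the extended posture seen once flow
#' ceases), else `static_bent` (the flow-deflected posture near the wall).
#'
#' @param trace An `angle_trace`.
#' @param freq Optional precomputed [dominant_frequency()] estimate.
#' @return One of `"oscillating"`, `"static_bent"`, `"static_perpendicular"`.
#' @export
classify_motion <- function(trace, freq = NULL) {
  if (is.null(freq)) freq <- dominant_frequency(trace)
  sw <- sweep_angle(trace)
  if (isTRUE(freq$valid) && sw >= 10) return("oscillating")
  a <- trace$angle_deg[trace$quality == "ok"]
  mu <- circular_mean_deg(a)
  if (mu > 180) mu <- mu - 360
  if (mu >= 70 && mu <= 110) "static_perpendicular" else "static_bent"
}
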