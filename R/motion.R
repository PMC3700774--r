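#' Temporal range-of-motion projection of a movie
#'
#' Per-pixel temporal mean over a time window (the whole movie if omitted):
#' the standard "average fluorescence" projection that displays the full
#' envelope swept by a moving cilium. The per-pixel temporal variance is
#' computed alongside, because downstream arc fitting uses it to separate
#' the stationary base from the moving distal segment.
#'
#' @param movie A [movie_stack()].
#' @param window Optional window length in seconds from the start of the
#'   movie; must be positive and at most the movie duration.
#' @return A list of class `range_of_motion_map` with elements `image`
#'   (mean), `variance`, `n_frames_used`, `time_window`.
#' @export
range_of_motion <- function(movie, window = NULL) {
  nf <- movie_n_frames(movie)
  if (is.null(window)) window <- movie_duration(movie)
  if (window <= 0) abort_input("window must be > 0 seconds")
  if (window > movie_duration(movie) + 1e-9) {
    abort_input("window exceeds movie duration")
  }
  use <- max(1L, min(nf, as.integer(floor(window * movie$fps))))
  d <- dim(movie$frames)
  p <- matrix(movie$frames[, , seq_len(use)], nrow = d[1] * d[2])
  m <- rowMeans(p)
  v <- rowMeans(p^2) - m^2
  v[v < 0] <- 0
  structure(list(image = matrix(m, d[1], d[2]),
                 variance = matrix(v, d[1], d[2]),
                 n_frames_used = use,
                 time_window = use / movie$fps),
            class = "range_of_motion_map")
}

# above-background mask of the mean projection; threshold is
# median + 5 * MAD, robust to the autofluorescent background dominating the
# field
rom_mask <- function(map) {
  img <- map$image
  thr <- median(img) + 5 * mad(img)
  img > thr
}

#' Construct an arc path
#'
#' The circular arc swept by a cilium tip about its hinge. The path
#' coordinate is angular: on a circle, equal angle is equal arc length, so
#' "each tenth of the path" is unambiguous once the span is fixed. Angles
#' use the image convention (0 = wall-parallel downstream, 90 =
#' perpendicular, i.e. `atan2(-dy, dx)` with y pointing down).
#'
#' @param hinge Numeric `(x, y)`, zero-based pixel coordinates.
#' @param radius Scan radius in pixels (> 0).
#' @param angle_start,angle_end Sector limits in degrees,
#'   `angle_start < angle_end`.
#' @param n_bins Number of equal-angle path bins.
#' @return A list of class `arc_path` with `bin_centers` included.
#' @export
arc_path <- function(hinge, radius, angle_start, angle_end, n_bins = 100L) {
  if (radius <= 0) abort_input("radius must be > 0")
  if (angle_start >= angle_end) abort_input("angle_start must be < angle_end")
  if (n_bins < 2) abort_input("n_bins must be >= 2")
  edges <- seq(angle_start, angle_end, length.out = n_bins + 1)
  structure(list(hinge = as.numeric(hinge), radius = radius,
                 angle_start = angle_start, angle_end = angle_end,
                 n_bins = as.integer(n_bins),
                 bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2),
            class = "arc_path")
}

#' @export
print.arc_path <- function(x, ...) {
  cat(sprintf("<arc_path> hinge (%.1f, %.1f), radius %.1f px, sector [%.1f, %.1f] deg, %d bins\n",
              x$hinge[1], x$hinge[2], x$radius, x$angle_start, x$angle_end,
              x$n_bins))
  invisible(x)
}

#' Fit the tip arc path from a range-of-motion projection
#'
#' Recovers the hinge (fixed bend point), scan radius and angular span of a
#' single cilium's swept sector from the temporal mean and variance images:
#'
#' 1. Mask the mean projection above background ([range_of_motion()]
#'    threshold: median + 5 MAD).
#' 2. Require genuinely moving pixels: temporal variance exceeding twice the
#'    Poisson expectation (`variance > 2 * (mean + 1)`). A static filament —
#'    noiseless or shot-noise limited — has none and raises the
#'    insufficient-motion error.
#' 3. Hinge: the stationary filament segment is the low-variance part of the
#'    mask; the initial hinge is its pixel closest to the centroid of the
#'    moving region. When the movie itself is supplied, the hinge is then
#'    refined to sub-pixel accuracy as the weighted least-squares
#'    intersection of per-frame filament line fits — every frame's filament
#'    line passes through the pivot, so the fitted lines meet there. An
#'    explicit `hinge_hint` overrides detection (but is still refined when
#'    the movie is available).
#' 4. Radius: 0.9 times the intensity-weighted 99.9th-percentile mask
#'    distance from the hinge — a robust maximum that lands the scan circle
#'    just inside the blurred tip envelope, i.e. on the tip path, whether or
#'    not shot noise truncates the faint PSF halo.
#' 5. Span: the smallest angular sector (wrap-aware) containing 99% of mask
#'    pixels within a PSF-scale annulus around the radius; spans under
#'    5 degrees raise the insufficient-motion error.
#'
#' @param map A [range_of_motion()] result.
#' @param movie Optional [movie_stack()] the map came from; enables the
#'   sub-pixel hinge refinement.
#' @param hinge_hint Optional `(x, y)` hinge override (zero-based pixels).
#' @param n_bins Number of equal-angle path bins for the returned arc.
#' @return An [arc_path()].
#' @export
fit_arc_path <- function(map, movie = NULL, hinge_hint = NULL, n_bins = 100L) {
  img <- map$image
  mask <- rom_mask(map)
  if (!any(mask)) {
    abort_stage("no above-background structure in range-of-motion map",
                class = "ciliamotion_error_insufficient_motion")
  }
  moving <- map$variance > 2 * (img + 1)
  if (!any(moving & mask)) {
    abort_stage("insufficient motion; supply ArcPath manually",
                class = "ciliamotion_error_insufficient_motion")
  }
  idx <- which(mask, arr.ind = TRUE)  # (row, col)
  xy <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)

  if (is.null(hinge_hint)) {
    midx <- which(moving & mask, arr.ind = TRUE)
    mcent <- c(mean(midx[, 2] - 1), mean(midx[, 1] - 1))
    static <- mask & !moving
    if (any(static)) {
      sidx <- which(static, arr.ind = TRUE)
      sxy <- cbind(sidx[, 2] - 1, sidx[, 1] - 1)
    } else {
      # fall back: lowest-variance tenth of the mask
      vv <- map$variance[mask]
      keep <- vv <= quantile(vv, 0.1)
      sxy <- xy[keep, , drop = FALSE]
    }
    d2 <- (sxy[, 1] - mcent[1])^2 + (sxy[, 2] - mcent[2])^2
    hinge <- as.numeric(sxy[which.min(d2), ])
  } else {
    hinge <- as.numeric(hinge_hint)
  }
  wts <- pmax(img[mask] - median(img), 0)
  if (!is.null(movie)) {
    max_dist <- weighted_qtile(
      sqrt((xy[, 1] - hinge[1])^2 + (xy[, 2] - hinge[2])^2), wts, 0.999)
    hinge <- refine_hinge(movie, hinge, exclude_radius = 0.35 * max_dist)
  }

  dist <- sqrt((xy[, 1] - hinge[1])^2 + (xy[, 2] - hinge[2])^2)
  radius <- 0.9 * weighted_qtile(dist, wts, 0.999)
  tol <- max(2, 0.15 * radius)
  ring <- abs(dist - radius) <= tol
  if (!any(ring)) {
    abort_stage("insufficient motion; supply ArcPath manually",
                class = "ciliamotion_error_insufficient_motion")
  }
  ang <- atan2(-(xy[ring, 2] - hinge[2]), xy[ring, 1] - hinge[1]) * 180 / pi

  # wrap-aware smallest sector: cut at the largest angular gap, then trim to
  # the central 99%
  a <- sort(ang)
  gaps <- c(diff(a), a[1] + 360 - a[length(a)])
  cut_after <- which.max(gaps)
  origin <- if (cut_after == length(a)) a[1] else a[cut_after + 1]
  rel <- (ang - origin) %% 360
  qs <- quantile(rel, c(0.005, 0.995), names = FALSE)
  angle_start <- origin + qs[1]
  angle_end <- origin + qs[2]
  if (angle_end - angle_start < 5) {
    abort_stage("insufficient motion; supply ArcPath manually",
                class = "ciliamotion_error_insufficient_motion")
  }
  arc_path(hinge, radius, angle_start, angle_end, n_bins)
}

weighted_qtile <- function(x, w, q) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= q)[1]]
}

# Sub-pixel hinge: the filament line of every frame passes through the
# pivot, so the hinge is the weighted least-squares intersection of
# per-frame total-least-squares line fits. Pixels within `exclude_radius`
# of the current hinge are dropped (the base-to-hinge stem is not on the
# distal line); frames whose bright blob is not clearly elongated are
# skipped. Two passes, the second with the refined centre.
refine_hinge <- function(movie, hinge0, exclude_radius = 8,
                         n_fit_frames = 64) {
  nf <- movie_n_frames(movie)
  ks <- unique(round(seq(1, nf, length.out = min(n_fit_frames, nf))))
  hinge <- hinge0
  for (pass in 1:2) {
    A <- matrix(0, 2, 2)
    b <- c(0, 0)
    used <- 0L
    for (k in ks) {
      fr <- movie$frames[, , k]
      thr <- median(fr) + 5 * mad(fr)
      idx <- which(fr > thr, arr.ind = TRUE)
      if (nrow(idx) < 8) next
      xy <- cbind(idx[, 2] - 1, idx[, 1] - 1)
      wt <- fr[idx] - thr
      d0 <- sqrt((xy[, 1] - hinge[1])^2 + (xy[, 2] - hinge[2])^2)
      keep <- d0 > exclude_radius
      if (sum(keep) < 8) next
      xy <- xy[keep, , drop = FALSE]
      wt <- wt[keep]
      mu <- c(sum(xy[, 1] * wt), sum(xy[, 2] * wt)) / sum(wt)
      cx <- sweep(xy, 2, mu)
      cc <- crossprod(cx * sqrt(wt)) / sum(wt)
      ev <- eigen(cc, symmetric = TRUE)
      if (ev$values[1] < 4 * ev$values[2]) next  # blob not line-like
      nv <- ev$vectors[, 2]  # unit normal to the fitted line
      P <- outer(nv, nv)
      A <- A + P
      b <- b + P %*% mu
      used <- used + 1L
    }
    if (used >= 5 && abs(det(A)) > 1e-8) hinge <- as.numeric(solve(A, b))
    else break
  }
  hinge
}

#' Extract a tip-path line-scan kymograph
#'
#' For every frame and every equal-angle bin of the arc, the intensity at
#' the bin-centre point on the scan circle is sampled by bilinear
#' interpolation, producing the classic path-position x time kymograph.
#' Bins whose sample point falls outside the frame are filled with zero and
#' flagged via the `clipped_bins` attribute; an arc fully outside the frame
#' is an error.
#'
#' @param movie A [movie_stack()].
#' @param arc An [arc_path()].
#' @return A `n_bins x n_frames` matrix of class `kymograph` with
#'   attributes `arc` and `fps`.
#' @export
extract_kymograph <- function(movie, arc) {
  d <- dim(movie$frames)
  h <- d[1]; w <- d[2]; nf <- d[3]
  th <- arc$bin_centers * pi / 180
  px <- arc$hinge[1] + arc$radius * cos(th)
  py <- arc$hinge[2] - arc$radius * sin(th)
  inside <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
  if (!any(inside)) abort_input("arc path lies fully outside the frame")
  if (any(!inside)) {
    warn(sprintf("%d of %d arc bins fall outside the frame; filled with 0",
                 sum(!inside), arc$n_bins))
  }
  kymo <- matrix(0, arc$n_bins, nf)
  p <- matrix(movie$frames, nrow = h * w)  # (pixel, frame)
  x0 <- floor(px); y0 <- floor(py)
  x0 <- pmin(pmax(x0, 0), w - 2); y0 <- pmin(pmax(y0, 0), h - 2)
  fx <- px - x0; fy <- py - y0
  lin <- function(xx, yy) yy + 1 + xx * h  # 1-based flat index of (row yy+1, col xx+1)
  ii <- which(inside)
  i00 <- lin(x0[ii], y0[ii]); i10 <- lin(x0[ii] + 1, y0[ii])
  i01 <- lin(x0[ii], y0[ii] + 1); i11 <- lin(x0[ii] + 1, y0[ii] + 1)
  w00 <- (1 - fx[ii]) * (1 - fy[ii]); w10 <- fx[ii] * (1 - fy[ii])
  w01 <- (1 - fx[ii]) * fy[ii]; w11 <- fx[ii] * fy[ii]
  kymo[ii, ] <- w00 * p[i00, , drop = FALSE] + w10 * p[i10, , drop = FALSE] +
    w01 * p[i01, , drop = FALSE] + w11 * p[i11, , drop = FALSE]
  structure(kymo, class = "kymograph", arc = arc, fps = movie$fps,
            clipped_bins = which(!inside))
}

tidy_kymograph <- function(kymo) {
  arc <- attr(kymo, "arc")
  tibble::tibble(
    bin = rep(seq_len(nrow(kymo)), times = ncol(kymo)),
    angle_deg = rep(arc$bin_centers, times = ncol(kymo)),
    frame = rep(0:(ncol(kymo) - 1), each = nrow(kymo)),
    intensity = as.vector(kymo)
  )
}

#' Tip-angle trace from a kymograph
#'
#' Per frame (kymograph column), the background is the column median and the
#' noise scale the column MAD; bins exceeding background + 3 MAD are taken
#' as tip signal and the angle is their background-subtracted
#' intensity-weighted centroid (sub-bin precision; the symmetric PSF makes
#' the centroid unbiased). Frames with no qualifying bin are flagged
#' `low_signal` and filled by linear interpolation, with the flag retained.
#' More than 50% low-signal frames aborts.
#'
#' @param kymo A [extract_kymograph()] result.
#' @return An `angle_trace` tibble.
#' @export
tip_angle_trace <- function(kymo) {
  arc <- attr(kymo, "arc")
  if (is.null(arc)) abort_input("kymograph lacks its arc_path attribute")
  nf <- ncol(kymo)
  nb <- nrow(kymo)
  centers <- arc$bin_centers
  ang <- rep(NA_real_, nf)
  ok <- rep(FALSE, nf)
  for (t in seq_len(nf)) {
    v <- kymo[, t]
    bg <- median(v)
    thr <- bg + 3 * mad(v) + 1e-12
    qual <- v > thr
    if (!any(qual)) next
    # restrict to the contiguous qualifying run containing the brightest
    # bin: the tip crosses the scan circle once, so isolated supra-threshold
    # noise bins elsewhere must not pull the centroid
    peak <- which.max(replace(v, !qual, -Inf))
    lo <- peak
    while (lo > 1 && qual[lo - 1]) lo <- lo - 1
    hi <- peak
    while (hi < nb && qual[hi + 1]) hi <- hi + 1
    w <- v[lo:hi] - bg
    ang[t] <- sum(w * centers[lo:hi]) / sum(w)
    ok[t] <- TRUE
  }
  if (sum(!ok) > nf / 2) {
    abort_stage("trace unreliable: more than 50% of frames have no tip signal",
                class = "ciliamotion_error_low_signal")
  }
  if (any(!ok)) {
    ang <- approx(which(ok), ang[ok], xout = seq_len(nf), rule = 2)$y
  }
  angle_trace_tbl(ang, attr(kymo, "fps"),
                  quality = ifelse(ok, "ok", "low_signal"))
}
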