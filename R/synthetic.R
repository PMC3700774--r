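#' Construct an angle trace
#'
#' An `angle_trace` is a tibble with one row per frame and columns `frame`
#' (0-based), `time_s` (= frame / fps), `angle_deg` (0 = wall-parallel
#' pointing downstream, 90 = perpendicular to the wall, measured in the image
#' plane) and `quality` (`"ok"` or `"low_signal"`). The frame rate is carried
#' as an attribute.
#'
#' @param angles Numeric vector of angles, degrees.
#' @param fps Frames per second (> 0).
#' @param quality Character vector of per-frame flags, recycled.
#' @param cilium_id Optional identifier stored as an attribute.
#' @return A tibble of class `angle_trace`.
#' @export
angle_trace_tbl <- function(angles, fps, quality = "ok", cilium_id = 1L) {
  if (fps <= 0) abort_input("fps must be > 0")
  n <- length(angles)
  out <- tibble::tibble(
    frame = 0:(n - 1),
    time_s = (0:(n - 1)) / fps,
    angle_deg = as.numeric(angles),
    quality = rep_len(quality, n)
  )
  attr(out, "fps") <- fps
  attr(out, "cilium_id") <- cilium_id
  class(out) <- c("angle_trace", class(out))
  out
}

trace_fps <- function(trace) {
  fps <- attr(trace, "fps")
  if (is.null(fps)) {
    dt <- diff(trace$time_s)
    if (length(dt) == 0) abort_input("cannot infer fps from a single frame")
    fps <- 1 / median(dt)
  }
  fps
}

#' Closed-form ground-truth tip-angle trace of a synthetic cilium
#'
#' Evaluates the saturating-dwell drive
#' `theta(t) = wall_angle_min + S * u(t)^p`, `u(t) = (1 + sin(2 pi f t + phi)) / 2`
#' at the scenario's frame times, applies the cilium's fixed phase offset and
#' (seeded) phase jitter, and overlays posture-reversal events
#' (`theta -> 180 - theta`) drawn from a Poisson process with exponential
#' durations when `reversal_rate > 0`. With no drive (`f = 0`, `S = 0`) the
#' trace is constant at `rest_angle`. Deterministic given the scenario seed.
#'
#' @param scenario A [cilium_scenario()].
#' @param cilium_index 1-based cilium index.
#' @return An `angle_trace` tibble ([angle_trace_tbl()]).
#' @export
#' @examples
#' tr <- angle_trace(scenario_preset("renal_anesthetized"))
#' range(tr$angle_deg)
angle_trace <- function(scenario, cilium_index = 1L) {
  sc <- scenario
  if (cilium_index < 1 || cilium_index > sc$n_cilia) {
    abort_input(sprintf("cilium_index %d out of range 1..%d",
                        cilium_index, sc$n_cilia))
  }
  nf <- n_frames(sc)
  t <- (0:(nf - 1)) / sc$fps

  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    eval(expr)
  }

  draws <- withr_seed(cilium_seed(sc, cilium_index), quote({
    jitter <- if (sc$phase_jitter_sd > 0) rnorm(1, 0, sc$phase_jitter_sd) else 0
    rev_iv <- NULL
    if (sc$reversal_rate > 0) {
      n_ev <- rpois(1, sc$reversal_rate * sc$duration)
      if (n_ev > 0) {
        starts <- sort(runif(n_ev, 0, sc$duration))
        durs <- rexp(n_ev, rate = 1 / sc$reversal_mean_duration)
        rev_iv <- cbind(starts, starts + durs)
      }
    }
    list(jitter = jitter, rev_iv = rev_iv)
  }))

  if (sc$drive_frequency == 0 && sc$sweep_span == 0) {
    theta <- rep(sc$rest_angle, nf)
  } else {
    phi <- (sc$phase_offsets[cilium_index] + draws$jitter) * pi / 180
    u <- (1 + sin(2 * pi * sc$drive_frequency * t + phi)) / 2
    theta <- sc$wall_angle_min + sc$sweep_span * u^sc$dwell_exponent
  }

  if (!is.null(draws$rev_iv)) {
    rev <- rep(FALSE, nf)
    for (k in seq_len(nrow(draws$rev_iv))) {
      rev <- rev | (t >= draws$rev_iv[k, 1] & t < draws$rev_iv[k, 2])
    }
    theta[rev] <- 180 - theta[rev]
  }
  angle_trace_tbl(theta, sc$fps, cilium_id = cilium_index)
}

#' Partition a per-cell photon budget across cilia
#'
#' Models GFP dilution: a ciliary membrane marker expressed at a fixed
#' per-cell level spreads over however many cilia the cell carries, so
#' per-cilium brightness scales as 1/N. With the observed counts
#' (about 150 tracheal/oviduct, 15 ependymal, 5 choroid-plexus cilia per
#' cell) the per-cilium brightness ratio is 1 : 10 : 30.
#'
#' @param total_photons Per-cell photon budget (>= 0).
#' @param n_cilia_per_cell Number of cilia sharing the budget (>= 1).
#' @return Photons per cilium; `n_cilia_per_cell * result` equals
#'   `total_photons` exactly.
#' @export
partition_budget <- function(total_photons, n_cilia_per_cell) {
  if (any(n_cilia_per_cell < 1)) {
    abort_input("n_cilia_per_cell must be >= 1")
  }
  if (any(total_photons < 0)) abort_input("total_photons must be >= 0")
  total_photons / n_cilia_per_cell
}

# sample points (0-based pixel coords) along base -> hinge -> tip polyline,
# spacing <= 0.25 px; returns list(x, y)
filament_samples <- function(base, hinge_height, distal_length, theta_deg,
                             step = 0.25) {
  th <- theta_deg * pi / 180
  hinge <- c(base[1], base[2] - hinge_height)
  tip <- hinge + distal_length * c(cos(th), -sin(th))
  seg <- function(p0, p1) {
    len <- sqrt(sum((p1 - p0)^2))
    if (len == 0) return(NULL)
    n <- ceiling(len / step)
    s <- (seq_len(n) - 0.5) / n  # midpoint sampling
    cbind(p0[1] + s * (p1[1] - p0[1]), p0[2] + s * (p1[2] - p0[2]))
  }
  pts <- rbind(seg(base, hinge), seg(hinge, tip))
  list(x = pts[, 1], y = pts[, 2])
}

#' Render the noiseless photon-mean image of a field at given tip angles
#'
#' Each cilium is drawn as a polyline (base to hinge perpendicular to the
#' wall, hinge to tip at the given angle), sampled at steps of at most
#' 0.25 px; every sample deposits an isotropic Gaussian of width `psf_sigma`
#' whose integrated intensity is the per-cilium photon budget divided by the
#' number of samples, so the expected total signal per cilium is independent
#' of the angle. A uniform background is added. Filament portions outside
#' the frame are clipped silently.
#'
#' @param scenario A [cilium_scenario()].
#' @param angles Numeric vector of tip angles (degrees, in `[0, 180]`), one
#'   per cilium.
#' @return `frame_height` x `frame_width` matrix of expected photon counts.
#' @export
render_frame <- function(scenario, angles) {
  sc <- scenario
  if (length(angles) != sc$n_cilia) {
    abort_input("angles must supply one angle per cilium")
  }
  if (any(angles < 0 | angles > 180)) {
    abort_input("angles must lie within [0, 180] degrees")
  }
  budget <- partition_budget(
    sc$photons_per_unit_length * (sc$hinge_height + sc$distal_length),
    sc$cilia_per_cell
  )
  img <- matrix(sc$background, sc$frame_height, sc$frame_width)
  for (i in seq_len(sc$n_cilia)) {
    smp <- filament_samples(sc$base_positions[i, ], sc$hinge_height,
                            sc$distal_length, angles[i])
    wts <- rep(budget / length(smp$x), length(smp$x))
    img <- img + deposit_gaussians(sc$frame_height, sc$frame_width,
                                   smp$x, smp$y, wts, sc$psf_sigma)
  }
  img
}

#' Simulate a noisy time-lapse movie of a cilium field
#'
#' Draws the ground-truth angle trace of every cilium, renders the
#' photon-mean image of each frame, applies per-pixel Poisson shot noise,
#' and quantizes to the scenario's bit depth. Saturated pixels (values
#' clipped at `2^bit_depth - 1`) are counted and reported via the
#' `saturated_pixels` attribute, never silently wrapped. Fully reproducible
#' from the scenario seed.
#'
#' @param scenario A [cilium_scenario()].
#' @return A list with elements `movie` (a [movie_stack()]) and `traces`
#'   (list of ground-truth [angle_trace()] tibbles, one per cilium).
#' @export
#' @examples
#' sim <- simulate_field(scenario_preset("renal_anesthetized", duration = 2))
#' dim(sim$movie$frames)
simulate_field <- function(scenario) {
  sc <- validate_scenario(scenario)
  nf <- n_frames(sc)
  if (nf < 4) abort_input("movie too short: fewer than 4 frames")

  traces <- lapply(seq_len(sc$n_cilia), function(i) angle_trace(sc, i))
  ang <- vapply(traces, function(tr) tr$angle_deg, numeric(nf))
  ang <- matrix(ang, nrow = nf)

  frames <- array(0, dim = c(sc$frame_height, sc$frame_width, nf))
  maxval <- 2^sc$bit_depth - 1
  saturated <- 0L
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(sc$seed)
  for (k in seq_len(nf)) {
    mu <- render_frame(sc, ang[k, ])
    noisy <- rpois(length(mu), lambda = mu)
    over <- noisy > maxval
    saturated <- saturated + sum(over)
    noisy[over] <- maxval
    frames[, , k] <- noisy
  }
  if (saturated > 0) {
    inform(sprintf("simulate_field: %d pixel value(s) saturated at %d",
                   saturated, maxval))
  }
  mv <- movie_stack(frames, fps = sc$fps, bit_depth = sc$bit_depth,
                    source = "synthetic")
  attr(mv, "saturated_pixels") <- saturated
  list(movie = mv, traces = traces)
}
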