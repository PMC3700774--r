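make_map <- function(image, variance) {
  structure(list(image = image, variance = variance,
                 n_frames_used = 10L, time_window = 1),
            class = "range_of_motion_map")
}

gauss_dot <- function(h, w, x0, y0, sigma = 1.5, amp = 100) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  amp * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * sigma^2))
}

test_that("range-of-motion projection is the per-pixel temporal mean", {
  f <- array(0, dim = c(4, 5, 3))
  f[, , 1] <- 0; f[, , 2] <- 2; f[, , 3] <- 1
  mv <- movie_stack(f, fps = 10)
  expect_true(all(range_of_motion(mv)$image == 1))

  cst <- movie_stack(array(7, dim = c(4, 5, 6)), fps = 10)
  m <- range_of_motion(cst)
  expect_true(all(m$image == 7))
  expect_true(all(m$variance == 0))

  # window restricts to the leading frames
  m2 <- range_of_motion(mv, window = 0.1)
  expect_true(all(m2$image == 0))
  expect_equal(m2$n_frames_used, 1L)
  expect_error(range_of_motion(mv, window = 0), "window")
  expect_error(range_of_motion(mv, window = 10), "duration")
})

test_that("thresholded projection covers the swept envelope", {
  sc <- renal_full()
  sim <- simulate_field(sc)
  map <- range_of_motion(sim$movie)
  est_mask <- map$image > median(map$image) + 5 * mad(map$image)
  # oracle: union of per-frame noiseless renders thresholded at half-max
  tru <- sim$traces[[1]]
  union_mask <- matrix(FALSE, sc$frame_height, sc$frame_width)
  for (k in seq_len(nrow(tru))) {
    r <- render_frame(sc, tru$angle_deg[k]) - sc$background
    union_mask <- union_mask | (r > max(r) / 2)
  }
  expect_gte(mean(est_mask[union_mask]), 0.95)
})

test_that("arc fitting recovers hinge and tip-path radius from movies", {
  sc <- renal_full()
  true_hinge <- c(sc$base_positions[1, 1],
                  sc$base_positions[1, 2] - sc$hinge_height)
  for (seed in 1:3) {
    sim <- simulate_field(renal_full(seed = seed))
    arc <- fit_arc_path(range_of_motion(sim$movie), movie = sim$movie)
    expect_lt(sqrt(sum((arc$hinge - true_hinge)^2)), 2)
    expect_lt(abs(arc$radius - sc$distal_length) / sc$distal_length, 0.10)
    expect_lt(arc$angle_start, sc$wall_angle_min + 5)
    expect_gt(arc$angle_end, sc$wall_angle_min + sc$sweep_span - 5)
  }
})

test_that("an analytic annular sector is recovered within one bin width", {
  h <- w <- 64
  hinge <- c(32, 32)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  d <- sqrt((xs - hinge[1])^2 + (ys - hinge[2])^2)
  a <- atan2(-(ys - hinge[2]), xs - hinge[1]) * 180 / pi
  img <- ifelse(abs(d - 20) <= 2 & a >= 30 & a <= 120, 100, 0)
  map <- make_map(img, variance = img * 10)  # uniformly "moving"
  arc <- fit_arc_path(map, hinge_hint = hinge, n_bins = 100)
  bin_w <- (arc$angle_end - arc$angle_start) / arc$n_bins
  expect_lt(abs(arc$angle_start - 30), bin_w + 1)
  expect_lt(abs(arc$angle_end - 120), bin_w + 1)
})

test_that("static movies raise the insufficient-motion error", {
  # noiseless static: zero temporal variance everywhere
  sc <- scenario_preset("death", duration = 2)
  nl <- noiseless_movie(sc)
  expect_error(fit_arc_path(range_of_motion(nl$movie)),
               class = "ciliamotion_error_insufficient_motion")
  # shot-noise-limited static: variance tracks the Poisson mean
  sim <- simulate_field(sc)
  expect_error(fit_arc_path(range_of_motion(sim$movie)),
               class = "ciliamotion_error_insufficient_motion")
})

test_that("kymograph line-scan samples the arc faithfully", {
  arc <- arc_path(c(32, 32), 20, 0, 120, n_bins = 100)
  mv <- movie_stack(array(4.5, dim = c(64, 64, 5)), fps = 26)
  kym <- extract_kymograph(mv, arc)
  expect_true(all(abs(kym - 4.5) < 1e-9))
  expect_equal(dim(kym), c(100L, 5L))

  # bright dot moving along the circle: per-column argmax lands in the
  # right bin
  alphas <- seq(10, 110, length.out = 12)
  frames <- array(0, dim = c(64, 64, length(alphas)))
  for (k in seq_along(alphas)) {
    th <- alphas[k] * pi / 180
    frames[, , k] <- gauss_dot(64, 64, 32 + 20 * cos(th), 32 - 20 * sin(th))
  }
  kym2 <- extract_kymograph(movie_stack(frames, fps = 26), arc)
  bin_w <- 120 / 100
  for (k in seq_along(alphas)) {
    got <- arc$bin_centers[which.max(kym2[, k])]
    expect_lt(abs(got - alphas[k]), bin_w + 1e-9)
  }
  expect_true(all(is.finite(colSums(kym2))) && all(kym2 >= 0))

  # arc fully outside the frame is an error
  expect_error(extract_kymograph(mv, arc_path(c(500, 500), 20, 0, 120)),
               "outside")
})

test_that("tip angle is the centroid of the qualifying bins", {
  arc <- arc_path(c(0, 0), 10, 0, 100, n_bins = 50)
  kym <- matrix(0, 50, 20)
  kym[17, ] <- 10  # single bright bin per column
  kym <- structure(kym, class = "kymograph", arc = arc, fps = 26)
  tr <- tip_angle_trace(kym)
  expect_true(all(abs(tr$angle_deg - arc$bin_centers[17]) < 1e-9))
  expect_true(all(tr$quality == "ok"))

  # featureless kymograph: every frame low-signal -> unreliable
  flat <- structure(matrix(1, 50, 20), class = "kymograph", arc = arc,
                    fps = 26)
  expect_error(tip_angle_trace(flat), class = "ciliamotion_error_low_signal")
})

test_that("noiseless full chain recovers the trace to under 2 degrees RMS", {
  sc <- renal_full()
  nl <- noiseless_movie(sc)
  arc <- fit_arc_path(range_of_motion(nl$movie), movie = nl$movie)
  est <- tip_angle_trace(extract_kymograph(nl$movie, arc))
  rmse <- sqrt(mean((est$angle_deg - nl$trace$angle_deg)^2))
  expect_lt(rmse, 2)
})

test_that("steady-flow cilia are measured bent toward the wall", {
  sim <- simulate_field(scenario_preset("steady_flow", duration = 10))
  arc <- arc_path(c(31.5, 51), 19, 0, 180, n_bins = 100)
  est <- tip_angle_trace(extract_kymograph(sim$movie, arc))
  expect_lt(mean(est$angle_deg), 45)
})

test_that("recovered angles are equivariant under a 90-degree rotation", {
  sc <- renal_short()
  sim <- simulate_field(sc)
  hinge <- c(sc$base_positions[1, 1], sc$base_positions[1, 2] - sc$hinge_height)
  est <- tip_angle_trace(extract_kymograph(
    sim$movie, fit_arc_path(range_of_motion(sim$movie), movie = sim$movie)))

  rot90 <- function(m) t(m[nrow(m):1, ])  # (x,y) -> (H-1-y, x)
  d <- dim(sim$movie$frames)
  fr <- array(0, dim = c(d[2], d[1], d[3]))
  for (k in seq_len(d[3])) fr[, , k] <- rot90(sim$movie$frames[, , k])
  mvr <- movie_stack(fr, fps = sc$fps)
  hinge_r <- c(d[1] - 1 - hinge[2], hinge[1])
  estr <- tip_angle_trace(extract_kymograph(
    mvr, fit_arc_path(range_of_motion(mvr), movie = mvr,
                      hinge_hint = hinge_r)))
  offset <- (estr$angle_deg - est$angle_deg) %% 180
  # constant offset of 90 degrees (mod 180), up to estimator noise
  dev <- pmin(abs(offset - 90), abs(offset - 90 + 180), abs(offset - 90 - 180))
  expect_lt(median(dev), 2)
  expect_lt(mean(dev > 5), 0.02)
})

test_that("trace is stable under path-bin refinement", {
  sc <- renal_short()
  sim <- simulate_field(sc)
  map <- range_of_motion(sim$movie)
  arc1 <- fit_arc_path(map, movie = sim$movie, n_bins = 100)
  arc2 <- arc_path(arc1$hinge, arc1$radius, arc1$angle_start,
                   arc1$angle_end, n_bins = 200)
  t1 <- tip_angle_trace(extract_kymograph(sim$movie, arc1))
  t2 <- tip_angle_trace(extract_kymograph(sim$movie, arc2))
  coarse_bin <- (arc1$angle_end - arc1$angle_start) / 100
  expect_lt(median(abs(t1$angle_deg - t2$angle_deg)), coarse_bin)
})

test_that("full-chain angle recovery holds across seeds", {
  errs <- sapply(1:10, function(seed) {
    sim <- simulate_field(renal_full(seed = seed))
    arc <- fit_arc_path(range_of_motion(sim$movie), movie = sim$movie)
    est <- tip_angle_trace(extract_kymograph(sim$movie, arc))
    median(abs(est$angle_deg - sim$traces[[1]]$angle_deg))
  })
  expect_lt(median(errs), 3)
})
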