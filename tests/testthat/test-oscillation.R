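sin_trace <- function(f, fps = 26, duration = 40, mean = 90, amp = 40,
                      phase = 0) {
  t <- (0:(floor(fps * duration) - 1)) / fps
  angle_trace_tbl(mean + amp * sin(2 * pi * f * t + phase), fps)
}

test_that("spectral peak estimation is exact for pure tones", {
  # constant trace: no peak, invalid but returned
  fe <- dominant_frequency(angle_trace_tbl(rep(90, 200), fps = 26))
  expect_false(fe$valid)
  expect_match(fe$reason, "no spectral peak")

  # on-grid and off-grid tones recovered within one resolution step
  for (f in c(2, 3.137, 4.58, 11.9)) {
    fe <- dominant_frequency(sin_trace(f))
    expect_true(fe$valid)
    expect_equal(fe$resolution, 1 / 40)
    expect_lt(abs(fe$frequency - f), fe$resolution)
  }

  # non-uniform sampling is rejected
  bad <- angle_trace_tbl(sin(1:100), fps = 26)
  bad$time_s[50] <- bad$time_s[50] + 0.01
  expect_error(dominant_frequency(bad), "uniform")
})

test_that("frequency estimate is invariant to scaling, offset, and fps", {
  tr <- sin_trace(4.58, phase = 1.1)
  f0 <- dominant_frequency(tr)$frequency
  # affine rescale of the angles
  tr2 <- tr
  tr2$angle_deg <- 3.7 * tr$angle_deg - 40
  expect_equal(dominant_frequency(tr2)$frequency, f0, tolerance = 1e-12)
  # phase offset
  expect_equal(dominant_frequency(sin_trace(4.58, phase = 2.7))$frequency, f0,
               tolerance = 1 / 40)
  # doubling fps leaves the estimate within one resolution step
  f52 <- dominant_frequency(sin_trace(4.58, fps = 52))$frequency
  expect_lt(abs(f52 - f0), 1 / 40)
})

test_that("analytic renal trace oscillates at the drive frequency", {
  tr <- angle_trace(renal_full())
  fe <- dominant_frequency(tr)
  expect_true(fe$valid)
  expect_lt(abs(fe$frequency - 4.58), fe$resolution)
})

test_that("Nyquist guard: super-Nyquist drives are never validated at f", {
  expect_warning(sc <- cilium_scenario(drive_frequency = 20, fps = 26),
                 "Nyquist")
  fe <- dominant_frequency(suppressWarnings(angle_trace(sc)))
  # the 20 Hz drive aliases below fps/2; whatever is reported, it is not 20
  expect_true(is.na(fe$frequency) || abs(fe$frequency - 20) > 1)
  # peaks hugging Nyquist carry the aliasing flag
  near_nyq <- sin_trace(12.99, fps = 26, duration = 40)
  expect_true(dominant_frequency(near_nyq)$aliasing_possible)
})

test_that("sweep angle measures the arc travelled", {
  expect_equal(sweep_angle(angle_trace_tbl(rep(33, 50), fps = 26)), 0)
  # amplitude 53 sinusoid sweeps 106 degrees peak to peak
  expect_equal(sweep_angle(sin_trace(2, fps = 200, amp = 53)), 106,
               tolerance = 0.1)
  expect_equal(sweep_angle(angle_trace(renal_full())), 106, tolerance = 2)
  # percentile method is robust to a single outlier frame
  tr <- sin_trace(2, amp = 53)
  tr$angle_deg[100] <- 179
  expect_gt(sweep_angle(tr) - 106, 10)
  expect_lt(abs(sweep_angle(tr, method = "percentile") - 106), 5)
  # low-signal frames are excluded
  tr2 <- angle_trace_tbl(c(rep(10, 50), 170), fps = 26,
                         quality = c(rep("ok", 50), "low_signal"))
  expect_equal(sweep_angle(tr2), 0)
})

test_that("dwell fractions recover closed-form occupancy laws", {
  # triangle wave (constant angular speed): uniform occupancy
  up <- seq(0, 100, length.out = 5001)[-5001]
  tri <- angle_trace_tbl(c(up, rev(up)), fps = 100)
  dw <- dwell_fractions(tri)
  expect_true(all(abs(dw$fraction - 0.1) < 0.005))
  expect_equal(sum(dw$fraction), 1, tolerance = 1e-12)

  # sinusoid: arcsine occupancy, heaviest at the extremes
  n <- 1e6
  t <- (0:(n - 1)) / n
  a <- 90 + 50 * sin(2 * pi * t)
  dws <- dwell_fractions(angle_trace_tbl(a, fps = n), n_bins = 10)
  amp <- (max(a) - min(a)) / 2
  mid <- (max(a) + min(a)) / 2
  edges <- seq(min(a), max(a), length.out = 11)
  closed <- diff(asin(pmin(pmax((edges - mid) / amp, -1), 1))) / pi
  expect_true(all(abs(dws$fraction - closed) < 0.01))
  expect_gt(dws$fraction[1], dws$fraction[5])
  expect_equal(dws$fraction, rev(dws$fraction), tolerance = 0.01)

  # invariances: additive offset and time reversal
  tr <- angle_trace(renal_full())
  dw0 <- dwell_fractions(tr)$fraction
  shifted <- tr
  shifted$angle_deg <- tr$angle_deg + 17
  expect_equal(dwell_fractions(shifted)$fraction, dw0, tolerance = 1e-12)
  reversed <- angle_trace_tbl(rev(tr$angle_deg), fps = 26)
  expect_equal(dwell_fractions(reversed)$fraction, dw0, tolerance = 1e-12)

  expect_error(dwell_fractions(angle_trace_tbl(rep(5, 10), fps = 26)),
               "zero angular span")
})

test_that("renal dwell is majority wall-proximal", {
  dw <- dwell_fractions(angle_trace(renal_full()))
  expect_gt(dw$fraction[1], 0.5)
  expect_true(all(dw$fraction[1] > dw$fraction[-1]))
  expect_equal(sum(dw$fraction), 1, tolerance = 1e-12)
})

test_that("phase-locking value separates synchrony from independence", {
  tr <- sin_trace(2, duration = 40)
  s <- synchrony(list(tr, tr))
  expect_equal(s$plv[1, 2], 1, tolerance = 1e-6)
  expect_equal(s$phase_diff_deg[1, 2], 0, tolerance = 1e-6)
  expect_equal(s$plv, t(s$plv))
  expect_true(all(diag(s$plv) == 1))

  # half-period shift: perfectly locked in antiphase (f = 1 Hz, 13 frames)
  t <- (0:1039) / 26
  a1 <- 90 + 40 * sin(2 * pi * 1 * t)
  tr1 <- angle_trace_tbl(a1, fps = 26)
  tr2 <- angle_trace_tbl(c(a1[14:1040], a1[1:13]), fps = 26)
  s2 <- synchrony(list(tr1, tr2))
  expect_equal(s2$plv[1, 2], 1, tolerance = 1e-2)
  expect_equal(abs(s2$phase_diff_deg[1, 2]), 180, tolerance = 1)

  # independent white noise: PLV near the Monte-Carlo null, below 0.2
  set.seed(1)
  n1 <- angle_trace_tbl(rnorm(1040, 90, 10), fps = 26)
  n2 <- angle_trace_tbl(rnorm(1040, 90, 10), fps = 26)
  expect_lt(synchrony(list(n1, n2))$plv[1, 2], 0.2)

  expect_error(synchrony(list(tr)), "at least 2")
  short <- angle_trace_tbl(rnorm(100), fps = 26)
  expect_error(synchrony(list(tr, short)), "same length")
})

test_that("motion states classify by frequency validity and posture", {
  expect_equal(classify_motion(angle_trace(scenario_preset("death"))),
               "static_perpendicular")
  expect_equal(classify_motion(angle_trace(scenario_preset("steady_flow"))),
               "static_bent")
  expect_equal(classify_motion(angle_trace(renal_full())), "oscillating")
})

test_that("oscillation report aggregates per-cilium and field statistics", {
  sc <- renal_short(n_cilia = 2, frame_width = 128,
                    base_positions = cbind(c(35, 92), c(55, 55)))
  traces <- lapply(1:2, function(i) angle_trace(sc, i))
  rep <- oscillation_report(traces)
  td <- tidy(rep)
  expect_equal(nrow(td), 2)
  expect_true(all(td$motion_class == "oscillating"))
  g <- glance(rep)
  expect_equal(g$n_oscillating, 2L)
  expect_equal(g$consensus_frequency_hz, 4.58, tolerance = 0.1)
  expect_gt(g$mean_plv, 0.99)
  # report survives JSON serialization
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$n_cilia, 2)
  expect_equal(back$per_cilium$frequency_hz, td$frequency_hz,
               tolerance = 1e-9)
})
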