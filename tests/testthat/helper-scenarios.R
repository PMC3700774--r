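# shared fixtures, built in code

renal_full <- function(...) scenario_preset("renal_anesthetized", ...)

# shorter record for mid-cost pipeline tests (same kinematics and optics)
renal_short <- function(...) {
  args <- list(...)
  if (!"duration" %in% names(args)) args$duration <- 10
  do.call(scenario_preset, c(list("renal_anesthetized"), args))
}

# noiseless movie rendered straight from a scenario's ground-truth trace
noiseless_movie <- function(sc) {
  tr <- angle_trace(sc)
  frames <- array(0, dim = c(sc$frame_height, sc$frame_width, nrow(tr)))
  for (k in seq_len(nrow(tr))) {
    frames[, , k] <- render_frame(sc, tr$angle_deg[k])
  }
  list(movie = movie_stack(frames, fps = sc$fps, bit_depth = sc$bit_depth),
       trace = tr)
}

# closed-form drive evaluated independently of angle_trace()
drive_theta <- function(t, f, S, p, theta_min, phi_deg = -90) {
  u <- (1 + sin(2 * pi * f * t + phi_deg * pi / 180)) / 2
  theta_min + S * u^p
}
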