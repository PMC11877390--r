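test_that("displacement simulation obeys the recording model and beat count", {
  # canonical recording: 500 fps x 6 s -> 3000 samples
  tr <- simulate_displacement(quiet_state(), 6, 500, seed = 1L)
  expect_equal(nrow(tr), 3000L)
  expect_identical(colnames(unclass(tr)), c("x", "y"))

  # zero-amplitude degeneracy: all components off -> all-zero trace
  zero <- cardiac_params(pulse_amplitude_px = 0, drift_amplitude_px = 0,
                         noise_sd_px = 0)
  tr0 <- simulate_displacement(state_profile("0 min", zero), 2, 100, seed = 3L)
  expect_true(all(tr0 == 0))

  # 1.2 Hz for 60 s with no jitter: exactly 72 local maxima above half the
  # pulse amplitude
  tr2 <- simulate_displacement(quiet_state(1.2, amp = 2), 60, 500, seed = 7L)
  x <- unclass(tr2)[, "x"]
  n <- length(x)
  is_peak <- x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
    x[2:(n - 1)] > max(x) / 2
  expect_identical(sum(is_peak), 72L)
  expect_length(attr(tr2, "beat_times"), 72L)

  # determinism and seed sensitivity
  expect_identical(simulate_displacement(quiet_state(), 1, 200, seed = 5L),
                   simulate_displacement(quiet_state(), 1, 200, seed = 5L))
  expect_false(identical(
    simulate_displacement(alcohol_state_profiles()[[1]], 1, 200, seed = 5L),
    simulate_displacement(alcohol_state_profiles()[[1]], 1, 200, seed = 6L)))

  expect_error(simulate_displacement(quiet_state(), -1, 500),
               "duration_s")
  expect_error(simulate_displacement(quiet_state(), 6, 0), "fps")
})

test_that("cardiac parameters enforce the physiological band", {
  expect_error(cardiac_params(heart_rate_hz = 0.3), "heart_rate_hz")
  expect_error(cardiac_params(heart_rate_hz = 3.5), "heart_rate_hz")
  expect_error(cardiac_params(drift_freq_hz = 0.7), "drift_freq_hz")
  expect_error(cardiac_params(hrv_sd_s = -1), "hrv_sd_s")
  expect_error(state_profile("lunch"), "label")
})

test_that("displacement power concentrates in the 0.5-3 Hz cardiac band", {
  # drift and noise off: >90% of non-DC power inside the band
  for (hr in c(0.8, 1.4, 2.5)) {
    st <- cardiac_params(heart_rate_hz = hr, hrv_sd_s = 0.05,
                         drift_amplitude_px = 0, noise_sd_px = 0)
    x <- unclass(simulate_displacement(state_profile("0 min", st), 60, 200,
                                       seed = 11L))[, "x"]
    n <- length(x)
    p <- Mod(fft(x - mean(x)))^2
    freq <- (1:(n %/% 2)) / n * 200
    pw <- p[2:(n %/% 2 + 1)]
    frac <- sum(pw[freq >= 0.5 & freq <= 3]) / sum(pw)
    expect_gt(frac, 0.9)
  }
})

test_that("speckle rendering is a rigid translation of one master field", {
  op <- optics_params(frame_px = 48, master_margin_px = 12, seed = 2L)

  # no motion, no noise -> every frame identical to frame 0
  vid0 <- render_speckle_video(matrix(0, 20, 2), op, fps = 100)
  expect_true(all(vid0$frames == as.vector(vid0$frames[, , 1])))

  # constant +1 px/frame in x: frame i equals frame 0 translated by (i, 0)
  sh <- cbind(x = 0:8, y = 0L)
  vid <- render_speckle_video(sh, op, fps = 100)
  for (i in c(2L, 5L, 9L)) {
    dx <- i - 1L
    expect_identical(vid$frames[, 1:(48 - dx), 1L],
                     vid$frames[, (1 + dx):48, i])
  }

  # determinism: same params twice -> bit-identical videos
  expect_identical(render_speckle_video(sh, op, fps = 100)$frames,
                   vid$frames)

  # bounds error names the offending frame
  expect_error(render_speckle_video(cbind(x = c(0, 30), y = 0), op),
               "frame 2")
})

test_that("master speckle field is a developed pattern, not a flat field", {
  m <- speckle_master_field(128, grain_px = 4, seed = 9L)
  cv <- sd(m) / mean(m)
  expect_gt(cv, 0.3)
  expect_true(all(m >= 0 & m <= 255))
  # grain scales with the aperture: coarser grains -> stronger lag-2
  # autocorrelation along rows
  ac <- function(mm) {
    v <- as.vector(mm[, -(1:2)] * mm[, 1:(ncol(mm) - 2)])
    (mean(v) - mean(mm)^2) / var(as.vector(mm))
  }
  m8 <- speckle_master_field(128, grain_px = 8, seed = 9L)
  expect_gt(ac(m8), ac(m))
})

test_that("study simulation mirrors the five-set design", {
  # 5 subjects x 5 states x 5 recordings -> 125 recordings (fast mode)
  study <- simulate_study(recordings_per_state = 5, duration_s = 0.1,
                          fps = 100, seed = 2L)
  expect_identical(nrow(study$manifest), 125L)
  expect_length(study$recordings, 125L)
  expect_identical(as.vector(table(study$manifest$subject_id)),
                   rep(25L, 5))

  # 1 subject x 5 states x 1 recording -> 5 rows
  one <- simulate_study(default_study_design(1), recordings_per_state = 1,
                        duration_s = 0.1, fps = 100, seed = 2L)
  expect_identical(nrow(one$manifest), 5L)
  expect_setequal(one$manifest$time_label, time_labels())

  # determinism of the whole study
  again <- simulate_study(default_study_design(1), recordings_per_state = 1,
                          duration_s = 0.1, fps = 100, seed = 2L)
  expect_identical(one, again)

  # duplicate subjects and incomplete label sets are rejected
  dup <- default_study_design(2)
  dup[[2]]$subject_id <- dup[[1]]$subject_id
  expect_error(simulate_study(dup, 1, 0.1, 100), "duplicate")
  short <- default_study_design(1)
  short[[1]]$profiles <- short[[1]]$profiles[1:4]
  expect_error(simulate_study(short, 1, 0.1, 100), "missing state labels")
})

test_that("alcohol-state defaults scale amplitude and rate monotonically back", {
  profs <- alcohol_state_profiles()
  amps <- vapply(profs, function(p) p$cardiac$pulse_amplitude_px, numeric(1))
  rates <- vapply(profs, function(p) p$cardiac$heart_rate_hz, numeric(1))
  expect_identical(names(profs), time_labels())
  # post-consumption values exceed baseline and decline toward it
  expect_true(all(amps[-1] > amps[1]))
  expect_true(all(diff(amps[-1]) < 0))
  expect_true(all(rates[-1] > rates[1]))
  expect_true(all(diff(rates[-1]) < 0))
})
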