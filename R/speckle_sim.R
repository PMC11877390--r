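#' Cardiac displacement-signal parameters
#'
#' Parameters of the heartbeat-driven surface-tilt waveform that moves the
#' speckle pattern laterally. Beats are raised-cosine (Hann) displacement
#' lobes at jittered beat times; inter-beat intervals are drawn from a
#' truncated-positive normal with mean `1/heart_rate_hz` and standard
#' deviation `hrv_sd_s` (the heart-rate-variability model). A sub-0.5 Hz
#' sinusoidal drift emulates motion artifacts and white displacement noise
#' emulates residual tracking jitter.
#'
#' @param heart_rate_hz Mean beat frequency in Hz. Must lie in the
#'   physiological band \[0.5, 3\] that separates cardiac motion from
#'   sub-0.5 Hz artifacts.
#' @param hrv_sd_s Standard deviation of inter-beat intervals, seconds.
#' @param pulse_amplitude_px Peak tilt-induced lateral shift per beat, pixels.
#' @param pulse_width_s Duration of one beat's displacement lobe, seconds.
#' @param drift_amplitude_px,drift_freq_hz Amplitude (px) and frequency (Hz,
#'   must be < 0.5) of the sinusoidal motion-artifact drift.
#' @param noise_sd_px Standard deviation of additive white displacement
#'   noise, pixels.
#' @param direction Unit direction (x, y) along which the cardiac signal
#'   acts; both axes carry correlated signal. Normalized internally.
#' @return An object of class `cardiac_params`.
#' @export
cardiac_params <- function(heart_rate_hz = 1.1, hrv_sd_s = 0.05,
                           pulse_amplitude_px = 2.0, pulse_width_s = 0.4,
                           drift_amplitude_px = 0.5, drift_freq_hz = 0.1,
                           noise_sd_px = 0.05, direction = c(1, 0.4)) {
  check_scalar_num(heart_rate_hz, "heart_rate_hz", 0.5, 3.0)
  check_scalar_num(hrv_sd_s, "hrv_sd_s", 0)
  check_scalar_num(pulse_amplitude_px, "pulse_amplitude_px", 0)
  check_scalar_num(pulse_width_s, "pulse_width_s", 0, strict_lower = TRUE)
  check_scalar_num(drift_amplitude_px, "drift_amplitude_px", 0)
  check_scalar_num(drift_freq_hz, "drift_freq_hz", 0)
  if (drift_freq_hz >= 0.5)
    stop_invalid("`drift_freq_hz` must be < 0.5 Hz (motion-artifact band), got %g",
                 drift_freq_hz)
  check_scalar_num(noise_sd_px, "noise_sd_px", 0)
  if (length(direction) != 2L || all(direction == 0))
    stop_invalid("`direction` must be a non-zero length-2 vector")
  structure(list(
    heart_rate_hz = heart_rate_hz, hrv_sd_s = hrv_sd_s,
    pulse_amplitude_px = pulse_amplitude_px, pulse_width_s = pulse_width_s,
    drift_amplitude_px = drift_amplitude_px, drift_freq_hz = drift_freq_hz,
    noise_sd_px = noise_sd_px,
    direction = as.numeric(direction) / sqrt(sum(direction^2))
  ), class = "cardiac_params")
}

#' Per-time-point state profile
#'
#' Binds one of the five measurement time-point labels to the cardiac
#' parameters that generate its displacement signal.
#'
#' @param label One of [time_labels()].
#' @param cardiac A [cardiac_params()] object.
#' @return An object of class `state_profile`.
#' @export
state_profile <- function(label, cardiac = cardiac_params()) {
  if (!is.character(label) || length(label) != 1L ||
      !(label %in% time_labels()))
    stop_invalid("`label` must be one of: %s",
                 paste(time_labels(), collapse = ", "))
  if (!inherits(cardiac, "cardiac_params"))
    stop_invalid("`cardiac` must be a cardiac_params object")
  structure(list(label = label, cardiac = cardiac), class = "state_profile")
}

#' Default alcohol-state profiles
#'
#' One [state_profile()] per time point. The baseline ("before drinking")
#' uses `heart_rate_hz = 1.1`, `pulse_amplitude_px = 2`, `hrv_sd_s = 0.05`;
#' post-consumption states scale amplitude by 1.5/1.4/1.25/1.15 and rate by
#' 1.25/1.2/1.12/1.06 at 0/30/60/90 min — a monotone return toward baseline
#' mimicking a linear decline of blood alcohol concentration from about
#' 0.05\% to 0.025\% over the session. These are simulator assumptions (the
#' stated world of the synthetic study), not measured effect sizes.
#'
#' @param baseline `cardiac_params` for the pre-consumption state.
#' @param amplitude_scale,rate_scale Length-4 multipliers applied to the
#'   baseline amplitude and heart rate at 0/30/60/90 min.
#' @return Named list of five `state_profile` objects.
#' @export
alcohol_state_profiles <- function(baseline = cardiac_params(),
                                   amplitude_scale = c(1.5, 1.4, 1.25, 1.15),
                                   rate_scale = c(1.25, 1.2, 1.12, 1.06)) {
  stopifnot(length(amplitude_scale) == 4L, length(rate_scale) == 4L)
  labs <- time_labels()
  profs <- vector("list", 5L)
  names(profs) <- labs
  profs[[1L]] <- state_profile(labs[1L], baseline)
  for (k in 1:4) {
    cp <- baseline
    cp$pulse_amplitude_px <- baseline$pulse_amplitude_px * amplitude_scale[k]
    cp$heart_rate_hz <- min(3, baseline$heart_rate_hz * rate_scale[k])
    profs[[k + 1L]] <- state_profile(labs[k + 1L], cp)
  }
  profs
}

#' Simulate a ground-truth 2D displacement time series
#'
#' Generates the lateral position of the speckle pattern over time: a train
#' of Hann-shaped beat lobes at jittered beat times projected onto the
#' cardiac direction vector, plus sinusoidal sub-0.5 Hz drift along a random
#' direction and white displacement noise. Deterministic for a given seed.
#'
#' @param state A [state_profile()] (or `cardiac_params`; label then unused).
#' @param duration_s Recording length in seconds (> 0).
#' @param fps Frame rate in Hz (> 0). The default recording model is
#'   500 fps for 6 s, i.e. 3000 samples at 2 ms resolution.
#' @param seed Integer RNG seed.
#' @return A numeric matrix with `round(duration_s * fps)` rows and columns
#'   `x`, `y` (cumulative lateral position, pixels), class
#'   `displacement_series`, with attributes `fps` and `beat_times` (the true
#'   beat centres, seconds).
#' @export
simulate_displacement <- function(state, duration_s = 6, fps = 500,
                                  seed = 1L) {
  if (inherits(state, "state_profile")) state <- state$cardiac
  if (!inherits(state, "cardiac_params"))
    stop_invalid("`state` must be a state_profile or cardiac_params object")
  check_scalar_num(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_scalar_num(fps, "fps", 0, strict_lower = TRUE)

  n <- round(duration_s * fps)
  t <- (seq_len(n) - 1) / fps
  set.seed(seed)

  ibi <- 1 / state$heart_rate_hz
  # beat times: first beat uniform within one mean interval, then jittered
  # intervals; redraw non-positive intervals (truncated-positive normal)
  beats <- numeric(0)
  tb <- runif(1, 0, ibi)
  while (tb < duration_s + state$pulse_width_s) {
    beats <- c(beats, tb)
    repeat {
      step <- rnorm(1, ibi, state$hrv_sd_s)
      if (step > 0) break
    }
    tb <- tb + step
  }

  s <- numeric(n)
  half <- state$pulse_width_s / 2
  for (tb in beats) {
    lo <- max(1L, ceiling((tb - half) * fps) + 1L)
    hi <- min(n, floor((tb + half) * fps) + 1L)
    if (lo > hi) next
    u <- t[lo:hi] - tb
    s[lo:hi] <- s[lo:hi] +
      state$pulse_amplitude_px * 0.5 * (1 + cos(pi * u / half))
  }

  pos <- outer(s, state$direction)  # n x 2, cardiac component
  if (state$drift_amplitude_px > 0) {
    phi <- runif(1, 0, 2 * pi)
    psi <- runif(1, 0, 2 * pi)
    drift <- state$drift_amplitude_px *
      sin(2 * pi * state$drift_freq_hz * t + phi)
    pos <- pos + outer(drift, c(cos(psi), sin(psi)))
  }
  if (state$noise_sd_px > 0)
    pos <- pos + matrix(rnorm(2 * n, 0, state$noise_sd_px), ncol = 2)

  colnames(pos) <- c("x", "y")
  structure(pos, class = c("displacement_series", class(pos)),
            fps = fps, beat_times = beats[beats < duration_s])
}

#' Speckle-field rendering parameters
#'
#' Controls synthesis of the master speckle field and the virtual camera.
#' The master field is larger than one frame by `master_margin_px` on every
#' side so that translated crops never leave its bounds.
#'
#' @param frame_px Frame side length in pixels.
#' @param grain_px Mean speckle grain size in pixels (>= 2, so the
#'   correlation peak is sampled above Nyquist).
#' @param master_margin_px Extra border of the master field, pixels. Must
#'   exceed the largest cumulative shift to be rendered.
#' @param bit_depth Output quantization, bits (8 matches common
#'   machine-vision sensors).
#' @param sensor_noise_sd Additive Gaussian intensity noise, grey levels.
#' @param seed RNG seed for field synthesis and sensor noise.
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(frame_px = 64, grain_px = 4, master_margin_px = 16,
                          bit_depth = 8, sensor_noise_sd = 0, seed = 1L) {
  check_scalar_num(frame_px, "frame_px", 0, strict_lower = TRUE)
  check_scalar_num(grain_px, "grain_px", 2)
  check_scalar_num(master_margin_px, "master_margin_px", 1)
  check_scalar_num(bit_depth, "bit_depth", 1, 16)
  check_scalar_num(sensor_noise_sd, "sensor_noise_sd", 0)
  structure(list(frame_px = as.integer(frame_px), grain_px = grain_px,
                 master_margin_px = as.integer(master_margin_px),
                 bit_depth = as.integer(bit_depth),
                 sensor_noise_sd = sensor_noise_sd, seed = as.integer(seed)),
            class = "optics_params")
}

#' Synthesize a fully developed speckle field
#'
#' Random-phase screen: uniform phases on a centred circular frequency
#' support of diameter `side / grain_px`, inverse-transformed; the intensity
#' is exponential-like (fully developed speckle) with grain size set by the
#' support diameter. Returned scaled so the mean intensity sits at one
#' quarter of full scale, leaving headroom for bright speckles.
#'
#' @param side Field side length, pixels.
#' @param grain_px Mean grain size, pixels.
#' @param bit_depth Quantization target used only to pick the intensity
#'   scale.
#' @param seed RNG seed.
#' @return `side` x `side` numeric matrix of intensities in
#'   \[0, 2^bit_depth - 1\].
#' @export
speckle_master_field <- function(side, grain_px = 4, bit_depth = 8,
                                 seed = 1L) {
  set.seed(seed)
  f <- c(0:(side %/% 2), -((side - (side %/% 2) - 1):1)) / side
  r2 <- outer(f^2, f^2, "+")
  support <- r2 <= (1 / (2 * grain_px))^2   # circular aperture, radius 1/(2*grain)
  phase <- matrix(runif(side * side, 0, 2 * pi), side, side)
  field <- matrix(0 + 0i, side, side)
  field[support] <- exp(1i * phase[support])
  amp <- fft(field, inverse = TRUE)
  intensity <- Mod(amp)^2
  full <- 2^bit_depth - 1
  out <- intensity / mean(intensity) * (full / 4)
  pmin(out, full)
}

#' Render a speckle video from a displacement series
#'
#' A defocused camera sees surface tilt as a rigid lateral shift of the
#' speckle pattern, so each frame is a crop of one master speckle field
#' translated by that frame's cumulative shift. Integer shifts are rendered
#' by pure indexing (exact), fractional parts by bilinear interpolation.
#' Sensor noise is added before quantization to `bit_depth`.
#'
#' @param true_shift n x 2 matrix of cumulative (x, y) shifts in pixels
#'   (e.g. from [simulate_displacement()]).
#' @param optics An [optics_params()] object.
#' @param fps Frames per second recorded in the video; defaults to the
#'   `fps` attribute of `true_shift` if present, else 500.
#' @return A `speckle_video`: list with `frames` (H x W x n integer array),
#'   `fps`, and `ground_truth` (the input shift series).
#' @export
render_speckle_video <- function(true_shift, optics = optics_params(),
                                 fps = NULL) {
  if (is.null(fps)) fps <- attr(true_shift, "fps")
  if (is.null(fps)) fps <- 500
  shift <- unclass(true_shift)
  if (!is.matrix(shift) || ncol(shift) != 2L)
    stop_invalid("`true_shift` must be an n x 2 matrix of (x, y) shifts")
  n <- nrow(shift)
  fp <- optics$frame_px
  margin <- optics$master_margin_px

  bad <- which(apply(abs(shift), 1L, max) > margin - 1)
  if (length(bad))
    stop_invalid(paste0("shift exceeds master margin (%d px) at frame %d ",
                        "(|shift| = %.2f px)"),
                 margin, bad[1L], max(abs(shift[bad[1L], ])))

  side <- fp + 2L * margin
  master <- speckle_master_field(side, optics$grain_px, optics$bit_depth,
                                 optics$seed)
  full <- 2^optics$bit_depth - 1

  # sensor noise drawn after field synthesis, same seeded stream
  frames <- array(0L, dim = c(fp, fp, n))
  base_r <- margin + seq_len(fp)   # row = y, col = x; origin top-left
  base_c <- margin + seq_len(fp)
  for (i in seq_len(n)) {
    sx <- shift[i, 1L]; sy <- shift[i, 2L]
    r0 <- floor(sy); c0 <- floor(sx)
    fy <- sy - r0;   fx <- sx - c0
    ri <- base_r - r0; ci <- base_c - c0
    if (fy == 0 && fx == 0) {
      fr <- master[ri, ci]
    } else {
      fr <- master[ri, ci] * (1 - fy) * (1 - fx) +
        master[ri - 1L, ci] * fy * (1 - fx) +
        master[ri, ci - 1L] * (1 - fy) * fx +
        master[ri - 1L, ci - 1L] * fy * fx
    }
    if (optics$sensor_noise_sd > 0)
      fr <- fr + rnorm(length(fr), 0, optics$sensor_noise_sd)
    frames[, , i] <- as.integer(pmin(pmax(round(fr), 0), full))
  }
  structure(list(frames = frames, fps = fps, ground_truth = shift),
            class = "speckle_video")
}

#' @export
print.speckle_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("speckle_video: %d frames of %d x %d px at %g fps (%.2f s)%s\n",
              d[3L], d[1L], d[2L], x$fps, d[3L] / x$fps,
              if (is.null(x$ground_truth)) "" else ", with ground truth"))
  invisible(x)
}

#' Default study design
#'
#' The synthetic counterpart of the five-subject drinking study: each
#' subject measured at all five time points with shared per-state cardiac
#' profiles.
#'
#' @param n_subjects Number of subjects.
#' @param profiles Named list of five `state_profile`s, one per time label.
#' @return List with one element per subject: `list(subject_id, profiles)`.
#' @export
default_study_design <- function(n_subjects = 5,
                                 profiles = alcohol_state_profiles()) {
  lapply(seq_len(n_subjects), function(s)
    list(subject_id = paste0("S", s), profiles = profiles))
}

#' Simulate a full drinking study
#'
#' Emits `recordings_per_state` recordings per subject per time point with
#' distinct derived seeds, plus a manifest. The default design mirrors the
#' study layout: 5 subjects x 5 states x 5 recordings = 125 videos. In fast
#' mode (`render = FALSE`) the ground-truth displacement traces are returned
#' directly, skipping speckle rendering; this is exact up to the vibrometry
#' stage's separately verified recovery error.
#'
#' @param design Study design as from [default_study_design()]. Every
#'   subject must carry all five labels; subject ids must be unique.
#' @param recordings_per_state Recordings per subject per time point.
#' @param duration_s,fps Recording length and frame rate.
#' @param seed Master seed; every recording derives its own seed from it.
#' @param render If `TRUE`, render speckle videos; if `FALSE` return the
#'   displacement traces (fast mode).
#' @param optics `optics_params` used when rendering.
#' @return List with `recordings` (named list of `speckle_video` or
#'   `displacement_series`) and `manifest` (tibble: subject_id, time_label,
#'   recording_id, name, seed).
#' @export
simulate_study <- function(design = default_study_design(),
                           recordings_per_state = 5, duration_s = 6,
                           fps = 500, seed = 1L, render = FALSE,
                           optics = optics_params()) {
  ids <- vapply(design, function(d) d$subject_id, character(1))
  if (anyDuplicated(ids))
    stop_invalid("duplicate subject ids in design: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (d in design) {
    labs <- vapply(d$profiles, function(p) p$label, character(1))
    if (!setequal(labs, time_labels()))
      stop_invalid("subject %s is missing state labels: %s", d$subject_id,
                   paste(setdiff(time_labels(), labs), collapse = ", "))
  }

  recs <- list()
  rows <- list()
  for (si in seq_along(design)) {
    d <- design[[si]]
    for (li in seq_along(time_labels())) {
      lab <- time_labels()[li]
      prof <- d$profiles[[which(vapply(d$profiles, function(p) p$label,
                                       character(1)) == lab)]]
      for (ri in seq_len(recordings_per_state)) {
        rec_seed <- derive_seed(seed, c(si, li, ri))
        tr <- simulate_displacement(prof, duration_s, fps, rec_seed)
        nm <- sprintf("%s_%s_rec%d", d$subject_id, gsub(" ", "", lab), ri)
        recs[[nm]] <- if (render) {
          op <- optics; op$seed <- derive_seed(rec_seed, 1L)
          render_speckle_video(tr, op)
        } else tr
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = d$subject_id, time_label = lab, recording_id = ri,
          name = nm, seed = rec_seed)
      }
    }
  }
  list(recordings = recs, manifest = do.call(rbind, rows))
}
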