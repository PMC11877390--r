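# Shared fixtures, all generated in code.

# short noise-free cardiac state for fast vibrometry round trips
quiet_state <- function(heart_rate_hz = 1.2, amp = 2) {
  state_profile("before drinking",
                cardiac_params(heart_rate_hz = heart_rate_hz, hrv_sd_s = 0,
                               pulse_amplitude_px = amp,
                               drift_amplitude_px = 0, noise_sd_px = 0))
}

# integer zig-zag shift series bounded well inside the default margin
integer_shift_series <- function(n, amp_x = 3, amp_y = 2, period = 40) {
  t <- seq_len(n) - 1
  cbind(x = round(amp_x * sin(2 * pi * t / period)),
        y = round(amp_y * sin(2 * pi * t / (period * 1.7))))
}

# a tiny study already chunked and featurized, cached per session
small_feature_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      study <- simulate_study(default_study_design(3),
                              recordings_per_state = 1, duration_s = 3,
                              fps = 500, seed = 404L)
      cache <<- extract_features(chunk_study(study))
    }
    cache
  }
})

# feature table with iid noise features and an optional separable column
synthetic_feature_table <- function(n_per_class, classes, n_features = 10,
                                    seed = 1L, separable = FALSE) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  lab <- rep(classes, each = n_per_class)
  feat <- matrix(rnorm(n * n_features), n,
                 dimnames = list(NULL, paste0("x__f", seq_len(n_features))))
  tab <- cbind(
    tibble::tibble(subject_id = rep(paste0("S", seq_along(classes)),
                                    each = n_per_class),
                   recording_id = 1, chunk_index = seq_len(n),
                   time_label = lab),
    tibble::as_tibble(feat))
  if (separable)
    tab$x__f1 <- as.numeric(factor(lab)) + rnorm(n, 0, 0.01)
  tab
}
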