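# Shared fixtures, built once per test run. Subject setups (calibration kit
# + trained classifier) are the expensive pieces, so they are memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture_setup <- function(cohort = "healthy", seed = 42L) {
  key <- paste0(cohort, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- suppressWarnings(
      subject_setup(cohort = cohort, seed = seed))
  .fixture_env[[key]]
}

# A single-frequency test recording on a minimal two-channel fcu/ecu layout.
sine_recording <- function(freq_hz, amp = 1, dur_s = 5, fs = 1000,
                           n_channels = 6) {
  tt <- seq_len(dur_s * fs) / fs
  x <- matrix(rep(amp * sin(2 * pi * freq_hz * tt), each = n_channels),
              nrow = n_channels, byrow = FALSE)
  roles <- c("fcu", "mid1", "mid2", "mid3", "mid4", "ecu")[seq_len(n_channels)]
  emg_recording(x, fs, roles)
}

# Two-channel calibration profile for controller arithmetic tests:
# channel 1 = fcu, channel 2 = ecu.
pair_calib <- function(rest_f = 0.1, mvc_f = 0.5, rest_e = 0.1, mvc_e = 1.0) {
  calibration_profile(rest_env = c(rest_f, rest_e),
                      mvc_env = c(mvc_f, mvc_e),
                      channel_roles = c("fcu", "ecu"))
}

# Magnitude of a digital filter's frequency response at f (Hz), computed
# directly from the coefficient polynomials — independent of the streaming
# filter implementation under test.
freq_response_mag <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}
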