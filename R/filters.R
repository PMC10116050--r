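#' Envelope series
#'
#' Non-negative, slowly varying amplitude estimate of a multichannel sEMG
#' signal (full-wave rectification followed by a causal low-pass filter),
#' sampled at the same rate as its source recording.
#'
#' @param values numeric matrix, channels x samples, millivolts, >= 0.
#' @param fs sampling rate in Hz.
#' @param channel_roles optional role labels carried over from the source.
#' @return An object of class `envelope_series`.
#' @export
envelope_series <- function(values, fs, channel_roles = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("envelope values must be non-negative")
  structure(list(values = values, fs = fs, channel_roles = channel_roles),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %d channels x %d samples @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

# Butterworth coefficients for the pipeline stages, designed at runtime from
# fs (bilinear transform via signal::butter), so non-1 kHz material works.
butter_coef <- function(order, cutoff_hz, fs, type) {
  w <- cutoff_hz / (fs / 2)
  if (any(w <= 0) || any(w >= 1))
    stop("cutoff must lie strictly inside (0, fs/2)")
  flt <- signal::butter(order, w, type = type)
  list(b = as.numeric(flt$b), a = as.numeric(flt$a))
}

# One streaming filter stage: coefficients + per-channel state.
iir_state <- function(coef, n_channels) {
  k <- max(length(coef$b), length(coef$a)) - 1L
  list(b = coef$b, a = coef$a,
       z = matrix(0, nrow = n_channels, ncol = k))
}

# Filter a channels x samples chunk through a stage, carrying state.
iir_apply <- function(state, x) {
  out <- .iir_chunk_cpp(state$b, state$a, x, state$z)
  state$z <- out$zf
  list(y = out$y, state = state)
}

#' High-pass filter raw sEMG (movement-artifact removal)
#'
#' Causal second-order Butterworth high-pass at 20 Hz, applied independently
#' per channel. Removes electrode drift and motion artifacts before feature
#' extraction or envelope computation.
#'
#' @param rec an [emg_recording()].
#' @param cutoff_hz high-pass cutoff, default 20 Hz.
#' @param order filter order, default 2.
#' @return An [emg_recording()] with filtered samples.
#' @export
emg_highpass <- function(rec, cutoff_hz = 20, order = 2) {
  stopifnot(inherits(rec, "emg_recording"))
  st <- iir_state(butter_coef(order, cutoff_hz, rec$fs, "high"),
                  nrow(rec$samples))
  y <- iir_apply(st, rec$samples)$y
  emg_recording(y, rec$fs, rec$channel_roles, rec$subject_profile_id)
}

#' Compute sEMG envelopes (rectify + low-pass)
#'
#' Full-wave rectification followed by a causal fourth-order Butterworth
#' low-pass at 2 Hz. The input is expected to be high-pass filtered already;
#' use [process_emg()] for the full pipeline. Filter ringing below zero is
#' clamped to zero, since envelopes are amplitude estimates.
#'
#' @param rec an [emg_recording()] (already high-pass filtered).
#' @param cutoff_hz low-pass cutoff, default 2 Hz.
#' @param order filter order, default 4.
#' @return An [envelope_series()].
#' @export
emg_envelope <- function(rec, cutoff_hz = 2, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  st <- iir_state(butter_coef(order, cutoff_hz, rec$fs, "low"),
                  nrow(rec$samples))
  y <- iir_apply(st, abs(rec$samples))$y
  y[y < 0] <- 0
  envelope_series(y, rec$fs, rec$channel_roles)
}

#' Full envelope pipeline: high-pass, rectify, low-pass
#'
#' The canonical real-time processing chain: a causal 2nd-order 20 Hz
#' Butterworth high-pass, full-wave rectification, then a causal 4th-order
#' 2 Hz Butterworth low-pass. All stages are forward-only (no zero-phase
#' filtering), matching a streaming controller.
#'
#' @param rec an [emg_recording()] of raw sEMG.
#' @return An [envelope_series()].
#' @export
process_emg <- function(rec) emg_envelope(emg_highpass(rec))

#' Streaming envelope pipeline with carried filter state
#'
#' Creates (and steps) a stateful version of [process_emg()] for chunked
#' real-time use: feeding a signal chunk by chunk through the stream
#' reproduces the one-shot result exactly, because every filter stage carries
#' its internal state across chunk boundaries.
#'
#' @param n_channels number of channels the stream will process.
#' @param fs sampling rate in Hz.
#' @param hp_hz,lp_hz high- and low-pass cutoffs (defaults 20 and 2 Hz).
#' @return `emg_stream()` returns a stream state object; `emg_stream_step()`
#'   returns `list(hp = , env = , stream = )` with the high-passed chunk, the
#'   envelope chunk, and the updated stream.
#' @export
emg_stream <- function(n_channels, fs, hp_hz = 20, lp_hz = 2) {
  list(hp = iir_state(butter_coef(2, hp_hz, fs, "high"), n_channels),
       lp = iir_state(butter_coef(4, lp_hz, fs, "low"), n_channels),
       fs = fs)
}

#' @rdname emg_stream
#' @param stream a stream state from `emg_stream()`.
#' @param chunk channels x samples matrix of raw sEMG.
#' @export
emg_stream_step <- function(stream, chunk) {
  hp <- iir_apply(stream$hp, chunk)
  stream$hp <- hp$state
  lp <- iir_apply(stream$lp, abs(hp$y))
  stream$lp <- lp$state
  env <- lp$y
  env[env < 0] <- 0
  list(hp = hp$y, env = env, stream = stream)
}
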