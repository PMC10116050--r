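#' Calibration profile: rest and MVC envelope levels
#'
#' Per-channel mean envelope at rest and at maximum voluntary contraction
#' (MVC), plus the across-channel mean MVC envelope of the six forearm
#' channels used by the pattern-recognition proportional signal. All values
#' are in millivolts; normalization happens only inside the controllers.
#'
#' @param rest_env numeric vector, per-channel rest envelope (mV).
#' @param mvc_env numeric vector, per-channel MVC envelope (mV).
#' @param channel_roles role labels matching the envelope vectors.
#' @return An object of class `calibration_profile` with fields `rest_env`,
#'   `mvc_env`, `mvc_mean_env` and `channel_roles`.
#' @export
calibration_profile <- function(rest_env, mvc_env, channel_roles) {
  if (length(rest_env) != length(mvc_env) ||
      length(rest_env) != length(channel_roles))
    stop("rest_env, mvc_env and channel_roles must have equal length")
  fore <- forearm_channels(channel_roles)
  bad <- fore[!(mvc_env[fore] > rest_env[fore] & rest_env[fore] >= 0)]
  if (length(bad) > 0)
    stop(sprintf(
      "degenerate calibration: MVC envelope does not exceed rest on channel(s) %s",
      paste(sprintf("%d (%s)", bad, channel_roles[bad]), collapse = ", ")))
  structure(
    list(rest_env = as.numeric(rest_env), mvc_env = as.numeric(mvc_env),
         mvc_mean_env = mean(mvc_env[fore]),
         channel_roles = as.character(channel_roles)),
    class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("<calibration_profile>\n")
  df <- data.frame(role = x$channel_roles, rest_mV = round(x$rest_env, 4),
                   mvc_mV = round(x$mvc_env, 4))
  print(df, row.names = FALSE)
  cat(sprintf("  mean forearm MVC envelope: %.4f mV\n", x$mvc_mean_env))
  invisible(x)
}

#' Calibrate rest and MVC envelope levels from recordings
#'
#' The MVC level of each channel is the mean envelope over the contiguous
#' 3 s window of the MVC recording with the largest summed forearm envelope
#' (robust to ramp-up at the start of the contraction); the rest level is the
#' mean envelope over the last 3 s of the rest recording.
#'
#' @param mvc_recording raw [emg_recording()] of a maximal contraction,
#'   at least 3 s long.
#' @param rest_recording raw [emg_recording()] of relaxed muscles, at least
#'   3 s long.
#' @param window_s averaging window, default 3 s.
#' @param min_ratio smallest acceptable MVC/rest envelope ratio per forearm
#'   channel, default 1.5; a genuine contraction sits far above this, so a
#'   violation flags a degenerate calibration (e.g. the subject never
#'   contracted, or rest and MVC recordings were swapped or identical).
#' @return A [calibration_profile()]. Errors (naming the channel) if any
#'   forearm channel's MVC envelope does not exceed `min_ratio` times its
#'   rest envelope.
#' @export
calibrate <- function(mvc_recording, rest_recording, window_s = 3,
                      min_ratio = 1.5) {
  stopifnot(inherits(mvc_recording, "emg_recording"),
            inherits(rest_recording, "emg_recording"))
  if (!identical(mvc_recording$channel_roles, rest_recording$channel_roles))
    stop("MVC and rest recordings must share the same channel layout")
  if (duration(mvc_recording) < window_s || duration(rest_recording) < window_s)
    stop(sprintf("both recordings must be at least %g s long", window_s))

  mvc_env <- process_emg(mvc_recording)
  rest_env <- process_emg(rest_recording)
  fs <- mvc_recording$fs
  w <- round(window_s * fs)

  # rest: mean over the final window
  n_r <- ncol(rest_env$values)
  rest_level <- rowMeans(rest_env$values[, (n_r - w + 1):n_r, drop = FALSE])

  # MVC: contiguous window maximizing the summed forearm envelope
  fore <- forearm_channels(mvc_recording$channel_roles)
  tot <- colSums(mvc_env$values[fore, , drop = FALSE])
  cs <- cumsum(c(0, tot))
  starts <- seq_len(length(tot) - w + 1)
  best <- starts[which.max(cs[starts + w] - cs[starts])]
  mvc_level <- rowMeans(mvc_env$values[, best:(best + w - 1), drop = FALSE])

  weak <- fore[mvc_level[fore] < min_ratio * rest_level[fore]]
  if (length(weak) > 0)
    stop(sprintf(
      "degenerate calibration: MVC/rest envelope ratio below %g on channel(s) %s",
      min_ratio,
      paste(sprintf("%d (%s)", weak, mvc_recording$channel_roles[weak]),
            collapse = ", ")))
  calibration_profile(rest_level, mvc_level, mvc_recording$channel_roles)
}

#' Voluntary envelope: subtract the rest baseline
#'
#' Per-channel rest envelope subtraction with clamping at zero, the shared
#' first step of both controllers' normalization.
#'
#' @param env an [envelope_series()].
#' @param calib a [calibration_profile()] with matching channel count.
#' @return An [envelope_series()] of voluntary (rest-free) envelopes.
#' @export
voluntary <- function(env, calib) {
  stopifnot(inherits(env, "envelope_series"),
            inherits(calib, "calibration_profile"))
  if (nrow(env$values) != length(calib$rest_env))
    stop("channel count mismatch between envelope and calibration")
  v <- env$values - calib$rest_env
  v[v < 0] <- 0
  envelope_series(v, env$fs, env$channel_roles)
}

#' Serialize / load a calibration profile as JSON
#' @param calib a [calibration_profile()].
#' @param path JSON file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   the profile.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_profile(x$rest_env, x$mvc_env, x$channel_roles)
}
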