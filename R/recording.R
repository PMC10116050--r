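#' Multichannel raw sEMG recording
#'
#' Container for a block of raw surface EMG: a channels-by-samples matrix in
#' millivolts plus the sampling rate and the role of each channel. Six
#' forearm channels are expected (one on the flexor carpi ulnaris, one on the
#' extensor carpi ulnaris, four equidistant in between); an optional seventh
#' `trigger` channel carries the remote switch muscle used by the DMD
#' profile.
#'
#' @param samples numeric matrix, channels x samples, millivolts.
#' @param fs sampling rate in Hz. Recordings meant to mimic the reference
#'   acquisition chain use 1000 Hz; any rate above twice the 20 Hz high-pass
#'   cutoff is accepted.
#' @param channel_roles character vector, one of `"fcu"`, `"ecu"`,
#'   `"mid1"`..`"mid4"`, `"trigger"`, one per row of `samples`.
#' @param subject_profile_id free-text identifier of the subject profile the
#'   recording belongs to.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_roles,
                          subject_profile_id = "unknown") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("sEMG samples must be finite numeric values")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 40)
    stop("sampling rate must be a single value > 40 Hz")
  channel_roles <- as.character(channel_roles)
  if (length(channel_roles) != nrow(samples))
    stop("one channel role per row of `samples` is required")
  if (!(nrow(samples) %in% c(6L, 7L)))
    stop("expected 6 forearm channels, optionally plus one trigger channel")
  if (sum(channel_roles == "fcu") != 1L || sum(channel_roles == "ecu") != 1L)
    stop("exactly one 'fcu' and one 'ecu' channel are required")
  if (sum(channel_roles == "trigger") > 1L)
    stop("at most one trigger channel is allowed")
  structure(
    list(samples = samples, fs = fs, channel_roles = channel_roles,
         subject_profile_id = as.character(subject_profile_id)),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.2f s), profile '%s'\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$subject_profile_id))
  cat("  roles:", paste(x$channel_roles, collapse = ", "), "\n")
  invisible(x)
}

#' @export
duration.emg_recording <- function(x) ncol(x$samples) / x$fs

#' Recording duration in seconds
#' @param x an [emg_recording()] or [envelope_series()].
#' @return duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.envelope_series <- function(x) ncol(x$values) / x$fs

forearm_channels <- function(roles) which(roles != "trigger")
trigger_channel <- function(roles) {
  i <- which(roles == "trigger")
  if (length(i) == 0L) NULL else i
}
role_index <- function(roles, role) {
  i <- which(roles == role)
  if (length(i) != 1L) stop(sprintf("recording has no unique '%s' channel", role))
  i
}

#' Write / read a recording as delimited text plus a JSON sidecar
#'
#' The CSV holds one header line `time_s,ch1,...,chN` and one row per sample;
#' channel roles, sampling rate and profile id go to `<path>.json`. The
#' reader checks that the time column advances in uniform 1/fs steps.
#'
#' @param rec an [emg_recording()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an [emg_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- ncol(rec$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs,
                   t(rec$samples), check.names = FALSE)
  names(df) <- c("time_s", paste0("ch", seq_len(nrow(rec$samples))))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_roles = rec$channel_roles,
         subject_profile_id = rec$subject_profile_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  tt <- df$time_s
  if (length(tt) > 1) {
    dt <- diff(tt)
    if (any(abs(dt - 1 / meta$fs) > 1e-6 / meta$fs))
      stop("time column is not uniformly spaced at 1/fs")
  }
  emg_recording(t(as.matrix(df[, -1, drop = FALSE])), fs = meta$fs,
                channel_roles = meta$channel_roles,
                subject_profile_id = meta$subject_profile_id)
}
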