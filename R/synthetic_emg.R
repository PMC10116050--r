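#' Subject profile for synthetic sEMG generation
#'
#' Describes a virtual subject's muscles as seen by the 6-channel forearm
#' montage: per-channel gain at full activation, a noise floor, and a synergy
#' matrix giving each channel's activation weight for each motion class. The
#' `dmd` profile has markedly lower gains (dystrophic muscle produces
#' considerably lower-amplitude sEMG) and a higher crosstalk (less
#' independent muscle activation), plus a seventh `trigger` channel on a
#' remote muscle used for mode switching.
#'
#' @param cohort `"healthy"` or `"dmd"`.
#' @param channel_gain 6-vector, mV at full activation. Defaults: healthy
#'   around 1 mV; dmd scaled by `dmd_gain_ratio`.
#' @param noise_floor channel noise RMS in mV, default 0.01.
#' @param crosstalk fraction of mean off-class synergy mixed into every
#'   channel's activation; default 0.1 (healthy) / 0.5 (dmd).
#' @param trigger_gain trigger-channel gain in mV (dmd only), default 0.8.
#' @param carrier_band sEMG carrier band in Hz, default c(20, 450).
#' @param dmd_gain_ratio amplitude ratio dmd/healthy, default 0.35.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(cohort = c("healthy", "dmd"),
                            channel_gain = NULL,
                            noise_floor = 0.01,
                            crosstalk = NULL,
                            trigger_gain = 0.8,
                            carrier_band = c(20, 450),
                            dmd_gain_ratio = 0.35) {
  cohort <- match.arg(cohort)
  base_gain <- c(1.2, 0.9, 1.0, 1.1, 0.95, 1.3)
  if (is.null(channel_gain))
    channel_gain <- if (cohort == "dmd") dmd_gain_ratio * base_gain else base_gain
  if (is.null(crosstalk)) crosstalk <- if (cohort == "dmd") 0.5 else 0.1
  stopifnot(length(channel_gain) == 6, all(channel_gain > 0),
            crosstalk >= 0, crosstalk < 1, noise_floor > 0)
  roles <- c("fcu", "mid1", "mid2", "mid3", "mid4", "ecu")
  # rows: fcu, mid1..mid4, ecu; columns: motion classes
  synergy <- cbind(
    HAND_OPEN       = c(0.05, 0.10, 0.30, 0.90, 0.60, 0.30),
    HAND_CLOSE      = c(0.35, 0.90, 0.60, 0.20, 0.10, 0.05),
    WRIST_FLEXION   = c(1.00, 0.50, 0.20, 0.10, 0.05, 0.05),
    WRIST_EXTENSION = c(0.05, 0.05, 0.10, 0.20, 0.50, 1.00),
    NO_MOTION       = c(0, 0, 0, 0, 0, 0))
  rownames(synergy) <- roles
  has_trigger <- cohort == "dmd"
  structure(
    list(cohort = cohort, id = paste0(cohort, "_default"),
         channel_roles = if (has_trigger) c(roles, "trigger") else roles,
         channel_gain = channel_gain, noise_floor = noise_floor,
         synergy = synergy, crosstalk = crosstalk,
         trigger_gain = if (has_trigger) trigger_gain else NA_real_,
         carrier_band = carrier_band),
    class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> cohort '%s', %d channels, crosstalk %.2f, mean gain %.3f mV\n",
              x$cohort, length(x$channel_roles), x$crosstalk,
              mean(x$channel_gain)))
  invisible(x)
}

#' Serialize / load a subject profile as JSON
#' @param profile a [subject_profile()].
#' @param path JSON file path.
#' @export
write_profile <- function(profile, path) {
  x <- unclass(profile)
  x$synergy <- as.data.frame(x$synergy)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- subject_profile(x$cohort, channel_gain = x$channel_gain,
                       noise_floor = x$noise_floor, crosstalk = x$crosstalk,
                       trigger_gain = if (is.null(x$trigger_gain)) 0.8 else x$trigger_gain,
                       carrier_band = x$carrier_band)
  p$synergy <- as.matrix(x$synergy)
  rownames(p$synergy) <- p$channel_roles[p$channel_roles != "trigger"]
  p$id <- x$id
  p
}

# Per-channel target activation for a command. `class` may be a motion
# class, "CO_CONTRACT" (flexion + extension synergies summed, capped at 1)
# or "MVC" (every muscle at its maximum weight).
command_activation <- function(profile, class, intensity, trigger = 0) {
  syn <- profile$synergy
  act <- switch(class,
    MVC = apply(syn[, setdiff(colnames(syn), "NO_MOTION")], 1, max),
    CO_CONTRACT = pmin(syn[, "WRIST_FLEXION"] + syn[, "WRIST_EXTENSION"], 1),
    NO_MOTION = rep(0, nrow(syn)),
    {
      k <- syn[, class]
      others <- setdiff(colnames(syn), c(class, "NO_MOTION"))
      pmin(k + profile$crosstalk * rowMeans(syn[, others, drop = FALSE]), 1)
    })
  out <- act * intensity
  if ("trigger" %in% profile$channel_roles) out <- c(out, trigger)
  out
}

#' Activation trace from a command sequence
#'
#' Turns a timed list of motion commands into a per-channel activation time
#' series in \[0, 1\]: each command holds until the next one; the commanded
#' activation pattern comes from the profile's synergy matrix plus crosstalk;
#' a 100 ms first-order lag emulates electromechanical smoothing.
#'
#' @param commands data.frame with columns `t` (s, ascending, first at 0),
#'   `class` (motion class, `"CO_CONTRACT"` or `"MVC"`), `intensity` in
#'   \[0, 1\] and optionally `trigger` in \[0, 1\].
#' @param profile a [subject_profile()].
#' @param fs sampling rate, Hz.
#' @param duration_s total trace length, seconds.
#' @param lag_s activation lag time constant, default 0.1 s.
#' @param init `"rest"` starts from zero activation; `"steady"` starts at the
#'   first command's level (a contraction already under way).
#' @return channels x samples activation matrix with attributes `fs` and
#'   `commands`.
#' @export
activation_from_intent <- function(commands, profile, fs, duration_s,
                                   lag_s = 0.1, init = c("rest", "steady")) {
  init <- match.arg(init)
  stopifnot(all(commands$intensity >= 0), all(commands$intensity <= 1),
            commands$t[1] <= 0 || nrow(commands) == 0)
  if (is.null(commands$trigger)) commands$trigger <- 0
  n <- round(duration_s * fs)
  nch <- length(profile$channel_roles)
  cmd <- matrix(0, nch, n)
  times <- (seq_len(n) - 1) / fs
  idx <- findInterval(times, commands$t)
  idx[idx < 1] <- 1L
  for (j in unique(idx)) {
    a <- command_activation(profile, as.character(commands$class[j]),
                            commands$intensity[j], commands$trigger[j])
    cmd[, idx == j] <- a
  }
  decay <- exp(-1 / (fs * lag_s))
  z0 <- if (init == "steady") cmd[, 1] else rep(0, nch)
  # one-pole lag y[t] = decay*y[t-1] + (1-decay)*cmd[t], state seeded at z0
  out <- .iir_chunk_cpp(1 - decay, c(1, -decay), cmd,
                        matrix(z0 * decay, nch, 1))$y
  structure(out, fs = fs, commands = commands)
}

# Streaming sEMG renderer: carries the carrier band-pass state and the
# activation lag state so the closed-loop simulator can draw one chunk at a
# time. Draws from the current R RNG stream.
emg_source <- function(profile, fs, lag_s = 0.1) {
  nch <- length(profile$channel_roles)
  gains <- c(profile$channel_gain,
             if ("trigger" %in% profile$channel_roles) profile$trigger_gain)
  list(profile = profile, fs = fs, nch = nch, gains = gains,
       bp = iir_state(butter_coef(2, profile$carrier_band, fs, "pass"), nch),
       act = rep(0, nch), lag_decay = exp(-1 / (fs * lag_s)))
}

# Advance the source by n samples with a constant commanded activation
# vector; returns list(emg = chunk, src = updated source).
emg_source_step <- function(src, cmd_act, n) {
  d <- src$lag_decay
  # exact one-pole lag toward cmd_act across the chunk
  steps <- d ^ seq_len(n)
  act <- outer(src$act - cmd_act, steps) + cmd_act
  src$act <- act[, n]
  bp <- iir_apply(src$bp, matrix(stats::rnorm(src$nch * n), src$nch, n))
  src$bp <- bp$state
  emg <- bp$y * (src$gains * act) +
    src$profile$noise_floor * matrix(stats::rnorm(src$nch * n), src$nch, n)
  list(emg = emg, src = src)
}

#' Render synthetic raw sEMG from an activation trace
#'
#' Amplitude-modulated band-limited noise: per channel, zero-mean unit
#' variance Gaussian noise band-passed to the carrier band (default
#' 20-450 Hz), multiplied pointwise by channel gain x activation, plus an
#' independent noise floor. Seeded and fully reproducible.
#'
#' @param trace activation matrix from [activation_from_intent()].
#' @param profile a [subject_profile()].
#' @param fs sampling rate, Hz (default 1000).
#' @param seed RNG seed.
#' @return An [emg_recording()].
#' @export
render_emg <- function(trace, profile, fs = 1000, seed = 1L) {
  nch <- length(profile$channel_roles)
  stopifnot(nrow(trace) == nch)
  n <- ncol(trace)
  gains <- c(profile$channel_gain,
             if ("trigger" %in% profile$channel_roles) profile$trigger_gain)
  samples <- withr::with_seed(seed, {
    st <- iir_state(butter_coef(2, profile$carrier_band, fs, "pass"), nch)
    carrier <- iir_apply(st, matrix(stats::rnorm(nch * n), nch, n))$y
    carrier * (gains * trace) +
      profile$noise_floor * matrix(stats::rnorm(nch * n), nch, n)
  })
  emg_recording(samples, fs, profile$channel_roles, profile$id)
}

#' Generate a full calibration and training kit
#'
#' Everything needed to set up both controllers for a virtual subject: a
#' rest recording (relaxed muscles), an MVC recording (maximal co-activation
#' of all muscles, trigger included for the DMD profile), and five 2 s
#' repetitions of each motion class at a comfortable 0.7 intensity for
#' classifier training. Training and MVC recordings start mid-contraction
#' (steady activation), as a researcher would record them.
#'
#' @param profile a [subject_profile()].
#' @param seed RNG seed; sub-recordings use seeds derived from it.
#' @param fs sampling rate, Hz.
#' @param rest_s,mvc_s rest/MVC durations, >= 4 s by default.
#' @param reps,rep_s training repetitions per class and their duration.
#' @param train_intensity training contraction intensity per repetition,
#'   recycled over `reps`. The default spreads the repetitions over
#'   0.5-0.9: "comfortable" contractions naturally vary in effort from
#'   repetition to repetition, and that spread is what makes the trained
#'   classifier robust to the intensity range met online.
#' @return `list(rest = , mvc = , training = )` where `training` is a named
#'   per-class list of [emg_recording()]s.
#' @export
make_calibration_kit <- function(profile, seed = 1L, fs = 1000,
                                 rest_s = 4, mvc_s = 4,
                                 reps = 5, rep_s = 2,
                                 train_intensity = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  cmd1 <- function(class, intensity, trigger = 0)
    data.frame(t = 0, class = class, intensity = intensity, trigger = trigger)
  rest <- render_emg(
    activation_from_intent(cmd1("NO_MOTION", 0), profile, fs, rest_s),
    profile, fs, seed = seed * 1000L + 1L)
  mvc <- render_emg(
    activation_from_intent(cmd1("MVC", 1, trigger = 1), profile, fs, mvc_s,
                           init = "steady"),
    profile, fs, seed = seed * 1000L + 2L)
  training <- list()
  rep_int <- rep_len(train_intensity, reps)
  i <- 3L
  for (cls in MOTION_CLASSES) {
    training[[cls]] <- lapply(seq_len(reps), function(r) {
      intensity <- if (cls == "NO_MOTION") 0 else rep_int[r]
      render_emg(
        activation_from_intent(cmd1(cls, intensity), profile, fs, rep_s,
                               init = "steady"),
        profile, fs, seed = seed * 1000L + i + r - 1L)
    })
    i <- i + reps
  }
  list(rest = rest, mvc = mvc, training = training)
}
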