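#' Direct-control configuration
#'
#' Parameters of the antagonist-pair proportional controller. One wrist
#' muscle pair (ECU extensor, FCU flexor) drives whichever cursor axis is
#' active; the active axis is toggled by a co-contraction of the pair
#' (healthy use) or by a separate trigger muscle (DMD use).
#'
#' @param mapping a [motion_mapping()].
#' @param cocontraction_threshold MVC fraction both antagonists must exceed
#'   to register a switch; default 0.50. The level is "comfortable" in the
#'   sense of the original protocol: reliably reachable with a firm
#'   deliberate co-contraction, yet above the ~0.45 antagonist crossover
#'   that occurs transiently when the user reverses direction, which would
#'   otherwise fire false switches.
#' @param switch_refractory_s minimum time between switches, default 0.5 s.
#' @param trigger_threshold MVC fraction of the trigger channel for
#'   trigger-based switching, default 0.5.
#' @param deadband MVC fraction below which the output is zeroed (suppresses
#'   rest-noise drift), default 0.02, must be in \[0, 0.2\].
#' @param switch_source `"cocontraction"` or `"trigger"`.
#' @return An object of class `dc_config`.
#' @export
dc_config <- function(mapping = motion_mapping("right_handed"),
                      cocontraction_threshold = 0.50,
                      switch_refractory_s = 0.5,
                      trigger_threshold = 0.5,
                      deadband = 0.02,
                      switch_source = c("cocontraction", "trigger")) {
  switch_source <- match.arg(switch_source)
  stopifnot(inherits(mapping, "motion_mapping"),
            cocontraction_threshold > 0, cocontraction_threshold < 1,
            switch_refractory_s > 0,
            deadband >= 0, deadband <= 0.2)
  structure(list(mapping = mapping,
                 cocontraction_threshold = cocontraction_threshold,
                 switch_refractory_s = switch_refractory_s,
                 trigger_threshold = trigger_threshold,
                 deadband = deadband,
                 switch_source = switch_source),
            class = "dc_config")
}

#' Direct-control mode-switch state
#'
#' @param active_axis `"x"` or `"y"`; controllers start on x.
#' @param last_switch_time time of the last toggle, seconds.
#' @return An object of class `dc_state`.
#' @export
dc_state <- function(active_axis = "x", last_switch_time = -Inf) {
  stopifnot(active_axis %in% c("x", "y"))
  structure(list(active_axis = active_axis,
                 last_switch_time = last_switch_time,
                 switching = FALSE, armed = TRUE, n_switches = 0L),
            class = "dc_state")
}

# Normalized activation of one channel: (envelope - rest)/MVC in [0, 1].
norm_activation <- function(env, rest, mvc) {
  pmin(pmax((env - rest) / mvc, 0), 1)
}

#' Normalized antagonist control signals
#'
#' U_e and U_f: each muscle's envelope with its rest baseline removed,
#' divided by its MVC envelope, clamped to \[0, 1\].
#'
#' @param env_e,env_f extensor (ECU) and flexor (FCU) envelope samples, mV.
#' @param calib a [calibration_profile()].
#' @return `list(U_e = , U_f = )`.
#' @export
dc_activations <- function(env_e, env_f, calib) {
  e <- role_index(calib$channel_roles, "ecu")
  f <- role_index(calib$channel_roles, "fcu")
  list(U_e = norm_activation(env_e, calib$rest_env[e], calib$mvc_env[e]),
       U_f = norm_activation(env_f, calib$rest_env[f], calib$mvc_env[f]))
}

#' Direct-control proportional signal
#'
#' The signed antagonist difference U = U_e - U_f in \[-1, 1\]: extensor
#' activation minus flexor activation, each rest-subtracted and
#' MVC-normalized. Values inside the deadband are zeroed.
#'
#' @inheritParams dc_activations
#' @param cfg a [dc_config()] (used for the deadband).
#' @return scalar in \[-1, 1\].
#' @export
dc_signal <- function(env_e, env_f, calib, cfg = dc_config()) {
  a <- dc_activations(env_e, env_f, calib)
  u <- a$U_e - a$U_f
  u[abs(u) < cfg$deadband] <- 0
  u
}

#' Detect a mode switch between cursor axes
#'
#' Co-contraction mode: the active axis toggles when both antagonists exceed
#' the co-contraction threshold and the refractory period has elapsed.
#' Trigger mode (DMD variant): the same logic on the normalized envelope of
#' the remote trigger muscle. The detector is edge-triggered: after a toggle
#' it re-arms only once the switch signal has dropped back below threshold,
#' so one sustained co-contraction produces exactly one switch no matter how
#' long it is held. The state's `switching` flag is set on any tick where the
#' switch condition holds (toggled, blocked or un-armed), so the caller can
#' zero the control output during the event.
#'
#' @param U_e,U_f normalized antagonist activations.
#' @param trigger_env_norm normalized trigger-channel envelope, or `NULL`
#'   when absent.
#' @param t current time, seconds.
#' @param cfg a [dc_config()].
#' @param state a [dc_state()].
#' @return the updated [dc_state()].
#' @export
detect_switch <- function(U_e, U_f, trigger_env_norm, t, cfg, state) {
  cond <- if (cfg$switch_source == "cocontraction") {
    min(U_e, U_f) >= cfg$cocontraction_threshold
  } else {
    if (is.null(trigger_env_norm))
      stop("trigger switching configured but no trigger channel present")
    trigger_env_norm >= cfg$trigger_threshold
  }
  state$switching <- isTRUE(cond)
  if (!isTRUE(cond)) {
    state$armed <- TRUE
  } else if (state$armed &&
             t - state$last_switch_time >= cfg$switch_refractory_s) {
    state$active_axis <- if (state$active_axis == "x") "y" else "x"
    state$last_switch_time <- t
    state$n_switches <- state$n_switches + 1L
    state$armed <- FALSE
  }
  state
}

#' Direct-control output vector
#'
#' Routes the signed proportional signal onto the active axis with the
#' preset's sign convention (wrist extension drives `dc_ext_sign` per axis);
#' the other axis is exactly zero. During a detected co-contraction /
#' trigger event the output is zeroed to avoid drift while switching.
#'
#' @param U scalar control signal in \[-1, 1\].
#' @param state a [dc_state()].
#' @param mapping a [motion_mapping()].
#' @return numeric 2-vector (x, y), at most one nonzero component.
#' @export
dc_output <- function(U, state, mapping) {
  stopifnot(abs(U) <= 1 + 1e-12)
  out <- c(0, 0)
  if (isTRUE(state$switching)) return(out)
  axis <- if (state$active_axis == "x") 1L else 2L
  out[axis] <- U * mapping$dc_ext_sign[axis]
  out
}
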