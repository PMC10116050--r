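#' Virtual user (intent policy)
#'
#' A stand-in for the human in the loop. Every 125 ms the user looks at the
#' cursor, predicts where it would coast to if they relaxed (position +
#' velocity x admittance time constant — experienced users internalize the
#' virtual dynamics) and issues the motion command that reduces the dominant
#' remaining error, with intensity proportional to that error and capped at
#' `activation_level`. They relax once the predicted stop point is within
#' `stop_deadband` of the target.
#'
#' Under direct control the user works one axis at a time: when the active
#' axis is done but the other still has error, they hold a co-contraction
#' (or press the trigger muscle) until the mode actually switches, then
#' pause `switch_settle_s` to re-orient before moving again — mode switching
#' is deliberately not free, mirroring how novice users handle it.
#'
#' Under pattern recognition the user never commands below
#' `pr_min_intensity`: weaker contractions would not be recognized by a
#' classifier trained on firm ones, so fine corrections are made as brief,
#' firm pulses (a characteristic limitation of PR control; direct control
#' has no such floor and can grade arbitrarily small corrections).
#'
#' Decisions take effect after a reaction delay and are corrupted with
#' probability `class_error_rate` (a wrong motion class is held for one
#' decision interval).
#'
#' @param profile a [subject_profile()].
#' @param reaction_delay_s visuomotor reaction delay, default 0.25 s.
#' @param activation_level maximal commanded intensity (MVC fraction) when
#'   far from the target, default 0.9 ("as fast as possible").
#' @param class_error_rate probability that a motion decision picks a wrong
#'   class, default 0.15 (novice-level online decoding/decision error); must
#'   be < 0.5. Under DC, errors that land on a hand class produce almost no
#'   antagonist imbalance, so DC absorbs most of them — an emergent
#'   asymmetry, not a separate parameter.
#' @param stop_deadband workspace distance below which the user relaxes,
#'   default 0.05 (inside the default target radius 0.08).
#' @param switch_settle_s pause after a completed mode switch, default 0.5 s.
#' @param ramp_dist error distance over which commanded intensity ramps
#'   linearly up to `activation_level`, default 1.2 workspace units. This
#'   sets the user's closed-loop gain: it must be gentle enough that the
#'   user-plus-delay loop does not oscillate, and it makes the approach time
#'   constant inversely proportional to each controller's proportional gain
#'   (so the weaker PR signal yields a slower approach, an emergent
#'   difference, not a per-method parameter).
#' @param axis_tol per-axis error below which an axis counts as done for DC
#'   axis scheduling, default 0.04.
#' @param min_intensity smallest nonzero commanded intensity under direct
#'   control, default 0.12 (above the controller deadband).
#' @param pr_min_intensity smallest commanded intensity under pattern
#'   recognition, default 0.30 (firm enough to classify).
#' @param co_intensity co-contraction burst intensity, default 0.7.
#' @return An object of class `virtual_user`.
#' @export
virtual_user <- function(profile,
                         reaction_delay_s = 0.25,
                         activation_level = 0.9,
                         class_error_rate = 0.15,
                         stop_deadband = 0.05,
                         switch_settle_s = 0.5,
                         ramp_dist = 1.2,
                         axis_tol = 0.04,
                         min_intensity = 0.12,
                         pr_min_intensity = 0.30,
                         co_intensity = 0.7) {
  stopifnot(inherits(profile, "subject_profile"),
            activation_level > 0, activation_level <= 1,
            class_error_rate >= 0, class_error_rate < 0.5,
            stop_deadband > 0, reaction_delay_s >= 0)
  structure(list(profile = profile,
                 reaction_delay_s = reaction_delay_s,
                 activation_level = activation_level,
                 class_error_rate = class_error_rate,
                 stop_deadband = stop_deadband,
                 switch_settle_s = switch_settle_s,
                 ramp_dist = ramp_dist, axis_tol = axis_tol,
                 min_intensity = min_intensity,
                 pr_min_intensity = pr_min_intensity,
                 co_intensity = co_intensity),
            class = "virtual_user")
}

# Fresh per-trial policy memory for user_intent().
user_policy <- function() list(phase = "move", settle_until = -Inf)

#' One virtual-user decision
#'
#' Computes the next motion command from the current cursor state and the
#' user's policy memory (`policy`, from the previous call; pass
#' `user_policy()` initially).
#'
#' @param user a [virtual_user()].
#' @param cursor current [cursor_state()].
#' @param target `list(center, radius)` of the active target.
#' @param method `"dc"` or `"pr"`.
#' @param mapping the active [motion_mapping()].
#' @param policy policy memory from the previous decision.
#' @param dc_axis currently active DC axis, `"x"` or `"y"`.
#' @param tau admittance time constant A/B, seconds.
#' @param use_trigger switch via the trigger muscle instead of
#'   co-contraction.
#' @param t decision time, seconds.
#' @return `list(intent = list(class, intensity, trigger), policy = )`.
#' @export
user_intent <- function(user, cursor, target, method, mapping,
                        policy = user_policy(), dc_axis = "x", tau = 0,
                        use_trigger = FALSE, t = 0) {
  p_stop <- cursor$pos + cursor$vel * tau
  e <- target$center - p_stop
  relax <- list(class = "NO_MOTION", intensity = 0, trigger = 0)
  done <- sqrt(sum(e^2)) <= user$stop_deadband

  intensity_for <- function(err, floor_int)
    max(floor_int,
        min(user$activation_level,
            user$activation_level * abs(err) / user$ramp_dist))

  if (method == "pr") {
    if (done) return(list(intent = relax, policy = policy))
    axis <- which.max(abs(e))
    cls <- pr_class_for_direction(mapping, axis, sign(e[axis]))
    return(list(intent = list(class = cls,
                              intensity = intensity_for(e[axis],
                                                        user$pr_min_intensity),
                              trigger = 0),
                policy = policy))
  }

  # --- direct control: move / switch / settle state machine
  axis <- if (dc_axis == "x") 1L else 2L
  other <- 3L - axis
  if (policy$phase == "switch") {
    if (dc_axis != policy$switch_from) {         # mode change observed
      policy$phase <- "settle"
      policy$settle_until <- t + user$switch_settle_s
      return(list(intent = relax, policy = policy))
    }
    if (abs(e[other]) <= user$axis_tol) {        # no longer worth switching
      policy$phase <- "move"
      return(list(intent = relax, policy = policy))
    }
    intent <- if (use_trigger)
      list(class = "NO_MOTION", intensity = 0, trigger = 1)
    else
      list(class = "CO_CONTRACT", intensity = user$co_intensity, trigger = 0)
    return(list(intent = intent, policy = policy))
  }
  if (policy$phase == "settle") {
    if (t < policy$settle_until)
      return(list(intent = relax, policy = policy))
    policy$phase <- "move"
  }
  if (done) return(list(intent = relax, policy = policy))
  if (abs(e[axis]) <= user$axis_tol) {
    if (abs(e[other]) > user$axis_tol) {
      policy$phase <- "switch"
      policy$switch_from <- dc_axis
      intent <- if (use_trigger)
        list(class = "NO_MOTION", intensity = 0, trigger = 1)
      else
        list(class = "CO_CONTRACT", intensity = user$co_intensity,
             trigger = 0)
      return(list(intent = intent, policy = policy))
    }
    return(list(intent = relax, policy = policy))
  }
  # extension drives dc_ext_sign[axis]; flexion the opposite
  cls <- if (sign(e[axis]) == mapping$dc_ext_sign[axis])
    "WRIST_EXTENSION" else "WRIST_FLEXION"
  list(intent = list(class = cls,
                     intensity = intensity_for(e[axis], user$min_intensity),
                     trigger = 0),
       policy = policy)
}

# Corrupt a motion decision with probability user$class_error_rate: the
# class is replaced by a uniformly drawn different motion class. Switch
# bursts and relaxation are not corrupted.
corrupt_intent <- function(user, intent) {
  if (user$class_error_rate <= 0) return(intent)
  if (intent$class %in% c("NO_MOTION", "CO_CONTRACT", "MVC")) return(intent)
  if (stats::runif(1) < user$class_error_rate) {
    pool <- setdiff(MOTION_CLASSES, c(intent$class, "NO_MOTION"))
    intent$class <- sample(pool, 1)
  }
  intent
}
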