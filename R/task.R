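#' Target layout for the reaching task
#'
#' Eight circular targets in the normalized workspace: targets 1-4 lie on the
#' axes (1-DOF trials), targets 5-8 on the diagonals (2-DOF trials). The
#' reference figure gives no coordinates, so the defaults put all targets at
#' the same component distance 0.55 with radius 0.08; both are configurable.
#'
#' @param distance axis distance of the target centers, default 0.55.
#' @param radius target radius, workspace units, default 0.08; must be > 0.
#' @param centers optional 8 x 2 matrix of custom centers (rows = targets).
#' @return An object of class `target_layout`: list of targets, each
#'   `list(id, center, radius)`, plus a `dof_of` integer vector.
#' @export
make_layout <- function(distance = 0.55, radius = 0.08, centers = NULL) {
  if (radius <= 0) stop("target radius must be > 0 (a point target cannot hold a dwell)")
  if (is.null(centers)) {
    d <- distance
    centers <- rbind(c(d, 0), c(-d, 0), c(0, d), c(0, -d),
                     c(d, d), c(-d, d), c(-d, -d), c(d, -d))
  }
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 8, ncol(centers) == 2,
            all(abs(centers) <= 1))
  dd <- as.matrix(stats::dist(centers))
  diag(dd) <- Inf
  if (any(dd < 2 * radius)) stop("targets overlap")
  targets <- lapply(1:8, function(i)
    list(id = i, center = as.numeric(centers[i, ]), radius = radius))
  structure(list(targets = targets,
                 dof_of = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)),
            class = "target_layout")
}

#' @export
print.target_layout <- function(x, ...) {
  cat("<target_layout>\n")
  for (tg in x$targets)
    cat(sprintf("  target %d (%d-DOF): center (%+.2f, %+.2f), radius %.2f\n",
                tg$id, x$dof_of[tg$id], tg$center[1], tg$center[2], tg$radius))
  invisible(x)
}

#' Serialize / load a target layout as JSON
#' @param layout a [make_layout()] layout.
#' @param path JSON file path.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(
    list(centers = t(vapply(layout$targets, `[[`, numeric(2), "center")),
         radius = layout$targets[[1]]$radius),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_layout(radius = x$radius, centers = x$centers)
}

#' Controller bundles
#'
#' Package a calibrated controller for the closed-loop simulator:
#' `dc_controller()` wraps the antagonist-pair direct controller,
#' `pr_controller()` the trained pattern-recognition controller.
#'
#' @param calib a [calibration_profile()].
#' @param cfg a [dc_config()] / [pr_config()].
#' @param model a trained [pr_model][pr_train()] (PR only).
#' @return An object of class `dc_controller` / `pr_controller`.
#' @export
dc_controller <- function(calib, cfg = dc_config()) {
  stopifnot(inherits(calib, "calibration_profile"), inherits(cfg, "dc_config"))
  structure(list(method = "dc", calib = calib, cfg = cfg),
            class = "dc_controller")
}

#' @rdname dc_controller
#' @export
pr_controller <- function(calib, model, cfg = pr_config()) {
  stopifnot(inherits(calib, "calibration_profile"), inherits(model, "pr_model"),
            inherits(cfg, "pr_config"))
  structure(list(method = "pr", calib = calib, model = model, cfg = cfg),
            class = "pr_controller")
}

#' Run one closed-loop reaching trial
#'
#' Simulates the full loop at the raw sEMG rate: virtual-user intent (125 ms
#' decision cadence, reaction-delayed) -> synthetic sEMG -> causal envelope
#' pipeline -> controller -> admittance cursor dynamics -> dwell bookkeeping.
#' The trial succeeds when the cursor stays inside the target circle for a
#' continuous `dwell_s`; the reaching time is the start of that dwell. The
#' dwell clock resets whenever the cursor leaves the target.
#'
#' @param controller a [dc_controller()] or [pr_controller()].
#' @param user a [virtual_user()].
#' @param layout a [make_layout()] layout.
#' @param target_id target to reach, 1-8.
#' @param params scaled [admittance_params()] of the cursor.
#' @param seed RNG seed for this trial.
#' @param dt control tick, seconds, default 0.01.
#' @param fs raw sEMG rate, Hz, default 1000; `fs * dt` must be an integer
#'   number of samples.
#' @param dwell_s required continuous in-target time, default 2 s.
#' @param timeout_s trial abandoned after this long, default 30 s.
#' @param dc_init a [dc_state()] carried over from the previous trial (the
#'   active DC axis persists across trials within a session).
#' @param store_timeseries keep the per-tick cursor/control trace.
#' @return `list(result = , dc_state = )`: `result` is a one-row data.frame
#'   (target_id, success, reaching_time_s, completed_at_s, n_switches, seed)
#'   with the optional timeseries as an attribute; `dc_state` the final
#'   mode-switch state.
#' @export
run_trial <- function(controller, user, layout, target_id, params,
                      seed = 1L, dt = 0.01, fs = 1000,
                      dwell_s = 2, timeout_s = 30,
                      dc_init = NULL, store_timeseries = FALSE) {
  target <- layout$targets[[target_id]]
  spt <- fs * dt
  if (abs(spt - round(spt)) > 1e-9) stop("fs * dt must be an integer sample count")
  spt <- as.integer(round(spt))
  method <- controller$method
  calib <- controller$calib
  profile <- user$profile
  stopifnot(identical(calib$channel_roles, profile$channel_roles))
  mapping <- controller$cfg$mapping
  tau <- params$A / params$B
  use_trigger <- method == "dc" && controller$cfg$switch_source == "trigger"

  nch <- length(profile$channel_roles)
  fore <- forearm_channels(profile$channel_roles)
  trig <- trigger_channel(profile$channel_roles)
  i_e <- role_index(profile$channel_roles, "ecu")
  i_f <- role_index(profile$channel_roles, "fcu")

  decision_dt <- 0.125
  win <- round(0.25 * fs)

  res <- withr::with_seed(seed, {
    src <- emg_source(profile, fs)
    stream <- emg_stream(nch, fs)
    cursor <- cursor_state(c(0, 0), c(0, 0), 0)
    dstate <- if (is.null(dc_init)) dc_state() else dc_init
    dstate$last_switch_time <- -Inf   # trial clocks restart at 0
    dstate$armed <- TRUE
    n0_switch <- dstate$n_switches
    cls_now <- "NO_MOTION"
    ring <- matrix(0, length(fore), win)  # last 250 ms of HP raw sEMG
    applied <- list(class = "NO_MOTION", intensity = 0, trigger = 0)
    pending <- list()                     # reaction-delay queue
    next_decision <- 0
    next_cls <- 0.25
    policy <- user_policy()
    inside_since <- NA_real_
    success <- FALSE
    reaching <- NA_real_
    completed <- NA_real_
    nticks <- ceiling(timeout_s / dt)
    trace <- if (store_timeseries)
      matrix(NA_real_, nticks, 7,
             dimnames = list(NULL, c("t", "x", "y", "ux", "uy", "U", "class")))
    t <- 0
    for (k in seq_len(nticks)) {
      # --- user decision at 8 Hz, applied after the reaction delay
      if (t >= next_decision - 1e-9) {
        dec <- user_intent(user, cursor, target, method, mapping,
                           policy = policy, dc_axis = dstate$active_axis,
                           tau = tau, use_trigger = use_trigger, t = t)
        policy <- dec$policy
        intent <- corrupt_intent(user, dec$intent)
        pending[[length(pending) + 1L]] <-
          c(intent, apply_at = t + user$reaction_delay_s)
        next_decision <- next_decision + decision_dt
      }
      while (length(pending) > 0 && pending[[1]]$apply_at <= t + 1e-9) {
        applied <- pending[[1]]
        pending <- pending[-1]
      }

      # --- synthesize and process one tick of raw sEMG
      cmd_act <- command_activation(profile, applied$class,
                                    applied$intensity, applied$trigger)
      step <- emg_source_step(src, cmd_act, spt)
      src <- step$src
      flt <- emg_stream_step(stream, step$emg)
      stream <- flt$stream
      env_now <- flt$env[, spt]
      ring <- cbind(ring[, -seq_len(spt), drop = FALSE], flt$hp[fore, , drop = FALSE])

      t <- k * dt

      # --- controller
      if (method == "dc") {
        a <- dc_activations(env_now[i_e], env_now[i_f], calib)
        trig_norm <- if (!is.null(trig))
          norm_activation(env_now[trig], calib$rest_env[trig],
                          calib$mvc_env[trig]) else NULL
        dstate <- detect_switch(a$U_e, a$U_f, trig_norm, t,
                                controller$cfg, dstate)
        U <- a$U_e - a$U_f
        if (abs(U) < controller$cfg$deadband) U <- 0
        u <- dc_output(U, dstate, mapping)
      } else {
        if (t >= next_cls - 1e-9) {
          feats <- extract_features(ring, controller$cfg$zc_ssc_deadband)
          cls_now <- pr_classify(controller$model, feats)
          next_cls <- next_cls + decision_dt
        }
        U <- pr_proportional(env_now, calib)
        u <- pr_output(cls_now, U, mapping)
      }

      # --- admittance dynamics and dwell bookkeeping
      cursor <- admittance_step(cursor, force_from_control(u), params, dt)
      if (store_timeseries)
        trace[k, ] <- c(t, cursor$pos, u, U,
                        match(cls_now, MOTION_CLASSES))
      inside <- sqrt(sum((cursor$pos - target$center)^2)) <= target$radius
      if (inside) {
        if (is.na(inside_since)) inside_since <- t
        if (t - inside_since >= dwell_s) {
          success <- TRUE
          reaching <- inside_since
          completed <- t
          break
        }
      } else inside_since <- NA_real_
    }
    result <- data.frame(target_id = target_id, success = success,
                         reaching_time_s = reaching,
                         completed_at_s = completed,
                         n_switches = dstate$n_switches - n0_switch,
                         seed = seed)
    if (store_timeseries)
      attr(result, "timeseries") <- trace[seq_len(k), , drop = FALSE]
    list(result = result, dc_state = dstate)
  })
  res
}

#' Apply the dwell rule to a cursor trace
#'
#' Given sample times and in-target flags, finds the first uninterrupted
#' in-target run of at least `dwell_s`: the trial succeeds, the reaching
#' time is the start of that run, and the completion time is `reaching +
#' dwell_s`. The dwell clock resets on any exit. Useful for scripted traces
#' and for auditing simulated trials.
#'
#' @param times ascending sample times, seconds.
#' @param inside logical vector, cursor inside the target at each time.
#' @param dwell_s required continuous in-target duration, default 2 s.
#' @return `list(success = , reaching_time_s = , completed_at_s = )`.
#' @export
reaching_outcome <- function(times, inside, dwell_s = 2) {
  stopifnot(length(times) == length(inside), !is.unsorted(times))
  start <- NA_real_
  for (i in seq_along(times)) {
    if (inside[i]) {
      if (is.na(start)) start <- times[i]
      if (times[i] - start >= dwell_s)
        return(list(success = TRUE, reaching_time_s = start,
                    completed_at_s = start + dwell_s))
    } else start <- NA_real_
  }
  list(success = FALSE, reaching_time_s = NA_real_, completed_at_s = NA_real_)
}

#' Session specification
#'
#' One task condition of the reaching protocol: a method (DC or PR), a
#' cohort, and a DOF condition. Healthy sessions use targets 1-4 (1-DOF) or
#' 5-8 (2-DOF) with ten trials per target, the first two discarded; the
#' reduced DMD protocol uses targets 1, 2 (1-DOF) or 6, 8 (2-DOF).
#' Targets are presented sequentially in numerical order, cycling.
#'
#' @param method `"dc"` or `"pr"`.
#' @param cohort `"healthy"` or `"dmd"`.
#' @param dof 1 or 2.
#' @param trials_per_target default 10.
#' @param discard_first leading trials per target flagged as practice,
#'   default 2; must be < `trials_per_target`.
#' @param dwell_s,inter_trial_s,timeout_s trial timing, defaults 2 / 2 / 30 s.
#' @param seed session RNG seed.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(method = c("dc", "pr"),
                         cohort = c("healthy", "dmd"),
                         dof = 1,
                         trials_per_target = 10, discard_first = 2,
                         dwell_s = 2, inter_trial_s = 2, timeout_s = 30,
                         seed = 1L) {
  method <- match.arg(method); cohort <- match.arg(cohort)
  stopifnot(dof %in% c(1, 2), discard_first < trials_per_target,
            discard_first >= 0)
  target_ids <- if (cohort == "healthy") {
    if (dof == 1) 1:4 else 5:8
  } else {
    if (dof == 1) c(1L, 2L) else c(6L, 8L)
  }
  structure(list(method = method, cohort = cohort, dof = dof,
                 target_ids = target_ids,
                 trials_per_target = trials_per_target,
                 discard_first = discard_first,
                 dwell_s = dwell_s, inter_trial_s = inter_trial_s,
                 timeout_s = timeout_s, seed = as.integer(seed)),
            class = "session_spec")
}

#' Set up a calibrated virtual subject
#'
#' Generates the subject's calibration kit, computes the calibration profile,
#' trains the gesture classifier, and builds the matching controllers,
#' virtual user and scaled admittance parameters. The admittance preset
#' follows the cohort and is rescaled to the normalized workspace
#' (`max_speed` at full control), preserving its time constant.
#'
#' @param profile a [subject_profile()]; default built from `cohort`.
#' @param cohort used when `profile` is NULL.
#' @param seed RNG seed for the kit and classifier training.
#' @param max_speed workspace terminal speed at F = 1 N, default 2 units/s.
#' @param mapping a [motion_mapping()]; defaults to `right_handed` for
#'   healthy and `dmd` for the DMD cohort.
#' @param user_args named list of overrides passed to [virtual_user()].
#' @return An object of class `subject_setup` bundling profile, calib, model,
#'   controllers, user and admittance params.
#' @export
subject_setup <- function(profile = NULL, cohort = c("healthy", "dmd"),
                          seed = 1L, max_speed = 2, mapping = NULL,
                          user_args = list()) {
  cohort <- match.arg(cohort)
  if (is.null(profile)) profile <- subject_profile(cohort)
  cohort <- profile$cohort
  if (is.null(mapping))
    mapping <- motion_mapping(if (cohort == "dmd") "dmd" else "right_handed")
  kit <- make_calibration_kit(profile, seed = seed)
  calib <- calibrate(kit$mvc, kit$rest)
  prc <- pr_config(mapping = mapping, seed = seed)
  model <- pr_train(build_training_set(kit$training, prc), prc)
  dcc <- dc_config(mapping = mapping,
                   switch_source = if (cohort == "dmd") "trigger" else "cocontraction")
  user <- do.call(virtual_user, c(list(profile = profile), user_args))
  params <- velocity_scale(admittance_preset(cohort), max_speed = max_speed)
  structure(list(profile = profile, calib = calib, model = model,
                 dc = dc_controller(calib, dcc),
                 pr = pr_controller(calib, model, prc),
                 user = user, params = params, seed = seed),
            class = "subject_setup")
}

#' Run a full session
#'
#' Executes every trial of a [session_spec()] for a calibrated subject:
#' targets cycle in numerical order, each appearing `trials_per_target`
#' times; the first `discard_first` presentations of each target are flagged
#' as discarded practice trials; the DC mode state persists across trials
#' while the cursor resets to the center during the inter-trial interval.
#' Fully deterministic for a fixed spec seed.
#'
#' @param spec a [session_spec()].
#' @param setup a [subject_setup()].
#' @param layout a [make_layout()] layout.
#' @param subject optional subject label stored with every trial.
#' @param store_timeseries keep per-trial cursor traces (as attributes).
#' @return data.frame, one row per trial: cohort, method, dof, subject,
#'   target_id, trial_index, discarded, success, reaching_time_s,
#'   completed_at_s, n_switches, seed.
#' @export
run_session <- function(spec, setup, layout = make_layout(),
                        subject = paste0(spec$cohort, "_s1"),
                        store_timeseries = FALSE) {
  stopifnot(inherits(spec, "session_spec"), inherits(setup, "subject_setup"))
  controller <- if (spec$method == "dc") setup$dc else setup$pr
  order_ids <- rep(spec$target_ids, times = spec$trials_per_target)
  n_trials <- length(order_ids)
  trial_no <- as.integer(stats::ave(seq_len(n_trials), order_ids, FUN = seq_along))
  trial_seeds <- withr::with_seed(spec$seed,
                                  sample.int(.Machine$integer.max, n_trials))
  dcs <- NULL
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    out <- run_trial(controller, setup$user, layout, order_ids[i],
                     setup$params, seed = trial_seeds[i],
                     dwell_s = spec$dwell_s, timeout_s = spec$timeout_s,
                     dc_init = dcs, store_timeseries = store_timeseries)
    dcs <- out$dc_state
    r <- out$result
    r$trial_index <- trial_no[i]
    r$discarded <- trial_no[i] <= spec$discard_first
    rows[[i]] <- r
  }
  res <- do.call(rbind, rows)
  res <- cbind(data.frame(cohort = spec$cohort, method = spec$method,
                          dof = spec$dof, subject = subject), res)
  if (store_timeseries)
    attr(res, "timeseries") <- lapply(rows, attr, "timeseries")
  res
}
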