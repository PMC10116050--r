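#' Admittance (virtual mass-damper) parameters
#'
#' First-order admittance H(s) = 1/(A s + B) from estimated force to cursor
#' velocity: A is the virtual inertia-related parameter, B the virtual
#' damping-related parameter. Presets carry the study's personalized values —
#' `healthy` A = 6.6e-4, B = 4e-4; `dmd` A = 5e-4, B = 6e-4 (the DMD user
#' preferred a lower virtual mass, for less fatiguing motion, and a higher
#' damping, for more stable control). The behaviorally meaningful time
#' constant is A/B: 1.65 s (healthy), ~0.833 s (dmd).
#'
#' @param A virtual inertia, force·s² per workspace unit; > 0.
#' @param B virtual damping, force·s per workspace unit; > 0.
#' @return An object of class `admittance_params`.
#' @export
admittance_params <- function(A, B) {
  stopifnot(is.finite(A), is.finite(B), A > 0, B > 0)
  structure(list(A = A, B = B), class = "admittance_params")
}

#' @rdname admittance_params
#' @param preset `"healthy"` or `"dmd"`.
#' @export
admittance_preset <- function(preset = c("healthy", "dmd")) {
  preset <- match.arg(preset)
  switch(preset,
         healthy = admittance_params(A = 6.6e-4, B = 4e-4),
         dmd     = admittance_params(A = 5e-4,  B = 6e-4))
}

#' @export
print.admittance_params <- function(x, ...) {
  cat(sprintf("<admittance_params> A = %g, B = %g (tau = A/B = %.4g s, v_ss at F=1: %.4g)\n",
              x$A, x$B, x$A / x$B, 1 / x$B))
  invisible(x)
}

#' Rescale admittance parameters to a workspace speed
#'
#' The raw study parameters imply a terminal velocity 1/B of thousands of
#' units/s; in the normalized \[-1, 1\]² workspace both parameters are scaled
#' by a common gain, which changes the terminal speed F/B while preserving
#' the time constant A/B exactly.
#'
#' @param p an [admittance_params()].
#' @param max_speed desired terminal cursor speed (workspace units/s) at
#'   F = 1 N; mutually exclusive with `gain`.
#' @param gain direct multiplicative gain on A and B (`gain = 1` is the
#'   identity).
#' @return rescaled [admittance_params()].
#' @export
velocity_scale <- function(p, max_speed = NULL, gain = NULL) {
  stopifnot(inherits(p, "admittance_params"))
  if (is.null(gain)) {
    stopifnot(!is.null(max_speed), max_speed > 0)
    gain <- 1 / (p$B * max_speed)
  }
  stopifnot(gain > 0)
  admittance_params(p$A * gain, p$B * gain)
}

#' Cursor state
#'
#' Position and velocity of the virtual cursor in the normalized workspace
#' \[-1, 1\]², plus the simulation clock.
#'
#' @param pos,vel numeric 2-vectors.
#' @param t time, seconds.
#' @return An object of class `cursor_state`.
#' @export
cursor_state <- function(pos = c(0, 0), vel = c(0, 0), t = 0) {
  stopifnot(all(is.finite(pos)), all(is.finite(vel)))
  structure(list(pos = pos, vel = vel, t = t), class = "cursor_state")
}

#' Estimated force from a control output
#'
#' The 2-vector control signal is converted to an estimated force with a
#' conversion gain of 1 N, so |F| <= 1 N per axis.
#'
#' @param u numeric 2-vector control output, |component| <= 1.
#' @param gain_n conversion gain in N, default 1.
#' @return numeric 2-vector force command.
#' @export
force_from_control <- function(u, gain_n = 1) {
  stopifnot(length(u) == 2, all(abs(u) <= 1 + 1e-12))
  gain_n * u
}

#' One admittance integration step (exact zero-order hold)
#'
#' Advances A·v̇ + B·v = F per axis over `dt` with F held constant, using the
#' closed-form solution: v' = v·e^(−dt/τ) + (F/B)(1 − e^(−dt/τ)) with
#' τ = A/B, and the exact integral of v for the position update — the
#' trajectory is therefore independent of the step size between force
#' updates. Positions are clamped to the workspace; a clamped axis has its
#' velocity zeroed.
#'
#' @param state a [cursor_state()].
#' @param F numeric 2-vector force command (finite).
#' @param p an [admittance_params()].
#' @param dt step length, seconds, > 0.
#' @param workspace half-width of the square workspace, default 1.
#' @return the advanced [cursor_state()].
#' @export
admittance_step <- function(state, F, p, dt, workspace = 1) {
  if (!all(is.finite(F))) stop("non-finite force command")
  stopifnot(dt > 0)
  tau <- p$A / p$B
  decay <- exp(-dt / tau)
  vinf <- F / p$B
  v0 <- state$vel
  v1 <- vinf + (v0 - vinf) * decay
  # integral of v over the step: vinf*dt + (v0 - vinf)*tau*(1 - decay)
  pos <- state$pos + vinf * dt + (v0 - vinf) * tau * (1 - decay)
  hi <- pos > workspace; lo <- pos < -workspace
  pos[hi] <- workspace; pos[lo] <- -workspace
  v1[hi | lo] <- 0
  cursor_state(pos, v1, state$t + dt)
}
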