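#' Motion classes
#'
#' The five gesture classes decoded by the pattern-recognition controller.
#' @export
MOTION_CLASSES <- c("HAND_OPEN", "HAND_CLOSE", "WRIST_FLEXION",
                    "WRIST_EXTENSION", "NO_MOTION")

#' Limb-motion to cursor-motion mapping
#'
#' Presets reflecting the experiment's mapping table. For PR control each
#' motion class owns one signed cursor direction; for DC control each axis
#' carries the signed antagonist difference U = U_ext - U_flex, with a
#' per-axis sign stating which direction wrist extension drives.
#'
#' * `right_handed` — PR: flexion left, extension right, hand open up, hand
#'   close down. DC: extension right (+x); flexion up, i.e. extension -y.
#' * `left_handed` — PR: extension left, flexion right, hand open up, hand
#'   close down. DC: flexion right (extension -x); extension up (+y).
#' * `dmd` — supinated forearm. PR: hand close left, hand open right,
#'   extension up, flexion down. DC: flexion right (extension -x);
#'   extension up (+y).
#'
#' @param preset one of `"right_handed"`, `"left_handed"`, `"dmd"`.
#' @return An object of class `motion_mapping` with a `pr` list (class ->
#'   unit direction) and a `dc_ext_sign` 2-vector (sign of the cursor motion
#'   produced by wrist extension on the x and y axes).
#' @export
motion_mapping <- function(preset = c("right_handed", "left_handed", "dmd")) {
  preset <- match.arg(preset)
  pr <- switch(preset,
    right_handed = list(
      WRIST_FLEXION   = c(-1, 0), WRIST_EXTENSION = c(1, 0),
      HAND_OPEN       = c(0, 1),  HAND_CLOSE      = c(0, -1)),
    left_handed = list(
      WRIST_EXTENSION = c(-1, 0), WRIST_FLEXION   = c(1, 0),
      HAND_OPEN       = c(0, 1),  HAND_CLOSE      = c(0, -1)),
    dmd = list(
      HAND_CLOSE      = c(-1, 0), HAND_OPEN       = c(1, 0),
      WRIST_EXTENSION = c(0, 1),  WRIST_FLEXION   = c(0, -1)))
  pr$NO_MOTION <- c(0, 0)
  dc_ext_sign <- switch(preset,
    right_handed = c(x = 1, y = -1),
    left_handed  = c(x = -1, y = 1),
    dmd          = c(x = -1, y = 1))
  structure(list(preset = preset, pr = pr, dc_ext_sign = dc_ext_sign),
            class = "motion_mapping")
}

# Invert the PR mapping: which class moves the cursor along `axis`
# (1 = x, 2 = y) in direction `sign`?
pr_class_for_direction <- function(mapping, axis, sign) {
  for (cls in setdiff(names(mapping$pr), "NO_MOTION")) {
    d <- mapping$pr[[cls]]
    if (d[axis] * sign > 0) return(cls)
  }
  stop("mapping is not bijective per axis")
}

#' @export
print.motion_mapping <- function(x, ...) {
  cat(sprintf("<motion_mapping> preset '%s'\n", x$preset))
  for (cls in setdiff(names(x$pr), "NO_MOTION"))
    cat(sprintf("  PR %-16s -> (%+d, %+d)\n", cls, x$pr[[cls]][1], x$pr[[cls]][2]))
  cat(sprintf("  DC wrist extension -> %+dx / %+dy\n",
              x$dc_ext_sign[1], x$dc_ext_sign[2]))
  invisible(x)
}
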