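#' Torque-velocity gain specifications
#'
#' The torque-velocity factor G_v enters the generator as a positive gain
#' applied to the combined factor eta. Under the null hypothesis that drives
#' the whole analysis it is a constant; an affine alternative is provided to
#' inject a controlled velocity effect for power studies.
#'
#' @param value gain at the reference velocity (dimensionless, > 0).
#' @param ref reference angular velocity in deg/s (default 90, the middle of
#'   the tested 60/90/120 deg/s protocol).
#' @param ratio ratio `g(120)/g(60)` of the affine gain across the tested
#'   velocity span; `ratio = 1` recovers a constant.
#' @param floor lower clamp on the gain as a fraction of `value`, so the gain
#'   stays positive when evaluated at very low speeds (isotonic starts).
#' @return An object of class `velocity_gain`.
#' @export
velocity_gain_constant <- function(value = 1) {
  check_num(value, "velocity_gain", lower = 0, open_lower = TRUE)
  structure(list(type = "constant", value = value), class = "velocity_gain")
}

#' @rdname velocity_gain_constant
#' @export
velocity_gain_affine <- function(value = 1, ref = 90, ratio = 2, floor = 0.1) {
  check_num(value, "velocity_gain", lower = 0, open_lower = TRUE)
  check_num(ratio, "velocity_gain ratio", lower = 0, open_lower = TRUE)
  # slope chosen so that g(ref+30)/g(ref-30) = ratio
  m <- (ratio - 1) / ((ratio + 1) * 30)
  structure(list(type = "affine", value = value, ref = ref, slope = m,
                 floor = floor),
            class = "velocity_gain")
}

as_velocity_gain <- function(x) {
  if (inherits(x, "velocity_gain")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(velocity_gain_constant(x))
  if (is.function(x)) {
    return(structure(list(type = "custom", fn = x), class = "velocity_gain"))
  }
  stop_invariant("velocity_gain", "must be a velocity_gain, a positive number or a function")
}

#' Evaluate a velocity gain at given angular speeds
#'
#' @param gain a [velocity_gain_constant()]/[velocity_gain_affine()] object,
#'   a positive scalar, or a function of speed.
#' @param speed angular speed in deg/s (sign is ignored).
#' @return positive numeric vector the length of `speed`.
#' @export
eval_velocity_gain <- function(gain, speed) {
  gain <- as_velocity_gain(gain)
  v <- abs(speed)
  out <- switch(gain$type,
    constant = rep(gain$value, length(v)),
    affine = pmax(gain$value * (1 + gain$slope * (v - gain$ref)),
                  gain$floor * gain$value),
    custom = vapply(v, gain$fn, numeric(1)))
  if (any(!is.finite(out)) || any(out <= 0)) {
    stop_invariant("velocity_gain", "gain must evaluate to a positive finite value")
  }
  out
}

#' @export
print.velocity_gain <- function(x, ...) {
  cat("<velocity_gain>", x$type,
      if (x$type == "constant") sprintf("value=%g", x$value)
      else if (x$type == "affine") sprintf("value=%g ref=%g slope=%.4g", x$value, x$ref, x$slope)
      else "", "\n")
  invisible(x)
}
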