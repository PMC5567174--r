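#' Synthetic subject parameters
#'
#' Draws the ground-truth parameters of one synthetic subject. The generator
#' states the world the analysis assumes: the combined torque-angle factor is
#' log-linear in elbow angle, `eta(theta) = exp(a1*theta + a2)` (N.m), the
#' torque-velocity factor is a multiplicative gain (constant 1 under the
#' null), the connatural circumference grows linearly with flexion, and the
#' voluntary circumferential strain is an endpoint-zero unimodal bump with
#' peak `s_max`.
#'
#' Default ranges place every subject inside the study's inclusion rule
#' (peak strain above 5% and at most 30%) and give peak isokinetic torques
#' of roughly 25-55 N.m, the magnitude reported for healthy adult elbow
#' flexion on an isokinetic dynamometer.
#'
#' @param seed integer seed; the draw is deterministic given the seed and
#'   the global RNG state is left untouched. `NULL` uses the current RNG.
#' @param overrides named list of fields to pin instead of sampling
#'   (e.g. `list(a1_true = -0.012, noise_torque_sd = 0)`). Overrides are
#'   validated against the same invariants as sampled values.
#' @return An object of class `subject_params` with fields
#'   `subject_id`, `a1_true` (1/deg), `a2_true` (log N.m), `velocity_gain`,
#'   `c0_mid` (mm at 90 deg), `c0_slope` (mm/deg), `s_max` (fraction),
#'   `strain_shape_p`, `t120_max` (N.m, derived), `noise_torque_sd` (N.m),
#'   `noise_circ_sd` (mm), `drift_amp` (mm), `drift_tau` (s),
#'   `inertia` (kg.m^2), `damping` (N.m.s/deg), `rom` (deg).
#' @examples
#' s <- make_subject(seed = 1)
#' s$s_max
#' @export
make_subject <- function(seed = NULL, overrides = list()) {
  draw <- function() {
    list(
      subject_id     = paste0("S", sprintf("%04d", sample.int(9999L, 1L))),
      a1_true        = stats::runif(1, -0.018, -0.008),
      a2_true        = stats::runif(1, 6.0, 7.0),
      velocity_gain  = velocity_gain_constant(1),
      c0_mid         = stats::runif(1, 270, 320),
      c0_slope       = stats::runif(1, 0.12, 0.30),
      s_max          = stats::runif(1, 0.08, 0.25),
      strain_shape_p = 1,
      noise_torque_sd = 0.5,
      noise_circ_sd  = 0.4,
      drift_amp      = 2,
      drift_tau      = 60,
      inertia        = 0.08,
      damping        = 0.10,
      rom            = c(30, 120)
    )
  }
  fields <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("overrides must be a named list", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), c(names(fields), "t120_max"))
    if (length(unknown)) {
      stop(sprintf("unknown subject field(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    fields[names(overrides)] <- overrides
  }
  fields$velocity_gain <- as_velocity_gain(fields$velocity_gain)
  subject <- structure(fields, class = "subject_params")
  validate_subject(subject)
  # derived: peak torque at 120 deg/s on a dense angle grid (the quantity the
  # isotonic impedance levels are set relative to)
  grid <- seq(subject$rom[1], subject$rom[2], by = 0.1)
  subject$t120_max <- max(strain_profile(subject, grid) *
                            eta_true(subject, grid, speed = 120))
  subject
}

validate_subject <- function(s) {
  check_num(s$a1_true, "a1_true")
  check_num(s$a2_true, "a2_true")
  check_num(s$c0_mid, "c0_mid", lower = 0, open_lower = TRUE)
  check_num(s$c0_slope, "c0_slope", lower = 0, open_lower = TRUE)
  check_num(s$s_max, "s_max", lower = 0.05, upper = 0.30, open_lower = TRUE)
  check_num(s$strain_shape_p, "strain_shape_p", lower = 0, open_lower = TRUE)
  check_num(s$noise_torque_sd, "noise_torque_sd", lower = 0)
  check_num(s$noise_circ_sd, "noise_circ_sd", lower = 0)
  check_num(s$drift_amp, "drift_amp", lower = 0)
  check_num(s$drift_tau, "drift_tau", lower = 0, open_lower = TRUE)
  check_num(s$inertia, "inertia", lower = 0, open_lower = TRUE)
  check_num(s$damping, "damping", lower = 0)
  check_num(s$rom, "rom", len = 2L)
  if (s$rom[1] >= s$rom[2]) stop_invariant("rom", "lower limit must be below upper limit")
  eval_velocity_gain(s$velocity_gain, c(60, 90, 120))  # positivity check
  invisible(s)
}

check_rom <- function(angle, rom, tol = 1e-8) {
  if (any(!in_closed(angle, rom, tol))) {
    stop(sprintf("angle out of range: ROM is [%g, %g] deg", rom[1], rom[2]),
         call. = FALSE)
  }
  invisible(angle)
}

#' Connatural (passive) upper-arm circumference
#'
#' Circumference of the relaxed upper arm as a function of elbow angle;
#' strictly increasing with flexion because passive shortening thickens the
#' biceps. Anchored at `c0_mid` at 90 deg with slope `c0_slope`.
#'
#' @param subject a [make_subject()] object.
#' @param angle elbow angle(s) in degrees, inside the subject's ROM.
#' @return circumference in mm.
#' @export
connatural_circumference <- function(subject, angle) {
  check_rom(angle, subject$rom)
  subject$c0_mid + subject$c0_slope * (angle - 90)
}

#' Voluntary circumferential strain profile
#'
#' Maximum-effort voluntary strain at each elbow angle: zero at both ROM
#' limits, unimodal, peaking at `s_max` mid-range. The shape is the scaled
#' bump `s_max * (4u(1-u))^p` with `u` the normalised angle.
#'
#' @inheritParams connatural_circumference
#' @return strain as a dimensionless fraction.
#' @export
strain_profile <- function(subject, angle) {
  check_rom(angle, subject$rom)
  u <- (angle - subject$rom[1]) / diff(subject$rom)
  u <- pmin(pmax(u, 0), 1)
  subject$s_max * (4 * u * (1 - u))^subject$strain_shape_p
}

# ground-truth combined factor eta(theta, thetadot) in N.m
eta_true <- function(subject, angle, speed) {
  exp(subject$a1_true * angle + subject$a2_true) *
    eval_velocity_gain(subject$velocity_gain, speed)
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("<subject_params> %s\n", x$subject_id))
  cat(sprintf("  ln eta: a1=%.5f /deg  a2=%.3f   s_max=%.3f  T120max=%.1f N.m\n",
              x$a1_true, x$a2_true, x$s_max, x$t120_max %||% NA_real_))
  cat(sprintf("  C0: %.1f mm @90deg, %.3f mm/deg;  noise: torque %.2f N.m, circ %.2f mm; drift %.1f mm / %g s\n",
              x$c0_mid, x$c0_slope, x$noise_torque_sd, x$noise_circ_sd,
              x$drift_amp, x$drift_tau))
  invisible(x)
}
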