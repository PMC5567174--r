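#' Trial protocol configuration
#'
#' Describes one dynamometer trial. Modes follow the experimental protocol:
#' `"isokinetic"` (constant-speed flexion/extension cycles), `"isotonic"`
#' (flexion against a constant impedance torque) and `"passive"` (assisted
#' motion with no voluntary contraction, used for calibration).
#'
#' @param mode one of `"passive"`, `"isokinetic"`, `"isotonic"`.
#' @param rom range of motion in degrees, default `c(30, 120)`.
#' @param velocity angular velocity in deg/s; required for isokinetic and
#'   passive trials.
#' @param impedance constant resistance torque in N.m; required for isotonic
#'   trials.
#' @param n_cycles number of extension-flexion cycles (default 4).
#' @param sample_rate sampling rate in Hz for all three channels (default 100).
#' @param return_velocity passive return speed in deg/s used for the
#'   extension phase of isotonic trials.
#' @param seed integer RNG seed for measurement noise and drift; `NULL`
#'   leaves the trial non-reproducible.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(mode = c("isokinetic", "isotonic", "passive"),
                            rom = c(30, 120), velocity = NULL,
                            impedance = NULL, n_cycles = 4,
                            sample_rate = 100, return_velocity = 90,
                            seed = NULL) {
  mode <- match.arg(mode)
  check_num(rom, "rom", len = 2L)
  if (rom[1] >= rom[2]) stop_invariant("rom", "lower limit must be below upper limit")
  check_num(n_cycles, "n_cycles", lower = 1)
  check_num(sample_rate, "sample_rate", lower = 0, open_lower = TRUE)
  if (mode %in% c("isokinetic", "passive")) {
    if (is.null(velocity)) {
      stop(sprintf("configuration error: %s trials require a velocity", mode),
           call. = FALSE)
    }
    check_num(velocity, "velocity", lower = 0, open_lower = TRUE)
  }
  if (mode == "isotonic") {
    if (is.null(impedance)) {
      stop("configuration error: isotonic trials require an impedance",
           call. = FALSE)
    }
    check_num(impedance, "impedance", lower = 0, open_lower = TRUE)
    check_num(return_velocity, "return_velocity", lower = 0, open_lower = TRUE)
  }
  if (!is.null(seed)) check_num(seed, "seed")
  structure(list(mode = mode, rom = rom, velocity = velocity,
                 impedance = impedance, n_cycles = as.integer(n_cycles),
                 sample_rate = sample_rate,
                 return_velocity = return_velocity, seed = seed),
            class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("<protocol_config> %s  ROM [%g, %g] deg, %d cycle(s) @ %g Hz",
              x$mode, x$rom[1], x$rom[2], x$n_cycles, x$sample_rate))
  if (!is.null(x$velocity)) cat(sprintf(", %g deg/s", x$velocity))
  if (!is.null(x$impedance)) cat(sprintf(", impedance %g N.m", x$impedance))
  cat("\n")
  invisible(x)
}
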