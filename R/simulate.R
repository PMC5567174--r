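#' Simulate an isokinetic flexion-extension trial
#'
#' The dynamometer enforces a triangular angle trajectory across the ROM at
#' constant speed. During flexion phases the subject produces the voluntary
#' strain profile and the generated torque follows the model
#' `T = s * exp(a1*theta + a2) * G_v(thetadot)`; during extensions the
#' subject rests (zero voluntary strain, zero torque). The circumference
#' channel is `C0(theta) * (1 + s)` plus slow baseline drift (fabric-sensor
#' resistance relaxation) and Gaussian noise; the torque channel carries
#' Gaussian noise.
#'
#' @param subject a [make_subject()] object.
#' @param protocol a [protocol_config()] with the matching mode.
#' @return A [trial_recording()] with `ground_truth` attached
#'   (`strain`, `eta`, `torque_clean`, `circumference_clean`, `speed`,
#'   `flexion`, `cycle`).
#' @export
simulate_isokinetic_trial <- function(subject, protocol) {
  if (protocol$mode != "isokinetic") {
    stop("configuration error: protocol mode must be 'isokinetic'", call. = FALSE)
  }
  sim_triangular(subject, protocol, voluntary = TRUE, drift = TRUE)
}

#' Simulate a passive (calibration) trial
#'
#' The elbow is moved through the same triangular trajectory with no
#' voluntary contraction: torque is measurement noise only and the
#' circumference equals the connatural profile plus noise (no drift by
#' default, matching a short assisted calibration run).
#'
#' @inheritParams simulate_isokinetic_trial
#' @export
simulate_passive_trial <- function(subject, protocol) {
  if (protocol$mode != "passive") {
    stop("configuration error: protocol mode must be 'passive'", call. = FALSE)
  }
  sim_triangular(subject, protocol, voluntary = FALSE, drift = FALSE)
}

# shared triangular-trajectory generator; flexion first, starting at ROM-low
sim_triangular <- function(subject, protocol, voluntary, drift) {
  rom <- protocol$rom
  span <- diff(rom)
  v <- protocol$velocity
  dur <- span / v
  rate <- protocol$sample_rate
  n_steps <- round(2 * dur * protocol$n_cycles * rate)
  t <- (0:(n_steps - 1L)) / rate   # half-open [0, T): no duplicate cycle start
  x <- (t * v / span) %% 2               # phase position in [0, 2)
  flex <- x <= 1
  theta <- rom[1] + span * ifelse(flex, x, 2 - x)
  theta <- pmin(pmax(theta, rom[1]), rom[2])
  cycle <- pmin(floor(t * v / (2 * span)) + 1L, protocol$n_cycles)

  s <- numeric(length(t))
  if (voluntary) s[flex] <- strain_profile(subject, theta[flex])
  speed <- ifelse(flex, v, -v)
  eta <- eta_true(subject, theta, speed)
  torque_clean <- s * eta
  circ_clean <- connatural_circumference(subject, theta) * (1 + s)

  noise <- draw_channel_noise(length(t), subject, protocol$seed)
  drift_base <- if (drift && subject$drift_amp > 0) {
    subject$drift_amp * (1 - exp(-t / subject$drift_tau))
  } else 0

  gt <- data.frame(strain = s, eta = eta, torque_clean = torque_clean,
                   circumference_clean = circ_clean, speed = speed,
                   flexion = flex, cycle = cycle)
  trial_recording(t, theta,
                  torque_clean + noise$torque,
                  circ_clean + drift_base + noise$circ,
                  protocol, subject_id = subject$subject_id,
                  ground_truth = gt, subject = subject)
}

draw_channel_noise <- function(n, subject, seed) {
  gen <- function() list(torque = stats::rnorm(n, 0, subject$noise_torque_sd),
                         circ = stats::rnorm(n, 0, subject$noise_circ_sd))
  if (subject$noise_torque_sd == 0 && subject$noise_circ_sd == 0) {
    return(list(torque = numeric(n), circ = numeric(n)))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate an isotonic flexion trial
#'
#' The forearm is a rigid body: `I * thetadd = T_muscle - impedance -
#' damping * thetad`, with the angle clipped to the ROM and the velocity
#' zeroed at the limits. Muscle torque comes from the same generator as the
#' isokinetic mode, `T = s * eta_true(theta, thetad)`. The voluntary strain
#' command is the maximum-effort profile with two protocol-driven
#' adjustments (documented in the methods vignette): an activation ramp at
#' the standstill start, and a drive floor that keeps the muscle torque just
#' above the impedance until close to the upper limit so the flexion
#' traverses the ROM, tapering to zero at ROM-high so torque and strain
#' still vanish there. Extensions are passive returns at
#' `protocol$return_velocity`.
#'
#' @inheritParams simulate_isokinetic_trial
#' @param margin fractional torque surplus of the drive floor over the
#'   impedance (default 0.1).
#' @param taper_deg width in degrees of the taper of the drive floor below
#'   ROM-high (default 8).
#' @param t_ramp activation ramp time at flexion start in seconds.
#' @param substeps Euler substeps per sample for the dynamics integration.
#' @export
simulate_isotonic_trial <- function(subject, protocol, margin = 0.1,
                                    taper_deg = 8, t_ramp = 0.3,
                                    substeps = 5L) {
  if (protocol$mode != "isotonic") {
    stop("configuration error: protocol mode must be 'isotonic'", call. = FALSE)
  }
  imp <- protocol$impedance
  if (imp >= subject$t120_max) {
    stop(sprintf(
      "infeasible protocol: impedance %.2f N.m is not below the subject's achievable peak torque %.2f N.m",
      imp, subject$t120_max), call. = FALSE)
  }
  rom <- protocol$rom
  dt <- 1 / protocol$sample_rate

  eta_angle <- function(theta) exp(subject$a1_true * theta + subject$a2_true)
  taper <- function(theta) {
    pmin(pmax((rom[2] - theta) / taper_deg, 0), 1)
  }
  strain_cmd <- function(theta, tloc) {
    ramp <- min(tloc / t_ramp, 1)
    drive <- (1 + margin) * imp / eta_angle(theta) * taper(theta)
    ramp * min(max(strain_profile(subject, theta), drive), 0.30)
  }

  time <- numeric(0); angle <- numeric(0)
  s_all <- numeric(0); speed_all <- numeric(0)
  flex_all <- logical(0); cycle_all <- integer(0)

  t0 <- 0
  for (cyc in seq_len(protocol$n_cycles)) {
    fl <- integrate_flexion(
      torque_fn = function(theta, omega, tloc) {
        s <- strain_cmd(theta, tloc)
        s * eta_angle(theta) * eval_velocity_gain(subject$velocity_gain, omega)
      },
      inertia = subject$inertia, damping = subject$damping,
      impedance = imp, rom = rom, dt = dt, substeps = substeps)
    s_fl <- vapply(seq_along(fl$time),
                   function(i) strain_cmd(fl$angle[i], fl$time[i]), numeric(1))
    # passive return to ROM-low at constant speed
    top <- fl$angle[length(fl$angle)]
    ext_dur <- (top - rom[1]) / protocol$return_velocity
    n_ext <- max(1L, ceiling(ext_dur / dt))
    t_ext <- seq_len(n_ext) * dt
    a_ext <- pmax(top - protocol$return_velocity * t_ext, rom[1])

    time <- c(time, t0 + fl$time, t0 + fl$time[length(fl$time)] + t_ext)
    angle <- c(angle, fl$angle, a_ext)
    s_all <- c(s_all, s_fl, numeric(n_ext))
    speed_all <- c(speed_all, fl$omega, rep(-protocol$return_velocity, n_ext))
    flex_all <- c(flex_all, rep(TRUE, length(fl$time)), rep(FALSE, n_ext))
    cycle_all <- c(cycle_all, rep(cyc, length(fl$time) + n_ext))
    t0 <- time[length(time)] + dt
  }

  eta <- eta_angle(angle) * eval_velocity_gain(subject$velocity_gain, speed_all)
  torque_clean <- s_all * eta
  circ_clean <- connatural_circumference(subject, angle) * (1 + s_all)
  noise <- draw_channel_noise(length(time), subject, protocol$seed)
  drift_base <- if (subject$drift_amp > 0) {
    subject$drift_amp * (1 - exp(-time / subject$drift_tau))
  } else 0

  gt <- data.frame(strain = s_all, eta = eta, torque_clean = torque_clean,
                   circumference_clean = circ_clean, speed = speed_all,
                   flexion = flex_all, cycle = cycle_all)
  trial_recording(time, angle,
                  torque_clean + noise$torque,
                  circ_clean + drift_base + noise$circ,
                  protocol, subject_id = subject$subject_id,
                  ground_truth = gt, subject = subject)
}

# Forward-Euler integration of one flexion against a constant impedance.
# torque_fn(theta, omega, tloc) returns the muscle torque in N.m; inertia in
# kg.m^2 (dynamics in radians, channels in degrees). The flexion ends when
# the angle reaches ROM-high or the arm stalls after having moved: either
# the velocity crosses zero, or it decays below `stall_speed` while the
# muscle torque no longer exceeds the impedance plus the residual damping
# load (the asymptotic approach to the drive-taper equilibrium).
integrate_flexion <- function(torque_fn, inertia, damping, impedance, rom,
                              dt, substeps = 5L, max_time = 15,
                              stall_speed = 1) {
  k <- 180 / pi
  h <- dt / substeps
  theta <- rom[1]; omega <- 0; tloc <- 0
  moved <- FALSE; done <- FALSE
  time <- numeric(0); ang <- numeric(0); om <- numeric(0)
  # sample at t = 0
  time <- c(time, 0); ang <- c(ang, theta); om <- c(om, omega)
  while (!done) {
    for (ss in seq_len(substeps)) {
      tm <- torque_fn(theta, omega, tloc)
      if (omega <= 0 && theta <= rom[1] && tm <= impedance) {
        omega <- 0  # held at the stop until torque exceeds the impedance
      } else {
        omega <- omega + h * k * (tm - impedance - damping * omega) / inertia
      }
      theta <- theta + omega * h
      tloc <- tloc + h
      if (theta >= rom[2]) { theta <- rom[2]; omega <- 0; done <- TRUE; break }
      if (theta <= rom[1]) { theta <- rom[1]; if (omega < 0) omega <- 0 }
      if (moved &&
          (omega <= 0 ||
           (omega < stall_speed &&
            tm <= impedance + damping * stall_speed))) {
        omega <- 0; done <- TRUE; break
      }
      if (theta > rom[1] + 0.5) moved <- TRUE
    }
    time <- c(time, tloc); ang <- c(ang, theta); om <- c(om, omega)
    if (tloc > max_time) {
      stop("infeasible protocol: flexion failed to traverse the ROM", call. = FALSE)
    }
  }
  list(time = time, angle = ang, omega = pmax(om, 0))
}

#' Add slow baseline drift to a circumference series
#'
#' Emulates resistance relaxation of fabric strain sensors: a saturating
#' baseline `amp * (1 - exp(-t/tau))` plus an optional Gaussian random walk.
#' The input series is not modified.
#'
#' @param circumference circumference series in mm.
#' @param time sample times in seconds (same length).
#' @param amp drift amplitude in mm (`0` returns the input unchanged).
#' @param tau relaxation time constant in seconds (> 0).
#' @param seed RNG seed for the random-walk component.
#' @param rw_sd standard deviation of the random-walk increments in
#'   mm/sqrt(s); default 0 (deterministic drift only).
#' @return the drifted circumference series.
#' @export
apply_drift <- function(circumference, time, amp, tau, seed = NULL, rw_sd = 0) {
  if (length(circumference) != length(time)) {
    stop_invariant("channels", "circumference and time must have equal length")
  }
  check_num(amp, "drift amp", lower = 0)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("parameter error: tau must be a positive number", call. = FALSE)
  }
  check_num(rw_sd, "rw_sd", lower = 0)
  out <- circumference + amp * (1 - exp(-time / tau))
  if (rw_sd > 0) {
    steps <- c(0, sqrt(pmax(diff(time), 0)))
    gen <- function() cumsum(stats::rnorm(length(time), 0, rw_sd) * steps)
    out <- out + if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  }
  out
}
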