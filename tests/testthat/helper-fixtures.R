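# zero-noise, zero-drift subject for exactness tests
quiet_overrides <- function(...) {
  c(list(noise_torque_sd = 0, noise_circ_sd = 0, drift_amp = 0), list(...))
}

quiet_subject <- function(seed = 42, ...) {
  make_subject(seed = seed, overrides = quiet_overrides(...))
}

# homogeneous-cohort overrides used by the ANOVA calibration runs: removes
# between-subject spread so the velocity groups are exchangeable
homogeneous_overrides <- list(a1_true = -0.012, a2_true = 6.5, s_max = 0.15,
                              c0_mid = 300, c0_slope = 0.2)

iso_protocol <- function(velocity = 90, seed = 1, n_cycles = 4, ...) {
  protocol_config("isokinetic", velocity = velocity, n_cycles = n_cycles,
                  seed = seed, ...)
}

passive_protocol <- function(seed = 1, velocity = 60, n_cycles = 2, ...) {
  protocol_config("passive", velocity = velocity, n_cycles = n_cycles,
                  seed = seed, ...)
}

# strain -> eta -> fit chain for one trial, given a calibrated profile
pipeline_fit <- function(trial, profile, endpoint_window = 1,
                         min_strain = 0.005, flexion_index = 2,
                         fit_range = c(50, 100)) {
  segs <- segment_flexions(trial)
  seg <- select_flexion(segs, flexion_index)
  rect <- rectify_circumference(seg, profile, endpoint_window = endpoint_window,
                                segments = segs)
  strain <- compute_strain(rect, profile)
  curve <- compute_eta(strain, min_strain = min_strain,
                       velocity = trial$protocol$velocity)
  list(strain = strain, curve = curve,
       fit = fit_log_eta(curve, fit_range = fit_range))
}

# bare eta curve for unit tests that bypass the preprocessing chain
make_eta_curve <- function(angle, eta, valid = rep(TRUE, length(angle)),
                           velocity = NA_real_) {
  out <- data.frame(angle = angle, eta = eta, strain = NA_real_,
                    torque = NA_real_, valid = valid)
  attr(out, "velocity") <- velocity
  class(out) <- c("eta_curve", class(out))
  out
}

# bare strain series for unit tests that bypass the preprocessing chain
make_strain_df <- function(angle, strain, torque = NA_real_,
                           valid = rep(TRUE, length(angle))) {
  data.frame(time = seq_along(angle), angle = angle, c_rect = NA_real_,
             strain = strain, torque = torque, valid = valid)
}
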