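test_that("make_subject is deterministic and enforces the inclusion rule", {
  expect_identical(make_subject(seed = 7), make_subject(seed = 7))
  expect_error(make_subject(seed = 1, overrides = list(s_max = 0.04)), "s_max")
  expect_error(make_subject(seed = 1, overrides = list(s_max = 0.31)), "s_max")
  expect_error(make_subject(seed = 1, overrides = list(drift_tau = -1)), "drift_tau")
  expect_error(make_subject(seed = 1, overrides = list(bogus = 1)), "unknown")
  smax <- vapply(1:1000, function(k) make_subject(seed = k)$s_max, numeric(1))
  expect_true(all(smax > 0.05 & smax <= 0.30))
})

test_that("connatural circumference is anchored, monotone and differentiable", {
  s <- make_subject(seed = 3)
  expect_equal(connatural_circumference(s, 90), s$c0_mid)
  expect_gt(connatural_circumference(s, 120), connatural_circumference(s, 30))
  grid <- seq(30, 120, by = 0.5)
  expect_true(all(diff(connatural_circumference(s, grid)) > 0))
  h <- 1e-4
  fd <- (connatural_circumference(s, 90 + h) -
           connatural_circumference(s, 90 - h)) / (2 * h)
  expect_equal(fd, s$c0_slope, tolerance = 1e-6)
  expect_error(connatural_circumference(s, 125), "out of range")
})

test_that("strain profile vanishes at the ROM limits and is unimodal", {
  for (p in c(1, 2)) {
    s <- make_subject(seed = 5, overrides = list(strain_shape_p = p))
    expect_equal(strain_profile(s, 30), 0)
    expect_equal(strain_profile(s, 120), 0)
    grid <- seq(30, 120, by = 0.1)
    prof <- strain_profile(s, grid)
    expect_equal(max(prof), s$s_max, tolerance = 1e-6)
    signs <- sign(diff(prof))
    expect_equal(sum(diff(signs[signs != 0]) != 0), 1)  # one rise->fall switch
  }
  expect_error(strain_profile(make_subject(seed = 5), 20), "out of range")
})

test_that("isokinetic trials have the protocol's phase structure and torque law", {
  s <- quiet_subject(seed = 42)
  for (cfg in list(c(90, 1.0), c(60, 1.5))) {
    tr <- simulate_isokinetic_trial(s, iso_protocol(velocity = cfg[1], seed = 1))
    gt <- tr$ground_truth
    # each flexion phase lasts span/velocity seconds
    runs <- rle(gt$flexion)
    flex_lens <- runs$lengths[runs$values]
    expect_equal(stats::median(flex_lens) / tr$protocol$sample_rate, cfg[2],
                 tolerance = 0.02)
    expect_equal(sum(runs$values), 4)  # four flexions in four cycles
  }
  # direct evaluation of the torque model at an exactly-sampled angle
  tr <- simulate_isokinetic_trial(s, iso_protocol(velocity = 90, seed = 1))
  k <- which(tr$ground_truth$flexion & abs(tr$angle - 75) < 1e-9)[1]
  expect_false(is.na(k))
  expect_equal(tr$torque[k],
               strain_profile(s, 75) * exp(s$a1_true * 75 + s$a2_true) *
                 eval_velocity_gain(s$velocity_gain, 90))
  # torque vanishes with strain at the ROM limits and during extensions
  expect_true(all(abs(tr$torque[tr$ground_truth$strain == 0]) < 1e-12))
  expect_error(simulate_isokinetic_trial(s, passive_protocol()), "mode")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  s <- make_subject(seed = 9)
  expect_identical(simulate_isokinetic_trial(s, iso_protocol(seed = 4)),
                   simulate_isokinetic_trial(s, iso_protocol(seed = 4)))
  expect_identical(simulate_passive_trial(s, passive_protocol(seed = 4)),
                   simulate_passive_trial(s, passive_protocol(seed = 4)))
  p <- protocol_config("isotonic", impedance = 0.3 * s$t120_max, seed = 4)
  expect_identical(simulate_isotonic_trial(s, p), simulate_isotonic_trial(s, p))
})

test_that("ground-truth eta is velocity-invariant under the null gain", {
  s <- quiet_subject(seed = 11)
  # 66 deg is sampled exactly at all three velocities (multiple of 3.6 deg)
  eta_at_66 <- vapply(c(60, 90, 120), function(v) {
    tr <- simulate_isokinetic_trial(s, iso_protocol(velocity = v, seed = 1))
    k <- which(tr$ground_truth$flexion & abs(tr$angle - 66) < 1e-9)[1]
    tr$ground_truth$eta[k]
  }, numeric(1))
  expect_equal(eta_at_66[1], eta_at_66[2])
  expect_equal(eta_at_66[2], eta_at_66[3])
})

test_that("passive trials are connatural circumference plus noise only", {
  s0 <- quiet_subject(seed = 13)
  tr0 <- simulate_passive_trial(s0, passive_protocol(seed = 2))
  expect_equal(tr0$circumference, connatural_circumference(s0, tr0$angle))
  expect_true(all(tr0$torque == 0))
  s1 <- make_subject(seed = 13)
  tr1 <- simulate_passive_trial(s1, passive_protocol(seed = 2))
  n <- length(tr1$torque)
  expect_lt(abs(mean(tr1$torque)), 3 * s1$noise_torque_sd / sqrt(n))
})

test_that("isotonic dynamics obey the rigid-body model", {
  s <- make_subject(seed = 42)
  # closed-form check: zero damping, constant surplus torque -> constant
  # angular acceleration surplus/inertia (in rad/s^2)
  surplus <- 2; imp <- 10; inertia <- 0.08
  fl <- flexitorque:::integrate_flexion(
    torque_fn = function(theta, omega, tloc) imp + surplus,
    inertia = inertia, damping = 0, impedance = imp, rom = c(30, 120),
    dt = 0.01, substeps = 1)
  alpha_deg <- (180 / pi) * surplus / inertia
  tt <- fl$time
  mid <- 2:(length(tt) - 1L)  # final sample is clipped at ROM-high
  expect_equal(fl$omega[mid], alpha_deg * tt[mid], tolerance = 1e-10)
  # forward-Euler position of a constant-acceleration ramp (exact recursion)
  pos <- 30 + alpha_deg * 0.01^2 * cumsum(seq_along(tt))
  expect_equal(fl$angle[mid], pos[mid - 1L], tolerance = 1e-8)

  p <- protocol_config("isotonic", impedance = 0.3 * s$t120_max, seed = 5)
  tr <- simulate_isotonic_trial(s, p)
  expect_true(all(tr$angle >= 30 - 1e-9 & tr$angle <= 120 + 1e-9))
  zero_strain <- tr$ground_truth$strain == 0
  expect_true(all(abs(tr$ground_truth$torque_clean[zero_strain]) < 1e-12))
  expect_error(
    simulate_isotonic_trial(s, protocol_config("isotonic",
                                               impedance = 1.5 * s$t120_max,
                                               seed = 1)),
    "infeasible")
  expect_error(simulate_isotonic_trial(s, iso_protocol()), "mode")
})

test_that("apply_drift has the stated saturating form", {
  tt <- seq(0, 120, by = 0.5)
  circ <- rep(300, length(tt))
  expect_identical(apply_drift(circ, tt, amp = 0, tau = 60), circ)
  d <- apply_drift(circ, tt, amp = 2, tau = 60)
  expect_equal(d[tt == 60] - 300, 2 * (1 - exp(-1)))
  expect_equal(d[length(d)] - 300, 2 * (1 - exp(-2)))
  expect_error(apply_drift(circ, tt, amp = 2, tau = 0), "tau")
  r1 <- apply_drift(circ, tt, amp = 1, tau = 60, seed = 3, rw_sd = 0.1)
  r2 <- apply_drift(circ, tt, amp = 1, tau = 60, seed = 3, rw_sd = 0.1)
  expect_identical(r1, r2)
  expect_false(identical(r1, d))
})
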