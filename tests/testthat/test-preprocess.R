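test_that("calibration round-trips the connatural profile", {
  s <- quiet_subject(seed = 21)
  tr <- simulate_passive_trial(s, passive_protocol(seed = 1))
  prof <- calibrate_connatural(tr)
  grid <- seq(30, 120, by = 0.25)
  expect_equal(predict(prof, grid), connatural_circumference(s, grid),
               tolerance = 1e-10)
  # averaging two identical trials changes nothing
  prof2 <- calibrate_connatural(list(tr, tr))
  expect_equal(prof2$c0, prof$c0)
  expect_error(predict(prof, 121), "out of range")
  expect_error(calibrate_connatural(simulate_isokinetic_trial(s, iso_protocol(seed = 1))),
               "passive")
})

test_that("calibration bin error shrinks roughly as 1/sqrt(n)", {
  err_for <- function(n_cycles, seed) {
    s <- make_subject(seed = 22)
    tr <- simulate_passive_trial(s, passive_protocol(seed = seed,
                                                     n_cycles = n_cycles))
    prof <- calibrate_connatural(tr)
    grid <- seq(35, 115, by = 1)
    sqrt(mean((predict(prof, grid) - connatural_circumference(s, grid))^2))
  }
  e_small <- mean(vapply(1:20, function(k) err_for(1, 100 + k), numeric(1)))
  e_large <- mean(vapply(1:20, function(k) err_for(8, 200 + k), numeric(1)))
  # 8x the samples per bin: expect close to sqrt(8) ~ 2.8x error reduction
  expect_gt(e_small / e_large, 1.8)
})

test_that("calibration reports coverage gaps", {
  s <- quiet_subject(seed = 23)
  narrow <- simulate_passive_trial(s, passive_protocol(seed = 1,
                                                       rom = c(30, 80)))
  expect_error(calibrate_connatural(narrow, rom = c(30, 120)), "coverage")
})

test_that("segmentation matches the brute-force extrema oracle", {
  s <- quiet_subject(seed = 24)
  for (v in c(60, 90, 120)) {
    tr <- simulate_isokinetic_trial(s, iso_protocol(velocity = v, seed = 1))
    segs <- segment_flexions(tr)
    expect_length(segs, 4)
    oracle <- oracle_flexion_bounds(tr$angle)
    # oracle rows whose rising sweep spans the ROM
    full <- oracle[tr$angle[oracle$end] - tr$angle[oracle$start] > 60, ]
    expect_equal(vapply(segs, `[[`, integer(1), "start"), full$start)
    expect_equal(vapply(segs, `[[`, integer(1), "end"), full$end)
  }
})

test_that("segmentation rejects sweeps that never rise", {
  prot <- passive_protocol(seed = 1)
  falling <- trial_recording(time = seq(0, 1.5, by = 0.01),
                             angle = seq(120, 30, length.out = 151),
                             torque = numeric(151),
                             circumference = rep(300, 151), prot)
  expect_error(segment_flexions(falling), "segmentation")
  expect_error(select_flexion(list(), 2), "only 0 found")
})

test_that("rectification endpoint identities hold", {
  s <- quiet_subject(seed = 25)
  tr <- simulate_isokinetic_trial(s, iso_protocol(seed = 1))
  prof <- calibrate_connatural(simulate_passive_trial(s, passive_protocol(seed = 2)))
  segs <- segment_flexions(tr)
  seg <- select_flexion(segs, 2)
  rect <- rectify_circumference(seg, prof, endpoint_window = 0, segments = segs)
  frame <- attr(rect, "frame")
  expect_equal(rect$c_rect[1], unname(frame["c0_lo"]))
  expect_equal(rect$c_rect[nrow(rect)], unname(frame["cbar"]))
  expect_equal(unname(frame["c0_lo"]), predict(prof, rect$angle[1]))
})

test_that("rectification is invariant to additive offsets (fixed frame)", {
  s <- make_subject(seed = 26)
  tr <- simulate_isokinetic_trial(s, iso_protocol(seed = 3))
  prof <- calibrate_connatural(simulate_passive_trial(s, passive_protocol(seed = 4)))
  segs <- segment_flexions(tr)
  seg <- select_flexion(segs, 2)
  base <- rectify_circumference(seg, prof, segments = segs)
  cbar <- unname(attr(base, "frame")["cbar"])
  shifted <- tr
  shifted$circumference <- tr$circumference + 5
  segs2 <- segment_flexions(shifted)
  seg2 <- select_flexion(segs2, 2)
  rect2 <- rectify_circumference(seg2, prof, cbar = cbar, segments = segs2)
  expect_equal(rect2$c_rect, base$c_rect, tolerance = 1e-10)
})

test_that("rectification suppresses baseline drift", {
  prot <- iso_protocol(seed = 5)
  s_drift <- make_subject(seed = 27, overrides = quiet_overrides(drift_amp = 3))
  s_clean <- make_subject(seed = 27, overrides = quiet_overrides())
  prof <- calibrate_connatural(
    simulate_passive_trial(s_clean, passive_protocol(seed = 6)))
  r_for <- function(s) {
    tr <- simulate_isokinetic_trial(s, prot)
    segs <- segment_flexions(tr)
    rectify_circumference(select_flexion(segs, 2), prof, segments = segs)
  }
  rd <- r_for(s_drift); rc <- r_for(s_clean)
  # paired drifted-vs-clean: differences stay at the drift scale (the frame
  # re-anchors to the trial's own average top), and after removing the
  # frame's affine component the shape distortion is an order of magnitude
  # smaller than the injected 3 mm drift
  d <- rd$c_rect - rc$c_rect
  expect_lt(max(abs(d)), 0.5)
  expect_lt(max(abs(stats::residuals(stats::lm(d ~ rc$c_rect)))), 0.05)

  # the operational benefit: flexions of one drifting trial agree with each
  # other after rectification far better than before
  tr <- simulate_isokinetic_trial(s_drift, prot)
  segs <- segment_flexions(tr)
  grid <- seq(35, 115, by = 1)
  spread <- function(m) max(apply(m, 1, function(x) diff(range(x))))
  rect_m <- sapply(seq_along(segs), function(k) {
    r <- rectify_circumference(segs[[k]], prof, segments = segs)
    stats::approx(r$angle, r$c_rect, grid)$y
  })
  raw_m <- sapply(seq_along(segs), function(k) {
    i <- segs[[k]]$start:segs[[k]]$end
    stats::approx(tr$angle[i], tr$circumference[i], grid)$y
  })
  expect_lt(spread(rect_m) * 10, spread(raw_m))
})

test_that("strain extraction recovers the generator's ground truth", {
  s <- quiet_subject(seed = 28)
  tr <- simulate_isokinetic_trial(s, iso_protocol(seed = 1))
  prof <- calibrate_connatural(simulate_passive_trial(s, passive_protocol(seed = 2)))
  segs <- segment_flexions(tr)
  seg <- select_flexion(segs, 2)
  strain <- compute_strain(
    rectify_circumference(seg, prof, endpoint_window = 0, segments = segs), prof)
  gt <- tr$ground_truth$strain[seg$start:seg$end]
  expect_lt(max(abs(strain$strain - gt)), 1e-12)
})

test_that("compute_strain evaluates the pointwise definition", {
  s <- quiet_subject(seed = 29)
  prof <- calibrate_connatural(simulate_passive_trial(s, passive_protocol(seed = 2)))
  theta <- seq(40, 110, by = 5)
  c0 <- predict(prof, theta)
  rect <- data.frame(time = seq_along(theta), angle = theta,
                     c_rect = c0, torque = 0)
  expect_equal(compute_strain(rect, prof)$strain, rep(0, length(theta)))
  rect$c_rect <- 1.1 * c0
  expect_equal(compute_strain(rect, prof)$strain, rep(0.1, length(theta)),
               tolerance = 1e-12)
})

test_that("passive trials carry zero-mean strain after calibration", {
  s <- make_subject(seed = 30)
  prof <- calibrate_connatural(simulate_passive_trial(s, passive_protocol(seed = 7)))
  tr <- simulate_passive_trial(s, passive_protocol(seed = 8))
  # passive sweeps have no flexion torque; evaluate strain directly on the
  # raw circumference against the profile
  inside <- tr$angle > 31 & tr$angle < 119
  strain <- (tr$circumference[inside] - predict(prof, tr$angle[inside])) /
    predict(prof, tr$angle[inside])
  n <- sum(inside)
  expect_lt(abs(mean(strain)),
            4 * (s$noise_circ_sd / s$c0_mid) / sqrt(n) + 1e-4)
})

test_that("normalize_strain produces beta in [0, 1] up to noise", {
  s <- quiet_subject(seed = 31)
  tr <- simulate_isokinetic_trial(s, iso_protocol(seed = 1))
  prof <- calibrate_connatural(simulate_passive_trial(s, passive_protocol(seed = 2)))
  segs <- segment_flexions(tr)
  strain <- compute_strain(
    rectify_circumference(select_flexion(segs, 2), prof, endpoint_window = 0,
                          segments = segs), prof)
  inner <- strain[strain$angle > 31 & strain$angle < 119, ]
  beta <- normalize_strain(inner, function(a) strain_profile(s, a))
  expect_equal(max(beta$beta[beta$valid]), 1, tolerance = 1e-6)
  sflat <- normalize_strain(strain, s$s_max)
  expect_equal(max(sflat$beta), 1, tolerance = 1e-6)
  expect_true(all(sflat$beta <= 1 + 1e-9))
  expect_error(normalize_strain(strain, 0), "positive")
})
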