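#' Study configuration
#'
#' Bundles every knob of the end-to-end study replica. Defaults mirror the
#' experimental protocol: 13 subjects, ROM 30-120 deg, isokinetic sets at
#' 60/90/120 deg/s (two sets each), isotonic sets at 30% and 40% of the
#' subject's peak torque at 120 deg/s (two sets each), four
#' extension-flexion cycles per set, analysis of the 2nd flexion, log-linear
#' fits over 50-100 deg.
#'
#' @param n_subjects cohort size (default 13).
#' @param seed top-level RNG seed; all per-trial seeds are fanned out from
#'   it deterministically.
#' @param velocities isokinetic velocities in deg/s.
#' @param impedance_frac isotonic impedance levels as fractions of the
#'   subject's peak torque at 120 deg/s.
#' @param rom range of motion in degrees.
#' @param fit_range log-linear fit interval in degrees.
#' @param eval_range error-evaluation interval in degrees.
#' @param min_strain strain mask threshold for the eta curves.
#' @param n_cycles cycles per set.
#' @param sample_rate sampling rate in Hz.
#' @param flexion_index which flexion of each set is analysed (default 2).
#' @param n_isokinetic_sets sets per velocity (default 2; the 1st trains the
#'   model, the 2nd is predicted. With a single set, training-only outputs
#'   are produced).
#' @param include_isotonic simulate and evaluate isotonic trials.
#' @param velocity_effect `NULL` for the null world (constant gain), a
#'   number for an affine gain with that `g(120)/g(60)` ratio, or any
#'   [velocity_gain_constant()]-style object.
#' @param subject_overrides named list forwarded to [make_subject()] for
#'   every subject (e.g. zero noise).
#' @param endpoint_window rectification endpoint window in degrees.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 13, seed = 1,
                         velocities = c(60, 90, 120),
                         impedance_frac = c(0.30, 0.40),
                         rom = c(30, 120), fit_range = c(50, 100),
                         eval_range = c(50, 100), min_strain = 0.005,
                         n_cycles = 4, sample_rate = 100,
                         flexion_index = 2, n_isokinetic_sets = 2,
                         include_isotonic = TRUE, velocity_effect = NULL,
                         subject_overrides = list(), endpoint_window = 1) {
  check_num(n_subjects, "n_subjects", lower = 1)
  check_num(velocities, "velocities", lower = 0, open_lower = TRUE,
            len = length(velocities))
  if (length(velocities) < 2L) {
    stop_invariant("velocities", "need at least 2 velocities for the ANOVA")
  }
  check_num(fit_range, "fit_range", len = 2L)
  if (fit_range[1] < rom[1] || fit_range[2] > rom[2]) {
    stop_invariant("fit_range", "fit range must lie within the ROM")
  }
  gain <- if (is.null(velocity_effect)) velocity_gain_constant(1)
          else if (is.numeric(velocity_effect) && length(velocity_effect) == 1L)
            velocity_gain_affine(ratio = velocity_effect)
          else as_velocity_gain(velocity_effect)
  structure(list(n_subjects = as.integer(n_subjects), seed = seed,
                 velocities = velocities, impedance_frac = impedance_frac,
                 rom = rom, fit_range = fit_range, eval_range = eval_range,
                 min_strain = min_strain, n_cycles = n_cycles,
                 sample_rate = sample_rate, flexion_index = flexion_index,
                 n_isokinetic_sets = as.integer(n_isokinetic_sets),
                 include_isotonic = include_isotonic, velocity_gain = gain,
                 subject_overrides = subject_overrides,
                 endpoint_window = endpoint_window),
            class = "study_config")
}

# strain series of the chosen flexion of one trial
process_trial <- function(trial, profile, config, segments = NULL) {
  segs <- segments %||% segment_flexions(trial)
  seg <- select_flexion(segs, config$flexion_index)
  rect <- rectify_circumference(seg, profile,
                                endpoint_window = config$endpoint_window,
                                segments = segs)
  compute_strain(rect, profile)
}

#' Run the full study replica
#'
#' For every synthetic subject: simulate a passive calibration trial and
#' calibrate the connatural profile; simulate the isokinetic sets, extract
#' the chosen flexion's strain and eta curve and fit `ln eta` per velocity;
#' train the averaged-eta torque model from the 1st isokinetic sets only;
#' predict the 2nd isokinetic sets and all isotonic sets; evaluate the five
#' error indicators per subject and mode. Cohort-level outputs are the
#' velocity ANOVA of `a1`/`a2` (groups = subjects' 1st-set fits per
#' velocity), a per-subject ANOVA table (both sets, 2 fits per velocity)
#' and the error summary table with its `Mean +/- Std` row.
#'
#' Reproducibility: a single top-level seed fans out to one seed per
#' subject and trial slot via one `sample.int` draw, so runs with the same
#' configuration are byte-identical.
#'
#' @param config a [study_config()].
#' @return An object of class `study_report`.
#' @export
run_study <- function(config = study_config()) {
  n <- config$n_subjects
  n_slots <- 2L + config$n_isokinetic_sets * length(config$velocities) +
    2L * length(config$impedance_frac)
  seeds <- withr::with_seed(config$seed,
                            matrix(sample.int(2147483646L, n * n_slots),
                                   nrow = n))
  fits <- NULL
  table1 <- NULL
  iso_reports <- list(); isot_reports <- list()
  subjects <- vector("list", n)

  for (i in seq_len(n)) {
    slot <- 1L
    nxt <- function() { s <- seeds[i, slot]; slot <<- slot + 1L; s }
    ov <- config$subject_overrides
    ov$velocity_gain <- config$velocity_gain
    ov$rom <- config$rom
    subject <- make_subject(seed = nxt(), overrides = ov)
    subjects[[i]] <- subject

    passive <- simulate_passive_trial(subject, protocol_config(
      "passive", rom = config$rom, velocity = 60, n_cycles = 2,
      sample_rate = config$sample_rate, seed = nxt()))
    profile <- calibrate_connatural(passive)

    curves <- list(); subj_fits <- NULL
    for (set in seq_len(config$n_isokinetic_sets)) {
      for (v in config$velocities) {
        trial <- simulate_isokinetic_trial(subject, protocol_config(
          "isokinetic", rom = config$rom, velocity = v,
          n_cycles = config$n_cycles, sample_rate = config$sample_rate,
          seed = nxt()))
        strain <- process_trial(trial, profile, config)
        curve <- compute_eta(strain, min_strain = config$min_strain,
                             velocity = v,
                             trial_id = sprintf("s%02d_iso%g_set%d", i, v, set))
        fit <- fit_log_eta(curve, fit_range = config$fit_range)
        subj_fits <- rbind(subj_fits,
                           data.frame(subject = i, velocity = v, set = set,
                                      a1 = fit$a1, a2 = fit$a2,
                                      rms = fit$rms, n = fit$n))
        curves[[sprintf("v%g_set%d", v, set)]] <-
          list(curve = curve, strain = strain, set = set, velocity = v)
      }
    }
    fits <- rbind(fits, subj_fits)

    if (config$n_isokinetic_sets >= 2L) {
      pa <- lapply(c("a1", "a2"), function(p) velocity_anova(subj_fits, p))
      table1 <- rbind(table1, data.frame(subject = i,
                                         p_a1 = pa[[1]]$p_value,
                                         p_a2 = pa[[2]]$p_value))
      train_curves <- lapply(Filter(function(cv) cv$set == 1L, curves),
                             `[[`, "curve")
      model <- train_torque_model(train_curves)
      pool <- list(m = numeric(0), c = numeric(0), a = numeric(0))
      for (cv in Filter(function(x) x$set == 2L, curves)) {
        pr <- predict_torque(cv$strain, model)
        ok <- pr$valid
        pool$m <- c(pool$m, pr$torque_meas[ok])
        pool$c <- c(pool$c, pr$torque_pred[ok])
        pool$a <- c(pool$a, pr$angle[ok])
      }
      iso_reports[[i]] <- error_metrics(pool$m, pool$c, pool$a,
                                        eval_range = config$eval_range)

      if (config$include_isotonic) {
        pool <- list(m = numeric(0), c = numeric(0), a = numeric(0))
        for (frac in config$impedance_frac) {
          for (set in 1:2) {
            trial <- simulate_isotonic_trial(subject, protocol_config(
              "isotonic", rom = config$rom,
              impedance = frac * subject$t120_max,
              n_cycles = config$n_cycles, sample_rate = config$sample_rate,
              seed = nxt()))
            strain <- process_trial(trial, profile, config)
            pr <- predict_torque(strain, model)
            ok <- pr$valid
            pool$m <- c(pool$m, pr$torque_meas[ok])
            pool$c <- c(pool$c, pr$torque_pred[ok])
            pool$a <- c(pool$a, pr$angle[ok])
          }
        }
        isot_reports[[i]] <- error_metrics(pool$m, pool$c, pool$a,
                                           eval_range = config$eval_range)
      }
    }
  }

  set1 <- fits[fits$set == 1L, ]
  anova_a1 <- velocity_anova(set1, "a1")
  anova_a2 <- velocity_anova(set1, "a2")

  cohort <- NULL
  if (length(iso_reports)) {
    modes <- list(isokinetic = iso_reports)
    if (length(isot_reports)) modes$isotonic <- isot_reports
    cohort <- cohort_report(modes, subject_ids = as.character(seq_len(n)))
  }
  structure(list(config = config, fits = fits, table1 = table1,
                 anova_a1 = anova_a1, anova_a2 = anova_a2,
                 cohort = cohort, subjects = subjects),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects, velocities {%s} deg/s\n",
              x$config$n_subjects, paste(x$config$velocities, collapse = ", ")))
  cat(sprintf("  cohort ANOVA: p_a1 = %.4f, p_a2 = %.4f (eta^2 %.4f / %.4f)\n",
              x$anova_a1$p_value, x$anova_a2$p_value,
              x$anova_a1$eta_squared, x$anova_a2$eta_squared))
  if (!is.null(x$cohort)) print(x$cohort)
  invisible(x)
}

#' Write a study report bundle to disk
#'
#' Emits `table1.csv` (per-subject ANOVA p-values), `table2.csv`
#' (per-subject `r_rms`/`r_m` by mode with a final `Mean +/- Std` row),
#' `fits.csv`, `anova.json` (cohort-level tests) and `manifest.json`.
#' Output is deterministic: no timestamps, fixed formatting.
#'
#' @param report a [run_study()] report.
#' @param dir output directory (created if needed).
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$fits, file.path(dir, "fits.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(report$table1)) {
    t1 <- report$table1
    t1$p_a1 <- fmt_num(t1$p_a1); t1$p_a2 <- fmt_num(t1$p_a2)
    utils::write.csv(t1, file.path(dir, "table1.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(report$cohort)) {
    tab <- report$cohort$table
    num_cols <- setdiff(names(tab), "subject")
    tab[num_cols] <- lapply(tab[num_cols], fmt_num)
    ms <- vapply(num_cols, function(cl) {
      paste0(fmt_num(report$cohort$summary[[cl]][1]), " ± ",
             fmt_num(report$cohort$summary[[cl]][2]))
    }, character(1))
    tab <- rbind(tab, c("Mean ± Std", ms))
    utils::write.csv(tab, file.path(dir, "table2.csv"), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  jsonlite::write_json(
    list(cohort_anova = list(
           a1 = list(F = report$anova_a1$F, p = report$anova_a1$p_value,
                     eta_squared = report$anova_a1$eta_squared,
                     effect = report$anova_a1$effect_label),
           a2 = list(F = report$anova_a2$F, p = report$anova_a2$p_value,
                     eta_squared = report$anova_a2$eta_squared,
                     effect = report$anova_a2$effect_label))),
    file.path(dir, "anova.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(n_subjects = report$config$n_subjects, seed = report$config$seed,
         velocities = report$config$velocities,
         impedance_frac = report$config$impedance_frac,
         rom = report$config$rom, fit_range = report$config$fit_range,
         files = c("fits.csv",
                   if (!is.null(report$table1)) "table1.csv",
                   if (!is.null(report$cohort)) "table2.csv",
                   "anova.json")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
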