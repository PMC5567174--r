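#' Torque prediction error indicators
#'
#' The five standard indicators comparing measured (`T_m`) and calculated
#' (`T_c`) torque, restricted to the evaluation angle range (default
#' 50-100 deg, the stable range of the dynamometer):
#' \itemize{
#'   \item `cc` -- Pearson correlation coefficient;
#'   \item `r_ma` -- maximum absolute error, `max |T_m - T_c|` (N.m);
#'   \item `r_mr` -- maximum relative error, `max |(T_m - T_c)/T_m|`,
#'     computed over samples with `|T_m|` above `tm_floor`;
#'   \item `r_rms` -- root-mean-square error (N.m);
#'   \item `r_m` -- mean relative error, `r_rms / mean(T_m)`.
#' }
#' Degenerate cases (zero variance, zero mean torque, no sample above the
#' relative-error floor) yield `NA` for the affected indicator rather than
#' an error.
#'
#' @param measured measured torque series (N.m).
#' @param predicted calculated torque series, aligned with `measured`.
#' @param angle elbow angle per sample (deg).
#' @param eval_range evaluation interval in degrees, default `c(50, 100)`.
#' @param tm_floor minimum `|T_m|` (N.m) for a sample to enter `r_mr`.
#' @return An object of class `error_report` with fields `cc`, `r_ma`,
#'   `r_mr`, `r_rms`, `r_m`, `eval_range`, `n`.
#' @export
error_metrics <- function(measured, predicted, angle,
                          eval_range = c(50, 100), tm_floor = 0.5) {
  n0 <- length(measured)
  if (length(predicted) != n0 || length(angle) != n0) {
    stop("measured, predicted and angle must be aligned", call. = FALSE)
  }
  sel <- in_closed(angle, eval_range) & is.finite(measured) & is.finite(predicted)
  if (sum(sel) < 2L) {
    stop("insufficient data: fewer than 2 aligned samples in the evaluation range",
         call. = FALSE)
  }
  tm <- measured[sel]; tc <- predicted[sel]
  err <- tm - tc
  cc <- if (stats::sd(tm) > 0 && stats::sd(tc) > 0) stats::cor(tm, tc) else NA_real_
  r_ma <- max(abs(err))
  rel_ok <- abs(tm) >= tm_floor
  r_mr <- if (any(rel_ok)) max(abs(err[rel_ok] / tm[rel_ok])) else NA_real_
  r_rms <- sqrt(mean(err^2))
  r_m <- if (abs(mean(tm)) > .Machine$double.eps^0.5) r_rms / mean(tm) else NA_real_
  structure(list(cc = cc, r_ma = r_ma, r_mr = r_mr, r_rms = r_rms, r_m = r_m,
                 eval_range = eval_range, n = length(tm)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> n=%d over [%g, %g] deg\n", x$n,
              x$eval_range[1], x$eval_range[2]))
  cat(sprintf("  C.C=%.4f  r_ma=%.4f N.m  r_mr=%.4f  r_rms=%.4f N.m  r_m=%.4f\n",
              x$cc, x$r_ma, x$r_mr, x$r_rms, x$r_m))
  invisible(x)
}

#' Cohort error summary
#'
#' Aggregates per-subject error reports by mode into the familiar study
#' table: one row per subject with `r_rms` and `r_m` per mode, plus a
#' `Mean +/- Std` row (arithmetic mean, sample standard deviation over
#' subjects; the SD is `NA` for a single subject).
#'
#' @param reports_by_mode named list; each element is a list of
#'   [error_metrics()] reports, one per subject, in subject order. All
#'   modes must cover the same subjects.
#' @param subject_ids optional subject labels.
#' @return An object of class `cohort_report`: `table` (data frame, one row
#'   per subject) and `summary` (mean and sd of each column).
#' @export
cohort_report <- function(reports_by_mode, subject_ids = NULL) {
  if (!length(reports_by_mode) || is.null(names(reports_by_mode))) {
    stop("reporting error: reports_by_mode must be a non-empty named list",
         call. = FALSE)
  }
  ns <- unique(lengths(reports_by_mode))
  if (length(ns) != 1L || ns == 0L) {
    stop("reporting error: every mode needs the same non-zero number of subjects",
         call. = FALSE)
  }
  subject_ids <- subject_ids %||% as.character(seq_len(ns))
  tab <- data.frame(subject = subject_ids)
  for (mode in names(reports_by_mode)) {
    reps <- reports_by_mode[[mode]]
    tab[[paste0(mode, "_r_rms")]] <- vapply(reps, `[[`, numeric(1), "r_rms")
    tab[[paste0(mode, "_r_m")]] <- vapply(reps, `[[`, numeric(1), "r_m")
  }
  num_cols <- setdiff(names(tab), "subject")
  summary <- data.frame(
    stat = c("mean", "sd"),
    rbind(vapply(tab[num_cols], mean, numeric(1)),
          vapply(tab[num_cols], function(x)
            if (length(x) > 1L) stats::sd(x) else NA_real_, numeric(1))))
  names(summary) <- c("stat", num_cols)
  structure(list(table = tab, summary = summary), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 4, ...) {
  tab <- x$table
  num_cols <- setdiff(names(tab), "subject")
  disp <- tab
  disp[num_cols] <- lapply(disp[num_cols], fmt_num, digits = digits)
  ms <- vapply(num_cols, function(cl) {
    paste0(fmt_num(x$summary[[cl]][1], digits), " ± ",
           fmt_num(x$summary[[cl]][2], digits))
  }, character(1))
  disp <- rbind(disp, c("Mean ± Std", ms))
  print(disp, row.names = FALSE)
  invisible(x)
}
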