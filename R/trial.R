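#' Trial recordings
#'
#' A `trial_recording` bundles the three synchronised channels of one
#' dynamometer trial -- elbow angle (deg), joint torque (N.m, already
#' gravity-corrected) and upper-arm circumference (mm) -- with the protocol
#' metadata. Simulated trials additionally carry a `ground_truth` data frame
#' (clean strain, eta and torque at every sample) used by the recovery tests.
#'
#' @param time strictly increasing sample times in seconds.
#' @param angle elbow angle in degrees.
#' @param torque joint torque in N.m.
#' @param circumference upper-arm circumference in mm.
#' @param protocol a [protocol_config()].
#' @param subject_id subject label.
#' @param ground_truth optional data frame of per-sample ground truth.
#' @param subject optional [make_subject()] object (synthetic trials only).
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(time, angle, torque, circumference, protocol,
                            subject_id = "unknown", ground_truth = NULL,
                            subject = NULL) {
  n <- length(time)
  if (length(angle) != n || length(torque) != n || length(circumference) != n) {
    stop_invariant("channels", "time, angle, torque and circumference must have equal length")
  }
  if (n > 1 && any(diff(time) <= 0)) {
    stop_invariant("time", "sample times must be strictly increasing")
  }
  if (!inherits(protocol, "protocol_config")) {
    stop("protocol must be a protocol_config", call. = FALSE)
  }
  check_rom(angle, protocol$rom, tol = 1e-6)
  structure(list(time = time, angle = angle, torque = torque,
                 circumference = circumference, protocol = protocol,
                 subject_id = subject_id, ground_truth = ground_truth,
                 subject = subject),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s, %s, %d samples over %.2f s\n",
              x$subject_id, x$protocol$mode, length(x$time),
              diff(range(x$time))))
  cat(sprintf("  angle [%.1f, %.1f] deg, torque peak %.2f N.m, circumference [%.1f, %.1f] mm\n",
              min(x$angle), max(x$angle), max(x$torque),
              min(x$circumference), max(x$circumference)))
  invisible(x)
}

#' @export
as.data.frame.trial_recording <- function(x, ...) {
  data.frame(time_s = x$time, angle_deg = x$angle, torque_Nm = x$torque,
             circumference_mm = x$circumference)
}

#' Read and write trial CSV files
#'
#' Trials travel as UTF-8 CSV with the header
#' `time_s, angle_deg, torque_Nm, circumference_mm`, one file per trial.
#'
#' @param trial a [trial_recording()].
#' @param path file path.
#' @param protocol protocol to attach on read; if `NULL` a permissive
#'   passive protocol covering the observed angle range is inferred.
#' @param subject_id subject label to attach on read.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns a [trial_recording()] (without ground truth).
#' @export
write_trial_csv <- function(trial, path) {
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path, protocol = NULL, subject_id = "unknown") {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_s", "angle_deg", "torque_Nm", "circumference_mm")
  if (!all(need %in% names(df))) {
    stop(sprintf("trial CSV must contain columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(protocol)) {
    protocol <- protocol_config("passive",
                                rom = c(floor(min(df$angle_deg)),
                                        ceiling(max(df$angle_deg))),
                                velocity = 60,
                                sample_rate = 1 / stats::median(diff(df$time_s)))
  }
  trial_recording(df$time_s, df$angle_deg, df$torque_Nm, df$circumference_mm,
                  protocol, subject_id = subject_id)
}
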