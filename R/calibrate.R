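#' Calibrate the connatural circumference profile
#'
#' Pools all samples of one or more passive trials, averages the measured
#' circumference in angle bins across the ROM, and returns a continuous
#' profile C0(theta). Within each bin the grid point is placed at the mean
#' sample angle (not the geometric bin centre), which makes the calibration
#' exact for locally linear profiles; evaluation interpolates linearly and
#' extrapolates linearly from the edge pairs out to the ROM limits.
#'
#' @param passive_trials a [trial_recording()] or list of them; all must be
#'   passive mode.
#' @param bin_width angle bin width in degrees (default 1).
#' @param rom range of motion; taken from the first trial's protocol if
#'   `NULL`.
#' @return An object of class `connatural_profile` with fields `angle`
#'   (grid, deg), `c0` (mm), `rom`, `bin_width`, `n_per_bin`.
#' @export
calibrate_connatural <- function(passive_trials, bin_width = 1, rom = NULL) {
  if (inherits(passive_trials, "trial_recording")) {
    passive_trials <- list(passive_trials)
  }
  if (!length(passive_trials)) stop("no passive trials supplied", call. = FALSE)
  for (tr in passive_trials) {
    if (!inherits(tr, "trial_recording") || tr$protocol$mode != "passive") {
      stop("calibration requires passive-mode trial recordings", call. = FALSE)
    }
  }
  rom <- rom %||% passive_trials[[1L]]$protocol$rom
  angle <- unlist(lapply(passive_trials, `[[`, "angle"))
  circ <- unlist(lapply(passive_trials, `[[`, "circumference"))
  keep <- in_closed(angle, rom, tol = 1e-6)
  angle <- angle[keep]; circ <- circ[keep]

  edges <- seq(rom[1], rom[2], by = bin_width)
  if (edges[length(edges)] < rom[2]) edges <- c(edges, rom[2])
  bin <- findInterval(angle, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  if (any(counts == 0L)) {
    gaps <- which(counts == 0L)
    stop(sprintf(
      "calibration coverage error: no passive samples in angle bin(s) %s",
      paste(sprintf("[%g,%g]", edges[gaps], edges[gaps + 1L]), collapse = ", ")),
      call. = FALSE)
  }
  grid <- as.numeric(tapply(angle, bin, mean))
  c0 <- as.numeric(tapply(circ, bin, mean))
  ord <- order(grid)
  grid <- grid[ord]; c0 <- c0[ord]
  if (any(c0 <= 0)) stop_invariant("c0", "calibrated circumference must be positive")
  structure(list(angle = grid, c0 = c0, rom = rom, bin_width = bin_width,
                 n_per_bin = counts[ord]),
            class = "connatural_profile")
}

#' Evaluate a connatural profile at arbitrary angles
#'
#' @param object a [calibrate_connatural()] profile.
#' @param angle angles in degrees; must lie within the profile's ROM.
#' @param ... unused.
#' @return circumference in mm.
#' @export
predict.connatural_profile <- function(object, angle, ...) {
  check_rom(angle, object$rom, tol = 1e-6)
  interp_linear(object$angle, object$c0, angle)
}

#' @export
print.connatural_profile <- function(x, ...) {
  cat(sprintf("<connatural_profile> %d bins over [%g, %g] deg, C0 in [%.1f, %.1f] mm\n",
              length(x$angle), x$rom[1], x$rom[2], min(x$c0), max(x$c0)))
  invisible(x)
}

#' Read and write connatural profiles as CSV
#'
#' Columns: `angle_deg, c0_mm`; the ROM and bin width are stored in a
#' comment-free side header row read back from the data range.
#'
#' @param profile a `connatural_profile`.
#' @param path file path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(angle_deg = profile$angle, c0_mm = profile$c0),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @param rom ROM to attach on read; defaults to the span of the grid.
#' @export
read_profile_csv <- function(path, rom = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("angle_deg", "c0_mm") %in% names(df))) {
    stop("profile CSV must contain columns angle_deg, c0_mm", call. = FALSE)
  }
  rom <- rom %||% c(floor(min(df$angle_deg)), ceiling(max(df$angle_deg)))
  structure(list(angle = df$angle_deg, c0 = df$c0_mm, rom = rom,
                 bin_width = stats::median(diff(df$angle_deg)),
                 n_per_bin = rep(NA_integer_, nrow(df))),
            class = "connatural_profile")
}
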