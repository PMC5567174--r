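#' Segment a trial into flexion sweeps
#'
#' Detects the monotone rising sweeps of the angle channel (flexions, angle
#' increasing from near ROM-low to near ROM-high). Turnarounds are found by
#' a zig-zag scan with hysteresis on a lightly smoothed angle signal, then
#' refined to the exact local extrema of the raw signal, so on noiseless
#' triangular trajectories the boundaries coincide with the brute-force
#' argmin/argmax of each cycle.
#'
#' @param trial a [trial_recording()].
#' @param hysteresis reversal threshold in degrees before a turnaround is
#'   committed (default 2).
#' @param smooth_window smoothing window for turnaround detection, in
#'   seconds (default 0.05).
#' @param min_span_frac minimum fraction of the ROM a rising sweep must
#'   cover to count as a flexion (default 0.7; isotonic flexions can stall
#'   slightly short of ROM-high).
#' @return A list of `flexion_segment` objects, ordered in time. Each holds
#'   `start`/`end` sample indices into the trial, the 1-based `cycle` index
#'   and a reference to the parent trial.
#' @export
segment_flexions <- function(trial, hysteresis = 2, smooth_window = 0.05,
                             min_span_frac = 0.7) {
  a <- trial$angle
  n <- length(a)
  rate <- trial$protocol$sample_rate
  k <- max(1L, round(smooth_window * rate))
  sm <- moving_average(a, k)

  tp <- zigzag_turnpoints(sm, hysteresis)
  # refine each turnpoint to the raw-signal extremum in its neighbourhood
  half <- max(k, 2L)
  for (i in seq_along(tp$idx)) {
    lo <- max(1L, tp$idx[i] - half)
    hi <- min(n, tp$idx[i] + half)
    win <- lo:hi
    tp$idx[i] <- if (tp$type[i] == "max") win[which.max(a[win])] else win[which.min(a[win])]
  }

  span_min <- min_span_frac * diff(trial$protocol$rom)
  segs <- list()
  cyc <- 0L
  i <- 1L
  while (i < length(tp$idx)) {
    if (tp$type[i] == "min" && tp$type[i + 1L] == "max" &&
        a[tp$idx[i + 1L]] - a[tp$idx[i]] >= span_min) {
      cyc <- cyc + 1L
      segs[[cyc]] <- structure(list(start = tp$idx[i], end = tp$idx[i + 1L],
                                    cycle = cyc, trial = trial),
                               class = "flexion_segment")
    }
    i <- i + 1L
  }
  if (!length(segs)) {
    stop("segmentation error: no complete flexion sweep found", call. = FALSE)
  }
  segs
}

# alternating-extremum scan: commits an extremum once the signal has moved
# against it by more than `hyst`; the series endpoints are included
zigzag_turnpoints <- function(x, hyst) {
  n <- length(x)
  idx <- integer(0); type <- character(0)
  dir <- 0L            # +1 rising (tracking a max), -1 falling, 0 unknown
  ext_i <- 1L
  for (i in 2:n) {
    if (dir >= 0L) {
      if (x[i] >= x[ext_i]) {
        ext_i <- i
        if (dir == 0L && x[i] - x[1L] > hyst) dir <- 1L
      } else if (x[ext_i] - x[i] > hyst) {
        if (dir == 0L) {
          idx <- c(idx, 1L); type <- c(type, if (ext_i == 1L) "max" else "min")
          if (ext_i != 1L) { idx <- c(idx, ext_i); type <- c(type, "max") }
        } else {
          idx <- c(idx, ext_i); type <- c(type, "max")
        }
        dir <- -1L; ext_i <- i
      }
    } else {
      if (x[i] <= x[ext_i]) {
        ext_i <- i
      } else if (x[i] - x[ext_i] > hyst) {
        idx <- c(idx, ext_i); type <- c(type, "min")
        dir <- 1L; ext_i <- i
      }
    }
  }
  if (dir == 0L) {   # never moved beyond the hysteresis band
    return(list(idx = integer(0), type = character(0)))
  }
  if (!length(idx) || idx[1L] != 1L) {
    # open with the starting point as the opposite extremum
    first_type <- if ((length(type) && type[1L] == "max") || (!length(type) && dir == 1L)) "min" else "max"
    idx <- c(1L, idx); type <- c(first_type, type)
  }
  idx <- c(idx, ext_i); type <- c(type, if (dir == 1L) "max" else "min")
  list(idx = idx, type = type)
}

#' Select one flexion from a segmentation
#'
#' The analysis convention is to use the 2nd flexion of each trial: the
#' fabric sensor's first cycle is not repeatable, and later cycles carry
#' more accumulated resistance-relaxation drift.
#'
#' @param segments result of [segment_flexions()].
#' @param index 1-based flexion index (default 2).
#' @export
select_flexion <- function(segments, index = 2L) {
  if (index < 1L || index > length(segments)) {
    stop(sprintf("flexion %d requested but only %d found", index,
                 length(segments)), call. = FALSE)
  }
  segments[[index]]
}

#' @export
print.flexion_segment <- function(x, ...) {
  a <- x$trial$angle
  cat(sprintf("<flexion_segment> cycle %d, samples %d..%d, angle %.1f -> %.1f deg\n",
              x$cycle, x$start, x$end, a[x$start], a[x$end]))
  invisible(x)
}
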