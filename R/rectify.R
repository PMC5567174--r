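#' Rectify the measured circumference of one flexion
#'
#' Fabric strain sensors drift slowly (resistance relaxation), so absolute
#' circumference values are unreliable over a 20-30 minute session. Each
#' flexion is therefore mapped affinely onto a fixed frame: the measured
#' span between the flexion's start (ROM-low, relaxed) and end (ROM-high,
#' torque back to zero) is fitted to the frame `[C0(low), Cbar(high)]`,
#' where `C0(low)` comes from the calibrated connatural profile and
#' `Cbar(high)` is the average measured circumference at the
#' flexion-to-extension turnarounds across the whole trial:
#'
#'   `c_rect = (C - C_lo) / (C_hi - C_lo) * (Cbar - C0(low)) + C0(low)`
#'
#' The map is exactly invariant to any additive constant on the measured
#' series (for a fixed frame), which is what removes the baseline drift.
#'
#' @param segment a `flexion_segment` from [segment_flexions()].
#' @param profile a [calibrate_connatural()] profile.
#' @param endpoint_window half-width in degrees of the window used to read
#'   the segment's endpoint circumferences `C_lo`, `C_hi` (default 1; `0`
#'   uses the single apex sample, appropriate for noiseless data).
#' @param cbar frame constant `Cbar(high)` in mm; computed from all flexion
#'   turnarounds of the parent trial when `NULL`.
#' @param segments optional precomputed [segment_flexions()] result for the
#'   parent trial, used only to compute `cbar` (avoids re-segmentation).
#' @return A data frame of class `rectified_series` with columns `time`,
#'   `angle`, `c_meas`, `c_rect`, `torque`, and the frame constants in
#'   attributes.
#' @export
rectify_circumference <- function(segment, profile, endpoint_window = 1,
                                  cbar = NULL, segments = NULL) {
  trial <- segment$trial
  idx <- segment$start:segment$end
  theta <- trial$angle[idx]
  C <- trial$circumference[idx]
  theta_lo <- theta[1L]
  theta_hi <- theta[length(theta)]

  c_lo <- endpoint_value(theta, C, theta_lo, endpoint_window, head = TRUE)
  c_hi <- endpoint_value(theta, C, theta_hi, endpoint_window, head = FALSE)
  span <- c_hi - c_lo
  if (abs(span) < 1e-9 * max(1, abs(c_hi))) {
    stop("rectification error: flat circumference signal over the flexion",
         call. = FALSE)
  }
  if (is.null(cbar)) {
    segs <- segments %||% segment_flexions(trial)
    tops <- vapply(segs, function(sg) {
      th <- trial$angle[sg$start:sg$end]
      cc <- trial$circumference[sg$start:sg$end]
      endpoint_value(th, cc, th[length(th)], endpoint_window, head = FALSE)
    }, numeric(1))
    cbar <- mean(tops)
  }
  c0_lo <- predict(profile, theta_lo)
  c_rect <- (C - c_lo) / span * (cbar - c0_lo) + c0_lo

  out <- data.frame(time = trial$time[idx], angle = theta, c_meas = C,
                    c_rect = c_rect, torque = trial$torque[idx])
  attr(out, "frame") <- c(c_lo = c_lo, c_hi = c_hi, cbar = cbar, c0_lo = c0_lo)
  attr(out, "segment") <- c(start = segment$start, end = segment$end,
                            cycle = segment$cycle)
  class(out) <- c("rectified_series", class(out))
  out
}

# mean circumference over the samples whose angle lies within `window`
# degrees of the segment end; window 0 takes the single end sample
endpoint_value <- function(theta, C, apex, window, head) {
  if (window <= 0) {
    return(if (head) C[1L] else C[length(C)])
  }
  sel <- abs(theta - apex) <= window
  mean(C[sel])
}

#' Extract the voluntary circumferential strain
#'
#' Pointwise strain relative to the connatural profile:
#' `s = (c_rect(theta) - C0(theta)) / C0(theta)`. Samples whose angle falls
#' outside the profile's ROM, or with non-finite inputs, are masked rather
#' than dropped.
#'
#' @param rectified a [rectify_circumference()] result (any data frame with
#'   `angle` and `c_rect` columns works).
#' @param profile a [calibrate_connatural()] profile covering the segment.
#' @return A data frame of class `strain_series` with columns `time`,
#'   `angle`, `c_rect`, `strain`, `torque`, `valid`.
#' @export
compute_strain <- function(rectified, profile) {
  theta <- rectified$angle
  inside <- in_closed(theta, profile$rom, tol = 1e-6)
  if (!any(inside)) {
    stop("out-of-range error: no samples inside the profile's ROM", call. = FALSE)
  }
  c0 <- rep(NA_real_, length(theta))
  c0[inside] <- predict(profile, theta[inside])
  s <- (rectified$c_rect - c0) / c0
  valid <- inside & is.finite(s)
  out <- data.frame(time = rectified$time %||% seq_along(theta),
                    angle = theta, c_rect = rectified$c_rect, strain = s,
                    torque = rectified$torque %||% NA_real_, valid = valid)
  attr(out, "frame") <- attr(rectified, "frame")
  attr(out, "segment") <- attr(rectified, "segment")
  class(out) <- c("strain_series", class(out))
  out
}

#' Normalised strain
#'
#' `beta = s / s_max(theta)`, the strain normalised by the subject's
#' maximum-effort strain at the same angle; plays the role of an activation
#' level. Exposed for completeness -- the trained torque model uses the raw
#' strain.
#'
#' @param strain a [compute_strain()] series.
#' @param s_max_profile either a single positive number or a function of
#'   angle returning the maximum strain.
#' @return the input with a `beta` column added.
#' @export
normalize_strain <- function(strain, s_max_profile) {
  smax <- if (is.function(s_max_profile)) s_max_profile(strain$angle)
          else rep(s_max_profile, nrow(strain))
  if (any(!is.finite(smax) | smax <= 0)) {
    stop("parameter error: s_max_profile must be positive over the segment",
         call. = FALSE)
  }
  strain$beta <- strain$strain / smax
  strain
}
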