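#' Combined torque-angle/torque-velocity factor
#'
#' The central quantity of the analysis: `eta = T / s`, torque per unit
#' circumferential strain (N.m). Because the strain vanishes at both ROM
#' limits, eta blows up there; samples with strain below `min_strain` are
#' masked, as are samples where the ratio is non-positive or non-finite
#' (the curve's validity mask guarantees `eta > 0` wherever it is true, so
#' the logarithm downstream is always defined).
#'
#' @param strain a [compute_strain()] series.
#' @param torque torque series aligned with `strain`; defaults to the
#'   `torque` column carried by the strain series.
#' @param min_strain minimum strain fraction for a valid sample
#'   (default 0.005).
#' @param velocity optional angular velocity label (deg/s) stored as
#'   provenance.
#' @param trial_id optional provenance label.
#' @return A data frame of class `eta_curve` with columns `angle`, `eta`,
#'   `strain`, `torque`, `valid`.
#' @export
compute_eta <- function(strain, torque = NULL, min_strain = 0.005,
                        velocity = NA_real_, trial_id = NA_character_) {
  torque <- torque %||% strain$torque
  if (length(torque) != nrow(strain)) {
    stop("torque series must be aligned with the strain series", call. = FALSE)
  }
  s <- strain$strain
  eta <- torque / s
  valid <- strain$valid & is.finite(s) & s >= min_strain &
    is.finite(eta) & eta > 0
  if (!any(valid)) {
    stop("degenerate input: no valid samples after strain masking", call. = FALSE)
  }
  out <- data.frame(angle = strain$angle, eta = eta, strain = s,
                    torque = torque, valid = valid)
  attr(out, "min_strain") <- min_strain
  attr(out, "velocity") <- velocity
  attr(out, "trial_id") <- trial_id
  class(out) <- c("eta_curve", class(out))
  out
}

#' Log-linear fit of the combined factor against angle
#'
#' Ordinary least squares of `log(eta)` on the elbow angle, restricted to
#' the fit range (default the stable range 50-100 deg) and the curve's
#' validity mask: `ln eta = a1 * theta + a2`. The log base is configurable;
#' the averaged-eta model and the velocity ANOVA conclusions are invariant
#' to it, only the scale of `(a1, a2)` changes.
#'
#' @param curve an [compute_eta()] curve.
#' @param fit_range angle interval in degrees, default `c(50, 100)`.
#' @param log_base base of the logarithm (default `exp(1)`).
#' @return An object of class `loglinear_fit`: `a1` (per degree), `a2`
#'   (intercept), `fit_range`, `rms` (residual RMS in log units), `n`,
#'   `log_base`, `velocity` (provenance).
#' @export
fit_log_eta <- function(curve, fit_range = c(50, 100), log_base = exp(1)) {
  sel <- curve$valid & in_closed(curve$angle, fit_range)
  if (sum(sel) < 2L) {
    stop("insufficient data: fewer than 2 valid samples in the fit range",
         call. = FALSE)
  }
  eta <- curve$eta[sel]
  if (any(eta <= 0)) {
    stop("domain error: non-positive eta inside the fit range", call. = FALSE)
  }
  theta <- curve$angle[sel]
  y <- log(eta) / log(log_base)
  # centred least squares for numerical stability
  mth <- mean(theta)
  a1 <- sum((theta - mth) * (y - mean(y))) / sum((theta - mth)^2)
  a2 <- mean(y) - a1 * mth
  resid <- y - (a1 * theta + a2)
  structure(list(a1 = a1, a2 = a2, fit_range = fit_range,
                 rms = sqrt(mean(resid^2)), n = length(y),
                 log_base = log_base,
                 velocity = attr(curve, "velocity"),
                 trial_id = attr(curve, "trial_id")),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat(sprintf("<loglinear_fit> log eta = %.6f * theta + %.4f  (base %s, [%g, %g] deg, n=%d, rms=%.4g)\n",
              x$a1, x$a2,
              if (abs(x$log_base - exp(1)) < 1e-12) "e" else format(x$log_base),
              x$fit_range[1], x$fit_range[2], x$n, x$rms))
  invisible(x)
}

# evaluate the fitted eta(theta) back on the natural scale
eta_from_fit <- function(fit, angle) {
  fit$log_base^(fit$a1 * angle + fit$a2)
}
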