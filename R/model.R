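#' Train the averaged-eta torque model
#'
#' With the torque-velocity factor reduced to a constant, the combined
#' factor is a function of angle only and can be averaged across training
#' flexions: `eta_bar(theta) = mean_i eta_i(theta)`. Curves are resampled
#' onto a common angle grid by linear interpolation within each curve's
#' valid range; a grid point is valid only where every input curve
#' contributes (the intersection of valid ranges).
#'
#' @param curves an [compute_eta()] curve or list of them.
#' @param grid common angle grid in degrees. `NULL` (default) uses the
#'   curve's own valid angles for a single curve, and a 1-degree grid over
#'   the intersection of valid ranges for several curves.
#' @return An object of class `torque_model`: `angle`, `eta_bar` (N.m),
#'   `valid`, and training metadata (`n_curves`, `velocities`, `trial_ids`).
#' @export
train_torque_model <- function(curves, grid = NULL) {
  if (inherits(curves, "eta_curve")) curves <- list(curves)
  if (!length(curves)) stop("training error: no eta curves supplied", call. = FALSE)
  vranges <- lapply(curves, function(cv) range(cv$angle[cv$valid]))
  lo <- max(vapply(vranges, `[`, numeric(1), 1L))
  hi <- min(vapply(vranges, `[`, numeric(1), 2L))
  if (lo >= hi) {
    stop("training error: empty intersection of valid angle ranges", call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- if (length(curves) == 1L) {
      sort(curves[[1L]]$angle[curves[[1L]]$valid])
    } else {
      seq(ceiling(lo), floor(hi), by = 1)
    }
  }
  vals <- vapply(curves, function(cv) {
    ok <- cv$valid
    stats::approx(cv$angle[ok], cv$eta[ok], xout = grid, rule = 1,
                  ties = "mean")$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  valid <- rowSums(is.na(vals)) == 0L
  if (!any(valid)) {
    stop("training error: no grid point covered by all curves", call. = FALSE)
  }
  eta_bar <- rowMeans(vals)
  structure(list(angle = grid, eta_bar = eta_bar, valid = valid,
                 n_curves = length(curves),
                 velocities = vapply(curves, function(cv)
                   as.numeric(attr(cv, "velocity") %||% NA_real_), numeric(1)),
                 trial_ids = vapply(curves, function(cv)
                   as.character(attr(cv, "trial_id") %||% NA_character_),
                   character(1))),
            class = "torque_model")
}

#' Predict torque from strain with a trained model
#'
#' `T(theta) = s(theta) * eta_bar(theta)`. The model is never extrapolated:
#' samples whose angle falls outside the model's valid range are masked
#' (`strict = TRUE` turns that into an error instead), as are samples
#' masked in the strain series.
#'
#' @param strain a [compute_strain()] series.
#' @param model a [train_torque_model()] model.
#' @param strict error (rather than mask) when a valid strain sample falls
#'   outside the model range.
#' @return A data frame with columns `time`, `angle`, `strain`,
#'   `torque_pred`, `torque_meas` (the strain series' aligned torque, for
#'   convenience in evaluation) and `valid`.
#' @export
predict_torque <- function(strain, model, strict = FALSE) {
  vr <- range(model$angle[model$valid])
  inside <- in_closed(strain$angle, vr)
  if (strict && any(strain$valid & !inside)) {
    stop(sprintf(
      "out-of-range error: strain samples outside the model's valid range [%g, %g] deg",
      vr[1], vr[2]), call. = FALSE)
  }
  ok <- model$valid
  eta_hat <- rep(NA_real_, nrow(strain))
  eta_hat[inside] <- stats::approx(model$angle[ok], model$eta_bar[ok],
                                   xout = strain$angle[inside], rule = 1,
                                   ties = "mean")$y
  valid <- strain$valid & inside & is.finite(eta_hat)
  pred <- strain$strain * eta_hat
  data.frame(time = strain$time, angle = strain$angle, strain = strain$strain,
             torque_pred = pred, torque_meas = strain$torque, valid = valid)
}

#' @export
print.torque_model <- function(x, ...) {
  vr <- range(x$angle[x$valid])
  cat(sprintf("<torque_model> eta_bar from %d curve(s), valid over [%.1f, %.1f] deg, %.1f-%.1f N.m\n",
              x$n_curves, vr[1], vr[2], min(x$eta_bar[x$valid]),
              max(x$eta_bar[x$valid])))
  invisible(x)
}

#' Read and write torque models
#'
#' The model travels as `model.csv` (`angle_deg, eta_bar_Nm, valid`) plus a
#' `model.json` sidecar with the training metadata.
#'
#' @param model a [train_torque_model()] model.
#' @param dir directory to write into (created if needed).
#' @export
write_torque_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(angle_deg = model$angle,
                              eta_bar_Nm = model$eta_bar,
                              valid = as.integer(model$valid)),
                   file.path(dir, "model.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_curves = model$n_curves,
                            velocities = model$velocities,
                            trial_ids = model$trial_ids),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_torque_model
#' @export
read_torque_model <- function(dir) {
  df <- utils::read.csv(file.path(dir, "model.csv"))
  meta_path <- file.path(dir, "model.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(list(angle = df$angle_deg, eta_bar = df$eta_bar_Nm,
                 valid = as.logical(df$valid),
                 n_curves = meta$n_curves %||% NA_integer_,
                 velocities = unlist(meta$velocities) %||% NA_real_,
                 trial_ids = unlist(meta$trial_ids) %||% NA_character_),
            class = "torque_model")
}
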