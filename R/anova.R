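#' One-way ANOVA of fitted parameters across angular velocities
#'
#' Classical fixed-effects single-factor analysis of variance of the
#' log-linear fit parameters (`a1` slopes or `a2` intercepts) grouped by
#' angular velocity, used to test whether the combined factor depends on
#' velocity. Reports the F statistic, the p-value and the eta-squared
#' effect size with its Cohen band label.
#'
#' @param fits either a data frame with columns `velocity`, `a1`, `a2`
#'   (one row per fitted flexion) or a list of [fit_log_eta()] objects
#'   carrying a `velocity` provenance field.
#' @param parameter which parameter to test, `"a1"` or `"a2"`.
#' @return An object of class `anova_result`: `parameter`, `groups`
#'   (velocity labels), `values` (list of group values), `F`, `df`,
#'   `p_value`, `eta_squared`, `effect_label`.
#' @export
velocity_anova <- function(fits, parameter = c("a1", "a2")) {
  parameter <- match.arg(parameter)
  if (is.data.frame(fits)) {
    df <- fits
  } else {
    df <- do.call(rbind, lapply(fits, function(f) {
      data.frame(velocity = f$velocity %||% NA_real_, a1 = f$a1, a2 = f$a2)
    }))
  }
  if (!all(c("velocity", parameter) %in% names(df))) {
    stop("fits must provide 'velocity' and the requested parameter", call. = FALSE)
  }
  groups <- split(df[[parameter]], df$velocity)
  check_groups(groups, min_per_group = 2L)
  ss <- anova_sums(groups)
  k <- length(groups); N <- ss$N
  # variance at the level of floating-point dust (e.g. noiseless simulations
  # where every fit is bit-near-identical) is an identical-groups case, not
  # a meaningful F ratio
  gm <- mean(unlist(groups, use.names = FALSE))
  if (ss$sst < N * (1e-9 * (abs(gm) + 1e-300))^2) {
    Fstat <- 0; p <- 1
    ss$ssb <- 0; ss$sst <- 1
  } else {
    Fstat <- (ss$ssb / (k - 1)) / (ss$ssw / (N - k))
    p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  }
  structure(list(parameter = parameter, groups = names(groups),
                 values = groups, F = Fstat, df = c(k - 1, N - k),
                 p_value = p, eta_squared = ss$ssb / ss$sst,
                 effect_label = cohen_label(ss$ssb / ss$sst)),
            class = "anova_result")
}

check_groups <- function(groups, min_per_group = 2L) {
  if (length(groups) < 2L) {
    stop("insufficient replication: need at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < min_per_group)) {
    stop(sprintf("insufficient replication: every group needs >= %d values",
                 min_per_group), call. = FALSE)
  }
  invisible(groups)
}

anova_sums <- function(groups) {
  all_v <- unlist(groups, use.names = FALSE)
  N <- length(all_v)
  gm <- mean(all_v)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  sst <- ssb + ssw
  if (sst <= 0) {
    stop("degenerate data: zero total variance", call. = FALSE)
  }
  list(ssb = ssb, ssw = ssw, sst = sst, N = N)
}

#' Eta-squared effect size with Cohen band label
#'
#' `eta^2 = SS_between / SS_total`, labelled by Cohen's conventional bands
#' for eta-squared: small 0.01, medium 0.06, large 0.14.
#'
#' @param groups a list of numeric vectors (one per group).
#' @return list with `eta_squared` and `label`.
#' @export
effect_size <- function(groups) {
  check_groups(groups, min_per_group = 1L)
  ss <- anova_sums(groups)
  es <- ss$ssb / ss$sst
  list(eta_squared = es, label = cohen_label(es))
}

cohen_label <- function(es) {
  if (es < 0.01) "negligible"
  else if (es < 0.06) "small"
  else if (es < 0.14) "medium"
  else "large"
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s across velocities {%s}\n", x$parameter,
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4f, eta^2 = %.4f (%s)\n",
              x$df[1], x$df[2], x$F, x$p_value, x$eta_squared,
              x$effect_label))
  invisible(x)
}
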