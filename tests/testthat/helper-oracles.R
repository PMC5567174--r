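# Independent brute-force oracles. These deliberately go through different
# code paths than the package (stats::lm / stats::aov and direct formula
# transcriptions) so agreement is informative.

# least squares of y on x via lm's QR decomposition
oracle_ols <- function(x, y) {
  cf <- stats::coef(stats::lm(y ~ x))
  list(a1 = unname(cf[2]), a2 = unname(cf[1]))
}

# one-way ANOVA via aov's model-based decomposition
oracle_anova <- function(values, groups) {
  tab <- summary(stats::aov(values ~ factor(groups)))[[1]]
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       eta_squared = tab[1, "Sum Sq"] / sum(tab[, "Sum Sq"]))
}

# direct transcription of the five error indicators
oracle_metrics <- function(tm, tc, angle, lo = 50, hi = 100, floor = 0.5) {
  keep <- angle >= lo & angle <= hi
  tm <- tm[keep]; tc <- tc[keep]
  rel <- abs(tm) >= floor
  rms <- sqrt(sum((tm - tc)^2) / length(tm))
  list(cc = suppressWarnings(stats::cor(tm, tc)),
       r_ma = max(abs(tm - tc)),
       r_mr = if (any(rel)) max(abs((tm[rel] - tc[rel]) / tm[rel])) else NA_real_,
       r_rms = rms,
       r_m = rms / mean(tm))
}

# brute-force flexion boundaries of a cyclic angle wave: local minima and
# maxima located by exhaustive scan of the finite differences
oracle_flexion_bounds <- function(angle) {
  n <- length(angle)
  d <- diff(angle)
  rising <- d > 0
  starts <- which(c(rising[1], !rising[-length(rising)] & rising[-1]))
  ends <- which(c(rising[-length(rising)] & !rising[-1], rising[length(rising)])) + 1L
  data.frame(start = starts, end = ends[seq_along(starts)])
}

# interpolate-then-average oracle for the eta_bar model
oracle_eta_bar <- function(curves, grid) {
  mat <- sapply(curves, function(cv) {
    ok <- cv$valid
    stats::approx(cv$angle[ok], cv$eta[ok], xout = grid, rule = 1)$y
  })
  rowMeans(mat)
}
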