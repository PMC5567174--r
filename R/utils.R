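`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar checks used by the constructors; each failure names the violated
# constraint so callers can surface it verbatim
stop_invariant <- function(name, msg) {
  stop(sprintf("invariant violated [%s]: %s", name, msg), call. = FALSE)
}

check_num <- function(x, name, lower = -Inf, upper = Inf,
                      open_lower = FALSE, open_upper = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_invariant(name, sprintf("must be a numeric vector of length %d", len))
  }
  lo_ok <- if (open_lower) all(x > lower) else all(x >= lower)
  hi_ok <- if (open_upper) all(x < upper) else all(x <= upper)
  if (!lo_ok || !hi_ok) {
    stop_invariant(name, sprintf(
      "must lie in %s%g, %g%s, got %s",
      if (open_lower) "(" else "[", lower, upper,
      if (open_upper) ")" else "]", paste(signif(x, 6), collapse = ", ")))
  }
  invisible(x)
}

in_closed <- function(x, rng, tol = 0) x >= rng[1] - tol & x <= rng[2] + tol

# centred moving average; window k forced odd, edges use shrunken windows
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# linear interpolation with *linear* (not flat) extrapolation from the edge
# pairs; exact for affine signals all the way to the evaluation limits
interp_linear <- function(x, y, xout) {
  n <- length(x)
  if (n < 2L) stop("need at least two points to interpolate", call. = FALSE)
  out <- stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
  below <- xout < x[1L]
  above <- xout > x[n]
  if (any(below)) {
    s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    out[below] <- y[1L] + s * (xout[below] - x[1L])
  }
  if (any(above)) {
    s <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    out[above] <- y[n] + s * (xout[above] - x[n])
  }
  out
}

fmt_num <- function(x, digits = 4) formatC(x, format = "f", digits = digits)
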