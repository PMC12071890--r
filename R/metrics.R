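#' Mean absolute error between two volumes (HU)
#'
#' @param a,b [image_volume()]s on the same grid.
#' @param mask optional logical array restricting the comparison (default:
#'   all voxels).
#' @return mean of |a - b| over the mask.
#' @export
mae <- function(a, b, mask = NULL) {
  vol_check(a); vol_check(b)
  stop_unless_same_grid(a, b)
  d <- abs(a$data - b$data)
  if (is.null(mask)) return(mean(d))
  if (!any(mask)) stop("empty mask")
  mean(d[mask])
}

#' Universal quality index (Wang-Bovik)
#'
#' `Q = 4 cov(a,b) mean(a) mean(b) / ((var(a)+var(b)) (mean(a)^2+mean(b)^2))`,
#' in \[-1, 1\] with 1 for identical images. `global` evaluates the formula
#' once over the whole grid (population moments); `windowed` averages Q over
#' sliding windows, skipping windows with zero denominator.
#'
#' @param a,b [image_volume()]s on the same grid.
#' @param mode "global" or "windowed".
#' @param window window edge length for windowed mode (default 8).
#' @param mask optional logical array (global mode only).
#' @return UQI in \[-1, 1\].
#' @export
uqi <- function(a, b, mode = c("global", "windowed"), window = 8, mask = NULL) {
  mode <- match.arg(mode)
  vol_check(a); vol_check(b)
  stop_unless_same_grid(a, b)
  if (mode == "windowed") {
    if (!is.null(mask)) stop("mask is only supported in global mode")
    return(cpp_uqi_win(a$data, b$data, as.integer(window)))
  }
  x <- if (is.null(mask)) as.vector(a$data) else a$data[mask]
  y <- if (is.null(mask)) as.vector(b$data) else b$data[mask]
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cv <- mean((x - mx) * (y - my))
  den <- (vx + vy) * (mx^2 + my^2)
  if (den == 0) stop("UQI undefined for two constant images (degenerate input)")
  4 * cv * mx * my / den
}

#' Lin's concordance correlation coefficient
#'
#' Agreement (not just correlation) between paired measurements:
#' `2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population (1/n)
#' moments.
#'
#' @param x,y numeric vectors of equal length (>= 2), not both constant.
#' @return CCC in \[-1, 1\].
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("CCC needs at least 2 paired values")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0) stop("CCC undefined for two constant sequences")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Qualitative agreement band for a CCC value
#'
#' Above 0.99: near-perfect; 0.95 to 0.99: substantial; 0.90 to 0.95:
#' moderate; below 0.90: poor. Boundaries are closed on the lower edge of
#' each named interval (0.90 is "moderate", 0.95 "substantial", 0.99
#' "near-perfect").
#'
#' @param value CCC in \[-1, 1\].
#' @return one of "near-perfect", "substantial", "moderate", "poor".
#' @export
ccc_band <- function(value) {
  if (!is.finite(value) || value < -1 || value > 1)
    stop("CCC value must lie in [-1, 1]")
  if (value >= 0.99) "near-perfect"
  else if (value >= 0.95) "substantial"
  else if (value >= 0.90) "moderate"
  else "poor"
}

#' Per-case metric summary (mean +/- SD)
#'
#' @param values numeric vector of per-case metric values.
#' @return list with `mean`, `sd`, `n` and the per-case `values`.
#' @export
metric_summary <- function(values) {
  list(mean = mean(values), sd = if (length(values) > 1) sd(values) else 0,
       n = length(values), values = values)
}
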