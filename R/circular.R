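#' Circular (phase) utilities
#'
#' Phase angles are handled on the half-open interval (-pi, pi] under the
#' cosine convention: 0 rad is an oscillation peak, pi rad a trough.
#' `wrap_phase()` maps arbitrary angles into that interval; `circ_diff()`
#' returns the signed shortest angular difference `a - b`, so its magnitude
#' never exceeds pi.
#'
#' @param x,a,b Angles in radians (any real value, vectorised).
#' @return Angles in radians in (-pi, pi].
#' @examples
#' wrap_phase(2 * pi)          # 0
#' circ_diff(pi - 0.1, -pi + 0.1)  # -0.2: shortest arc crosses +/-pi
#' @export
wrap_phase <- function(x) {
  stopifnot(is.numeric(x))
  if (any(!is.finite(x))) abort("phases must be finite", class = "phasestim_data_error")
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps onto [-pi, pi); fold the single boundary point so pi stays pi
  w[w == -pi] <- pi
  w
}

#' @rdname wrap_phase
#' @export
circ_diff <- function(a, b) wrap_phase(a - b)

#' Circular mean, resultant length, and quartile interval
#'
#' `circ_mean()` is the argument of the mean resultant vector,
#' `circ_r()` its length (0 = uniform, 1 = concentrated). `circ_quartiles()`
#' rotates the sample onto its circular mean, takes linear quartiles of the
#' signed deviations, and rotates back, giving a (Q1, Q3) dispersion
#' interval around the mean direction.
#'
#' @param x Angles in radians.
#' @param na.rm Drop missing values first.
#' @return `circ_mean()` and `circ_r()` return a scalar; `circ_quartiles()`
#'   a named numeric vector `c(q1, q3)` in (-pi, pi].
#' @export
circ_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  Arg(sum(exp(1i * x)))
}

#' @rdname circ_mean
#' @export
circ_r <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  Mod(mean(exp(1i * x)))
}

#' @rdname circ_mean
#' @export
circ_quartiles <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  m <- circ_mean(x)
  d <- circ_diff(x, m)
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  out <- wrap_phase(m + q)
  names(out) <- c("q1", "q3")
  out
}

#' Circular root-mean-square error between two phase series
#'
#' RMS of the wrapped differences; insensitive to whole-cycle offsets.
#'
#' @param a,b Angles in radians, equal length.
#' @param na.rm Drop pairs with missing values.
#' @return Scalar RMSE in radians, in `[0, pi]`.
#' @export
circ_rmse <- function(a, b, na.rm = FALSE) {
  d <- circ_diff(a, b)
  if (na.rm) d <- d[!is.na(d)]
  sqrt(mean(d^2))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle against a unimodal alternative, using the classical approximation
#' to the distribution of the resultant length.
#'
#' @param x Angles in radians.
#' @return A list with `statistic` (Rayleigh z = n * rbar^2), `r` (mean
#'   resultant length), `n`, and `p.value`.
#' @export
rayleigh_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) abort("need at least 2 angles", class = "phasestim_data_error")
  rbar <- circ_r(x)
  R <- n * rbar
  z <- R^2 / n
  # Zar's approximation; accurate for moderate n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(statistic = z, r = rbar, n = n, p.value = min(1, max(0, p)))
}
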