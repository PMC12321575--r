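#' Wrap angles to the half-open interval [-pi, pi)
#'
#' All angles in the package live on `[-pi, pi)`. Wrapping is the identity for
#' angles already in range.
#'
#' @param x Numeric vector of angles (radians).
#' @return Numeric vector of the same length, wrapped to `[-pi, pi)`.
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Circular mean of a set of angles
#'
#' The argument of the mean unit vector. Returns `NA` when the mean resultant
#' length is numerically zero (the mean direction is undefined).
#'
#' @param x Numeric vector of angles (radians).
#' @return A single angle in `[-pi, pi)`, or `NA_real_`.
#' @export
circ_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  s <- sum(sin(x)); c <- sum(cos(x))
  if (sqrt(s^2 + c^2) < .Machine$double.eps * length(x)) return(NA_real_)
  wrap_angle(atan2(s, c))
}

#' Vector strength (mean resultant length) of a set of angles
#'
#' Each angle is treated as a unit vector; the modulus of their mean is
#' returned. This equals 1 minus the circular variance, and is the measure
#' used for head-direction encoding accuracy: 1 means all offsets agree,
#' 0 means they are uninformative.
#'
#' @param angles Numeric vector of angles (radians); must be non-empty after
#'   removing `NA`s.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' vector_strength(c(0, 0, 0))        # 1
#' vector_strength(c(0, pi))          # 0
#' vector_strength(c(0, pi / 2))      # sqrt(2)/2
vector_strength <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0L) {
    stop("vector_strength() needs at least one non-missing angle")
  }
  sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
}

#' Signed circular difference a - b on [-pi, pi)
#' @param a,b Numeric vectors of angles (radians).
#' @return Wrapped differences.
#' @export
circ_diff <- function(a, b) wrap_angle(a - b)

# Centered running mean with a span of `span` samples, truncated at the ends.
# For even spans the extra sample sits on the right of the center.
running_mean <- function(x, span) {
  stopifnot(span >= 1)
  n <- length(x)
  left <- floor((span - 1) / 2)
  right <- span - 1 - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Deterministic sub-stream seeds from one root seed, so that e.g. toggling
# velocity noise does not perturb the heading draw. Kept below 2^31.
derive_seeds <- function(seed, labels) {
  stopifnot(length(seed) == 1, is.finite(seed))
  base <- as.double(seed %% 2147483647L)
  out <- vapply(seq_along(labels), function(i) {
    h <- (base * 48271 + i * 1299709) %% 2147483563
    as.integer(h %% 2147483000 + 1)
  }, integer(1))
  names(out) <- labels
  out
}
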