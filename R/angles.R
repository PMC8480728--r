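#' Wrap angles to the canonical range
#'
#' All angles in the package live on `[-pi, pi)`. Every function that returns
#' an angle wraps it through this single utility.
#'
#' @param theta numeric vector of angles, radians.
#' @return numeric vector of the same length, wrapped to `[-pi, pi)`.
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # %% can return 2*pi - eps for tiny negative remainders; re-fold exactly
  out[out >= pi] <- out[out >= pi] - 2 * pi
  out
}

#' Unwrap a sampled phase series
#'
#' Removes the 2*pi jumps from a densely sampled, wrapped phase series so
#' that drift accumulates monotonically.
#'
#' @param theta numeric vector of wrapped angles, radians.
#' @return numeric vector of unwrapped angles.
#' @export
unwrap_angle <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  jumps <- -2 * pi * cumsum(round(d / (2 * pi)))
  theta + c(0, jumps)
}

# circular difference a - b folded to [-pi, pi)
circ_diff <- function(a, b) wrap_angle(a - b)
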