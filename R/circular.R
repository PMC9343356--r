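# Circular geometry on the 360-degree shape wheel.
#
# All angles are in degrees.  Positions live in [0, 360); signed errors in
# (-180, 180] with positive = clockwise.

#' Reduce angles onto the shape wheel
#'
#' Maps arbitrary angles (degrees) onto the wheel domain `[0, 360)`.
#' 360 maps to 0.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 360)`.
#' @examples
#' wrap360(c(-10, 360, 725))
#' @export
wrap360 <- function(x) {
  stopifnot(is.numeric(x))
  out <- x %% 360
  # guard against 360 - eps rounding artefacts from %% on negative input
  out[out >= 360] <- 0
  out
}

#' Shortest signed angular displacement
#'
#' Signed displacement from `b` to `a` along the wheel, in `(-180, 180]`
#' degrees.  Positive values are clockwise.  The antipodal tie (exactly 180
#' degrees apart) resolves to +180 by convention, so
#' `signed_delta(a, b) == -signed_delta(b, a)` everywhere except at 180.
#'
#' @param a,b Numeric vectors of wheel positions (degrees); recycled.
#' @return Numeric vector of signed errors in `(-180, 180]`.
#' @examples
#' signed_delta(10, 0)   # +10
#' signed_delta(350, 0)  # -10
#' signed_delta(180, 0)  # +180 by convention
#' @export
signed_delta <- function(a, b) {
  d <- (a - b) %% 360
  d - 360 * (d > 180)
}

#' Absolute circular error
#'
#' `abs(signed_delta(a, b))`, in `[0, 180]` degrees.  For a response drawn
#' uniformly on the wheel the expected absolute error is 90 degrees, the
#' paradigm's chance level.
#'
#' @inheritParams signed_delta
#' @return Numeric vector in `[0, 180]`.
#' @export
abs_error <- function(a, b) {
  abs(signed_delta(a, b))
}

#' Circular mean of wheel positions
#'
#' Direction of the (optionally weighted) vector resultant.  For tightly
#' clustered values this reduces to the arithmetic mean.  When the resultant
#' length is (numerically) zero -- e.g. `{0, 180}` unweighted -- the mean
#' direction is undefined and an error is signalled rather than guessing.
#'
#' @param values Numeric vector of wheel positions (degrees), length >= 1.
#' @param weights Optional nonnegative weights, same length, not all zero.
#' @param tol Tolerance on the mean resultant length below which the mean is
#'   declared undefined.
#' @return A single wheel position in `[0, 360)`.
#' @examples
#' circ_mean(c(10, 356))  # 3, the clustered-average limit across 0
#' @export
circ_mean <- function(values, weights = NULL, tol = 1e-8) {
  stopifnot(is.numeric(values), length(values) >= 1L, !anyNA(values))
  if (is.null(weights)) {
    weights <- rep(1, length(values))
  }
  stopifnot(length(weights) == length(values), all(weights >= 0))
  wsum <- sum(weights)
  if (wsum <= 0) stop("weights must not be all zero")
  rad <- values * pi / 180
  cc <- sum(weights * cos(rad)) / wsum
  ss <- sum(weights * sin(rad)) / wsum
  if (sqrt(cc^2 + ss^2) < tol) {
    stop("undefined circular mean: resultant length below tolerance")
  }
  wrap360(atan2(ss, cc) * 180 / pi)
}

#' Running cumulative circular means of ordered bets
#'
#' Element `k` is the unweighted circular mean of bets `1..k`; element 1
#' equals bet 1.  The error of these running means against the target is the
#' "cumulative error" curve: its decrease with `k` indicates that later bets
#' add information beyond a single point estimate.
#'
#' @param bets Numeric vector of ordered bet centers (degrees).
#' @inheritParams circ_mean
#' @return Numeric vector, same length as `bets`, of wheel positions.
#' @examples
#' # a first bet 10 deg clockwise and a second 4 deg counterclockwise of a
#' # target at 0 average to 3 deg clockwise
#' cumulative_means(c(10, 356))
#' @export
cumulative_means <- function(bets, tol = 1e-8) {
  stopifnot(is.numeric(bets), length(bets) >= 1L)
  vapply(seq_along(bets), function(k) circ_mean(bets[seq_len(k)], tol = tol),
         numeric(1))
}

#' Rotate an uncertainty profile around the wheel
#'
#' Circle-shifts a 360-bin profile so that bin `i` of the output holds bin
#' `(i + shift) mod 360` of the input.  Used to align trial profiles on the
#' target (shift by the target's bin) before averaging across trials.  Mass
#' is conserved exactly.
#'
#' @param profile Numeric vector of 360 nonnegative bin heights
#'   (bin `i + 1` covers integer degree `i`).
#' @param shift Integer degrees to shift by.
#' @return The rotated profile (numeric vector of 360 heights).
#' @export
rotate_profile <- function(profile, shift) {
  stopifnot(is.numeric(profile), length(profile) == 360L,
            length(shift) == 1L, shift == round(shift))
  profile[(((0:359) + shift) %% 360) + 1L]
}
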