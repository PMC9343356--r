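# The per-trial uncertainty profile: penalized sums of wrapped Gaussian bets
# on the 360-bin wheel, and the points rule that scores them.

#' Scoring-rule parameters for the betting game
#'
#' Bundles the constants of the betting paradigm: each bet adds a wrapped
#' Gaussian component (sd 4 degrees on the shape space); the first bet is
#' twice as tall as bets 2-6; stacking is discouraged by scaling each new
#' component by `1 - y(b)^exponent`, where `y(b)` is the profile height
#' already present at the bet position `b`; the trial earns
#' `500 * height at the target`.
#'
#' The height of the unscaled ("standard") Gaussian component is not pinned
#' down by the points rule alone.  Two normalizations are provided:
#'
#' * `"fixed"`: `standard_peak = 0.1` (close to the 0.0997 peak of a
#'   unit-area Gaussian with sd 4 degrees), which makes the double-height
#'   first bet peak at a round 0.2 and caps the six-bet stacked score at
#'   about 199.2 points;
#' * `"calibrated"`: `standard_peak` is solved numerically so that stacking
#'   all six bets on the target scores exactly `max_points` (200 by
#'   default), matching the stated per-trial maximum.
#'
#' Heights can never reach 1: the penalty recursion has its asymptote there
#' provided `first_bet_multiplier * standard_peak <= 1` (enforced).
#'
#' @param exponent Penalty exponent in (0, 1); default 0.4.
#' @param gauss_sd Standard deviation of each bet's Gaussian component, in
#'   degrees of shape space; default 4.
#' @param standard_peak Peak height of the unscaled unit-multiplier
#'   component, in (0, 0.5); ignored under `normalization = "calibrated"`.
#' @param normalization `"fixed"` or `"calibrated"` (see above).
#' @param n_bets Number of bets per trial; default 6.
#' @param first_bet_multiplier Height multiplier of bet 1; default 2.
#' @param max_points Per-trial maximum used by the calibrated normalization.
#' @return An object of class `penalty_params` (a list of the above, with
#'   `standard_peak` resolved).
#' @examples
#' penalty_params()
#' penalty_params(normalization = "calibrated")$standard_peak
#' @export
penalty_params <- function(exponent = 0.4, gauss_sd = 4, standard_peak = 0.1,
                           normalization = c("fixed", "calibrated"),
                           n_bets = 6L, first_bet_multiplier = 2,
                           max_points = 200) {
  normalization <- match.arg(normalization)
  stopifnot(exponent > 0, exponent < 1,
            gauss_sd > 0, gauss_sd <= 90,
            n_bets >= 1, n_bets == round(n_bets),
            first_bet_multiplier > 0, max_points > 0)
  if (normalization == "calibrated") {
    standard_peak <- calibrate_standard_peak(
      exponent = exponent, n_bets = n_bets,
      first_bet_multiplier = first_bet_multiplier, max_points = max_points)
  }
  stopifnot(standard_peak > 0, standard_peak < 0.5,
            standard_peak * first_bet_multiplier <= 1)
  structure(
    list(exponent = exponent, gauss_sd = gauss_sd,
         standard_peak = standard_peak, normalization = normalization,
         n_bets = as.integer(n_bets),
         first_bet_multiplier = first_bet_multiplier,
         max_points = max_points),
    class = "penalty_params")
}

#' @export
print.penalty_params <- function(x, ...) {
  cat("Betting-game scoring parameters\n")
  cat(sprintf("  bets per trial      : %d (first bet x%g height)\n",
              x$n_bets, x$first_bet_multiplier))
  cat(sprintf("  component sd        : %g deg\n", x$gauss_sd))
  cat(sprintf("  penalty exponent    : %g\n", x$exponent))
  cat(sprintf("  standard peak       : %.6f (%s)\n",
              x$standard_peak, x$normalization))
  invisible(x)
}

#' Scalar stacking recursion
#'
#' Height reached at a single wheel position when components with the given
#' height multipliers are stacked there in order: starting from `y = 0`,
#' each step adds `standard_peak * m * (1 - y^exponent)`.  This is the
#' grid-free reference for the peak of a fully stacked profile; the
#' grid-based [build_profile()] must reproduce it at the stacked bin.
#'
#' @param standard_peak Unscaled component height.
#' @param exponent Penalty exponent.
#' @param multipliers Vector of per-bet height multipliers, in bet order.
#' @return The final scalar height.
#' @export
stacked_peak <- function(standard_peak, exponent, multipliers) {
  y <- 0
  for (m in multipliers) {
    gain <- min(max(1 - y^exponent, 0), 1)
    y <- y + standard_peak * m * gain
  }
  y
}

#' Solve for the standard peak giving an exact maximum score
#'
#' Finds the unscaled component height at which stacking all bets on the
#' target scores exactly `max_points` under the penalty recursion.
#'
#' @inheritParams penalty_params
#' @return The calibrated `standard_peak` (about 0.1006 under defaults).
#' @export
calibrate_standard_peak <- function(exponent = 0.4, n_bets = 6L,
                                    first_bet_multiplier = 2,
                                    max_points = 200) {
  mult <- c(first_bet_multiplier, rep(1, n_bets - 1L))
  f <- function(h) 500 * stacked_peak(h, exponent, mult) - max_points
  stats::uniroot(f, interval = c(1e-6, 1 / first_bet_multiplier - 1e-9),
                 tol = 1e-14)$root
}

bin_index <- function(position) {
  (round(position) %% 360) + 1L
}

#' One wrapped Gaussian bet component on the wheel grid
#'
#' Evaluates a Gaussian of standard deviation `params$gauss_sd` centered at
#' `center` (a continuous wheel position) on the 360 integer-degree bins,
#' wrapped around the circle, and scaled so its peak height is
#' `params$standard_peak * multiplier`.
#'
#' @param center Bet center in degrees (continuous positions allowed).
#' @param params A [penalty_params()] object.
#' @param multiplier Height multiplier (2 for bet 1, 1 for bets 2-6).
#' @return Numeric vector of 360 bin heights.
#' @export
gaussian_component <- function(center, params, multiplier = 1) {
  stopifnot(inherits(params, "penalty_params"), multiplier > 0)
  delta <- signed_delta(0:359, center)
  v <- 2 * params$gauss_sd^2
  h <- exp(-delta^2 / v)
  for (k in c(-720, -360, 360, 720)) {
    h <- h + exp(-(delta + k)^2 / v)
  }
  params$standard_peak * multiplier * h
}

#' Add one penalized bet to an uncertainty profile
#'
#' Implements the stacking rule: the new component is the wrapped Gaussian
#' at the bet center, scaled by `1 - y(b)^exponent` where `y(b)` is the
#' current profile height at the bin nearest the bet center `b`.  The gain
#' factor is clamped to `[0, 1]`, so adding a bet never removes mass.
#'
#' @param profile Numeric vector of 360 bin heights (the profile so far).
#' @param center Bet center in degrees.
#' @inheritParams gaussian_component
#' @return The updated 360-bin profile.
#' @export
add_bet <- function(profile, center, params, multiplier = 1) {
  stopifnot(length(profile) == 360L, all(profile >= 0))
  y_b <- profile[bin_index(center)]
  gain <- min(max(1 - y_b^params$exponent, 0), 1)
  profile + gain * gaussian_component(center, params, multiplier)
}

#' Build a trial's uncertainty profile from its ordered bets
#'
#' Folds [add_bet()] over the bets in placement order, with the first-bet
#' height multiplier for bet 1 and multiplier 1 thereafter.
#'
#' @param bets Numeric vector of exactly `params$n_bets` bet centers
#'   (degrees).
#' @param params A [penalty_params()] object.
#' @return Numeric vector of 360 bin heights.
#' @examples
#' pp <- penalty_params()
#' prof <- build_profile(rep(120, 6), pp)
#' score_trial(prof, 120)  # about 199.2 under the fixed normalization
#' @export
build_profile <- function(bets, params = penalty_params()) {
  if (!is.numeric(bets) || length(bets) != params$n_bets || anyNA(bets)) {
    stop(sprintf("malformed trial: expected %d bet centers", params$n_bets))
  }
  mult <- c(params$first_bet_multiplier, rep(1, params$n_bets - 1L))
  profile <- numeric(360L)
  for (k in seq_along(bets)) {
    profile <- add_bet(profile, bets[k], params, mult[k])
  }
  profile
}

#' Score a trial
#'
#' `500 * height of the final uncertainty profile at the bin nearest the
#' target shape`.  With all bets stacked on the target this is capped at
#' the per-trial maximum (200 points under the calibrated normalization).
#'
#' @param profile Numeric vector of 360 bin heights.
#' @param target Target wheel position in degrees.
#' @return Points earned (scalar).
#' @export
score_trial <- function(profile, target) {
  stopifnot(length(profile) == 360L)
  500 * profile[bin_index(target)]
}

#' Spread of an uncertainty profile about the target
#'
#' Treats the profile, rotated so the target sits at 0 and normalized to
#' unit mass, as a distribution over the signed-error variable on
#' `(-180, 180]` and returns either its standard deviation or its
#' interquartile range (both in degrees).  Quantiles are computed from the
#' piecewise-linear CDF that spreads each bin's mass uniformly over its
#' 1-degree support.
#'
#' @param profile Numeric vector of 360 bin heights with positive total
#'   mass.
#' @param target Target wheel position (degrees).
#' @param measure `"sd"` or `"iqr"`.
#' @return Spread in degrees.
#' @export
profile_spread <- function(profile, target, measure = c("sd", "iqr")) {
  measure <- match.arg(measure)
  stopifnot(length(profile) == 360L, all(profile >= 0))
  total <- sum(profile)
  if (total <= 0) stop("zero-mass profile: spread undefined")
  aligned <- rotate_profile(profile, round(target))
  d <- 0:359
  x <- d - 360 * (d > 180)          # signed error per bin, (-180, 180]
  ord <- order(x)
  p <- aligned[ord] / total
  xs <- x[ord]
  if (measure == "sd") {
    mu <- sum(p * xs)
    return(sqrt(sum(p * xs^2) - mu^2))
  }
  q <- profile_quantiles(p, xs, c(0.25, 0.75))
  q[2] - q[1]
}

# Inverse of the piecewise-linear CDF over bins centered at xs (sorted),
# each of unit width, with masses p (summing to 1).
profile_quantiles <- function(p, xs, probs) {
  p <- p / sum(p)
  cum <- cumsum(p)
  vapply(probs, function(q) {
    i <- which(cum >= q * cum[length(cum)])[1]
    left <- if (i == 1L) 0 else cum[i - 1L]
    frac <- if (p[i] > 0) (q - left) / p[i] else 0.5
    (xs[i] - 0.5) + frac
  }, numeric(1))
}
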