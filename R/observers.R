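# Generative observer models for the betting game.
#
# Three accounts of what an observer has access to on a single trial:
#   sampling             - a trial-specific internal probability distribution,
#                          each bet an independent draw from it;
#   discrete             - only a point estimate; bets 2-6 scatter
#                          symmetrically about it with a spread unrelated to
#                          the trial's encoding error;
#   discrete_confidence  - a point estimate plus a scalar confidence: the
#                          scatter width tracks the (unobservable) encoding
#                          error magnitude.

#' Parameters of a simulated observer
#'
#' @param kind `"sampling"`, `"discrete"`, or `"discrete_confidence"`.
#' @param encoding_sd Circular-normal sd (degrees) of the trial-level error
#'   of the internal representation's center.
#' @param internal_sd_mean,internal_sd_spread Mean and sd (degrees) of the
#'   per-trial width of the internal distribution / bet scatter (draws are
#'   floored just above zero so the noiseless limit stays exact).
#' @param bet_noise_growth Extra motor/decay noise sd added to bet `k`,
#'   equal to `bet_noise_growth * (k - 1)` degrees.
#' @param skew Asymmetry of the sampling observer's internal distribution
#'   (0 = symmetric).  Implemented as a two-component mixture: with
#'   probability 0.3 a draw comes from a component offset by
#'   `2 * width * skew`.  Ignored by the discrete kinds, whose scatter is
#'   symmetric by assumption.
#' @param confidence_coupling In `[0, 1]`; for `discrete_confidence`, how
#'   strongly the per-trial scatter width tracks the encoding error
#'   magnitude (0 = not at all, 1 = fully).
#' @param lapse_rate Probability that any given bet is replaced by a
#'   uniform mis-click on the wheel.
#' @param undo_enabled If `TRUE` (the control-study mechanic), a lapsed bet
#'   may be erased and re-placed; at most one undo per trial.
#' @param undo_prob Probability that a lapsed bet gets undone when undos
#'   are enabled.
#' @param noise `"wrapped"` (wrapped normal, the default) or `"vonmises"`
#'   for all circular-normal draws.
#' @param n_bets Bets per trial.
#' @return An object of class `observer_params`.
#' @examples
#' observer_params("sampling")
#' @export
observer_params <- function(kind = c("sampling", "discrete",
                                     "discrete_confidence"),
                            encoding_sd = 12, internal_sd_mean = 10,
                            internal_sd_spread = 3, bet_noise_growth = 2,
                            skew = 0, confidence_coupling = 0.6,
                            lapse_rate = 0.004, undo_enabled = FALSE,
                            undo_prob = 0.8,
                            noise = c("wrapped", "vonmises"), n_bets = 6L) {
  kind <- match.arg(kind)
  noise <- match.arg(noise)
  stopifnot(encoding_sd > 0, internal_sd_mean > 0, internal_sd_spread >= 0,
            bet_noise_growth >= 0, confidence_coupling >= 0,
            confidence_coupling <= 1, lapse_rate >= 0, lapse_rate <= 1,
            undo_prob >= 0, undo_prob <= 1, n_bets >= 1)
  structure(
    list(kind = kind, encoding_sd = encoding_sd,
         internal_sd_mean = internal_sd_mean,
         internal_sd_spread = internal_sd_spread,
         bet_noise_growth = bet_noise_growth, skew = skew,
         confidence_coupling = confidence_coupling, lapse_rate = lapse_rate,
         undo_enabled = undo_enabled, undo_prob = undo_prob, noise = noise,
         n_bets = as.integer(n_bets)),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("Observer model: %s\n", x$kind))
  cat(sprintf("  encoding sd %g deg | internal width %g +/- %g deg\n",
              x$encoding_sd, x$internal_sd_mean, x$internal_sd_spread))
  cat(sprintf("  growth %g deg/bet | skew %g | coupling %g | lapse %g\n",
              x$bet_noise_growth, x$skew, x$confidence_coupling,
              x$lapse_rate))
  if (x$undo_enabled) cat("  undo mechanic enabled\n")
  invisible(x)
}

# Circular-normal draws centered at 0, in degrees.  Wrapped normal by
# default; von Mises (Best & Fisher 1979 rejection sampler) as a robustness
# switch, with kappa matched as 1/sd^2 in radians.
rcircnorm <- function(n, sd, noise = "wrapped") {
  if (sd <= 0) return(numeric(n))
  if (noise == "wrapped") return(stats::rnorm(n, 0, sd))
  kappa <- 1 / (sd * pi / 180)^2
  rvonmises(n, kappa) * 180 / pi
}

rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# One draw-per-bet from the internal distribution: width w, optional skew.
draw_internal <- function(n, w, skew, noise) {
  base <- rcircnorm(n, w, noise)
  if (skew == 0) return(base)
  shifted <- stats::runif(n) < 0.3
  base[shifted] <- base[shifted] + 2 * w * skew
  base
}

trial_width <- function(params, eps) {
  w_ind <- max(1e-6, stats::rnorm(1, params$internal_sd_mean,
                                  params$internal_sd_spread))
  if (params$kind != "discrete_confidence") return(w_ind)
  cc <- params$confidence_coupling
  # scale |eps| so that its average maps back onto the mean internal width
  q <- abs(eps) / (params$encoding_sd * sqrt(2 / pi))
  max(1e-6, (1 - cc) * w_ind + cc * params$internal_sd_mean * q)
}

draw_bets <- function(params, m, w) {
  growth <- vapply(seq_len(params$n_bets), function(k) {
    s <- params$bet_noise_growth * (k - 1)
    if (s > 0) rcircnorm(1, s, params$noise) else 0
  }, numeric(1))
  if (params$kind == "sampling") {
    centers <- m + draw_internal(params$n_bets, w, params$skew, params$noise)
  } else {
    centers <- c(m, m + rcircnorm(params$n_bets - 1L, w, params$noise))
  }
  wrap360(centers + growth)
}

#' Simulate one trial of the betting game
#'
#' Draws the observer's internal center `m = target + eps` (encoding
#' error), a per-trial internal width, and the ordered bets according to
#' the observer's kind; applies uniform mis-click lapses and, when enabled,
#' the undo mechanic (a lapsed bet is erased and re-placed, with the
#' erased position recorded).
#'
#' Uses the current RNG state; seed management belongs to
#' [simulate_dataset()].
#'
#' @param params An [observer_params()] object.
#' @param target Target wheel position (degrees).
#' @return A list with `target`, `bets` (numeric, `n_bets` confirmed
#'   positions), `undo_bet_index` (NA or the erased bet's index), and
#'   `undo_original_deg` (NA or the erased position).
#' @export
simulate_trial <- function(params, target) {
  stopifnot(inherits(params, "observer_params"))
  eps <- rcircnorm(1, params$encoding_sd, params$noise)
  m <- target + eps
  w <- trial_width(params, eps)
  bets <- draw_bets(params, m, w)
  lapsed <- which(stats::runif(params$n_bets) < params$lapse_rate)
  bets[lapsed] <- stats::runif(length(lapsed), 0, 360)
  undo_idx <- NA_integer_
  undo_orig <- NA_real_
  if (params$undo_enabled && length(lapsed) > 0 &&
      stats::runif(1) < params$undo_prob) {
    undo_idx <- lapsed[1]
    undo_orig <- bets[undo_idx]
    bets[undo_idx] <- draw_bets(params, m, w)[undo_idx]
  }
  list(target = wrap360(target), bets = bets,
       undo_bet_index = undo_idx, undo_original_deg = undo_orig)
}

#' Simulate a cohort of observers
#'
#' Generates a full synthetic dataset: `n_participants` observers, each
#' completing `n_trials` trials with uniformly random targets.  Participant
#' heterogeneity is introduced by jittering `encoding_sd`,
#' `internal_sd_mean`, and `bet_noise_growth` multiplicatively by
#' `U(1 - jitter, 1 + jitter)` around the supplied values.
#'
#' Reproducibility: one master seed spawns per-participant seeds, which in
#' turn spawn per-trial seeds, so the same seed always yields the identical
#' dataset and extending the cohort leaves earlier participants' trials
#' untouched.  Angles are recorded to 3 decimal degrees (far below the
#' 1-degree wheel resolution), so datasets round-trip losslessly through
#' the CSV schema.
#'
#' @param params An [observer_params()] object (shared base parameters), or
#'   a list of length `n_participants` of such objects for full control.
#' @param n_participants,n_trials Cohort shape; defaults 40 x 150, the
#'   study's design.
#' @param seed Integer master seed.
#' @param participant_jitter Relative heterogeneity of participant
#'   parameters (ignored when `params` is a list).
#' @return A `bet_dataset`: a data.frame with columns `participant_id`,
#'   `experiment`, `trial_index`, `target_deg`, `bet1_deg` .. `bet6_deg`,
#'   `undo_bet_index`, `undo_original_deg`, carrying the per-participant
#'   `observer_params` in `attr(, "observers")` and a provenance record
#'   (seed, generator, version) in `attr(, "provenance")`.
#' @examples
#' d <- simulate_dataset(observer_params("sampling"),
#'                       n_participants = 2, n_trials = 5, seed = 1)
#' head(d)
#' @export
simulate_dataset <- function(params = observer_params("sampling"),
                             n_participants = 40L, n_trials = 150L,
                             seed = 1L, participant_jitter = 0.2) {
  stopifnot(n_participants >= 1, n_trials >= 1)
  shared <- inherits(params, "observer_params")
  if (!shared) {
    stopifnot(is.list(params), length(params) == n_participants,
              all(vapply(params, inherits, logical(1), "observer_params")))
  }
  set.seed(seed)
  pseeds <- sample.int(.Machine$integer.max, n_participants)
  rows <- vector("list", n_participants)
  observers <- vector("list", n_participants)
  base <- if (shared) params else NULL
  for (p in seq_len(n_participants)) {
    set.seed(pseeds[p])
    if (shared) {
      jit <- stats::runif(3, 1 - participant_jitter, 1 + participant_jitter)
      pp <- base
      pp$encoding_sd <- base$encoding_sd * jit[1]
      pp$internal_sd_mean <- base$internal_sd_mean * jit[2]
      pp$bet_noise_growth <- base$bet_noise_growth * jit[3]
    } else {
      pp <- params[[p]]
    }
    observers[[p]] <- pp
    tseeds <- sample.int(.Machine$integer.max, n_trials)
    trials <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      set.seed(tseeds[t])
      tr <- simulate_trial(pp, stats::runif(1, 0, 360))
      trials[[t]] <- c(tr$target, tr$bets, tr$undo_bet_index,
                       tr$undo_original_deg)
    }
    mat <- do.call(rbind, trials)
    rows[[p]] <- data.frame(
      participant_id = sprintf("s%03d", p),
      experiment = if (pp$undo_enabled) 2L else 1L,
      trial_index = seq_len(n_trials),
      target_deg = round(mat[, 1], 3),
      stringsAsFactors = FALSE)
    nb <- observers[[p]]$n_bets
    for (k in seq_len(nb)) {
      rows[[p]][[paste0("bet", k, "_deg")]] <- round(mat[, 1 + k], 3)
    }
    rows[[p]]$undo_bet_index <- as.integer(mat[, nb + 2])
    rows[[p]]$undo_original_deg <- round(mat[, nb + 3], 3)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "observers") <- observers
  attr(out, "provenance") <- list(
    seed = seed, n_participants = n_participants, n_trials = n_trials,
    participant_jitter = if (shared) participant_jitter else NA_real_,
    generator = "wheelbets::simulate_dataset",
    version = as.character(utils::packageVersion("wheelbets")))
  class(out) <- c("bet_dataset", "data.frame")
  out
}

#' Extract the bet matrix of a dataset
#'
#' @param dataset A `bet_dataset` (or any data.frame in the dataset
#'   schema).
#' @return Numeric matrix, one row per trial, one column per bet.
#' @export
bet_matrix <- function(dataset) {
  cols <- grep("^bet[0-9]+_deg$", names(dataset), value = TRUE)
  cols <- cols[order(as.integer(sub("^bet([0-9]+)_deg$", "\\1", cols)))]
  as.matrix(dataset[, cols, drop = FALSE])
}

#' Signed per-bet errors of a dataset
#'
#' @inheritParams bet_matrix
#' @return Numeric matrix of `signed_delta(bet, target)`, one row per
#'   trial, one column per bet; positive = clockwise of the target.
#' @export
bet_errors <- function(dataset) {
  b <- bet_matrix(dataset)
  sweep_target <- matrix(dataset$target_deg, nrow(b), ncol(b))
  matrix(signed_delta(b, sweep_target), nrow(b), ncol(b),
         dimnames = list(NULL, colnames(b)))
}
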