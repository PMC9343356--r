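# The analysis battery: spread-error correlations, profile-vs-error KS
# comparisons (with flipped-profile control), bet-order error curves with
# repeated-measures ANOVA, and undo summaries.

#' Spread of one trial's bets: median absolute adjacent-bet distance
#'
#' The median of the five absolute circular distances between consecutive
#' bets (consecutive in placement order).  A cheap, profile-free measure of
#' how widely a trial's bets were spread.
#'
#' @param bets Numeric vector of ordered bet centers (degrees), length >= 2,
#'   or a matrix with one trial per row.
#' @return Spread in degrees (scalar, or one value per row).
#' @examples
#' adjacent_bet_spread(c(0, 10, 20, 30, 40, 50))  # 10
#' @export
adjacent_bet_spread <- function(bets) {
  if (is.matrix(bets)) {
    return(apply(bets, 1, adjacent_bet_spread))
  }
  stopifnot(length(bets) >= 2)
  k <- length(bets)
  stats::median(abs_error(bets[-1], bets[-k]))
}

trial_spread <- function(dataset, spread_measure, params) {
  b <- bet_matrix(dataset)
  switch(spread_measure,
    adjacent = adjacent_bet_spread(b),
    profile_sd = vapply(seq_len(nrow(b)), function(i) {
      profile_spread(build_profile(b[i, ], params),
                     dataset$target_deg[i], "sd")
    }, numeric(1)),
    profile_iqr = vapply(seq_len(nrow(b)), function(i) {
      profile_spread(build_profile(b[i, ], params),
                     dataset$target_deg[i], "iqr")
    }, numeric(1)))
}

#' Does bet spread track first-response error?
#'
#' Per participant, the Pearson correlation across trials between the
#' magnitude of the first bet's error and a measure of that trial's bet
#' spread; correlations are Fisher-z-transformed and the z-values tested
#' against zero with a one-sample t-test.  A positive group mean indicates
#' that observers spread their bets more widely on trials where their first
#' response was worse -- i.e. the reported distributions carry trial-level
#' imprecision.
#'
#' @param dataset A `bet_dataset` (>= 3 trials per participant).
#' @param spread_measure `"adjacent"` (median absolute adjacent-bet
#'   distance), `"profile_sd"`, or `"profile_iqr"` (moments of the drawn
#'   uncertainty profile about the target).
#' @param params [penalty_params()], used by the profile-based measures.
#' @return A list with `per_participant` (data.frame of `participant_id`,
#'   `n`, `r`, `z`, `p` of the per-participant correlation test),
#'   `mean_r`, `mean_z`, `n_significant` (participants with r > 0 and
#'   p < 0.05), `group_t` (one-sample t of the z-values against 0), and
#'   `excluded` (participants dropped for zero variance).
#' @export
spread_error_analysis <- function(dataset,
                                  spread_measure = c("adjacent",
                                                     "profile_sd",
                                                     "profile_iqr"),
                                  params = penalty_params()) {
  spread_measure <- match.arg(spread_measure)
  spread <- trial_spread(dataset, spread_measure, params)
  err1 <- abs(bet_errors(dataset)[, 1])
  ids <- unique(dataset$participant_id)
  rows <- lapply(ids, function(id) {
    sel <- dataset$participant_id == id
    x <- err1[sel]
    y <- spread[sel]
    if (length(x) < 3) stop("spread-error analysis needs >= 3 trials per participant")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(participant_id = id, n = length(x), r = NA_real_,
                        z = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y)
    data.frame(participant_id = id, n = length(x),
               r = unname(ct$estimate), z = fisher_z(unname(ct$estimate)),
               p = ct$p.value)
  })
  per <- do.call(rbind, rows)
  excluded <- per$participant_id[is.na(per$r)]
  if (length(excluded) > 0) {
    warning(sprintf("excluding %d participant(s) with degenerate variance: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  ok <- per[!is.na(per$r), ]
  list(spread_measure = spread_measure,
       per_participant = per,
       mean_r = mean(ok$r), mean_z = mean(ok$z),
       n_significant = sum(ok$p < 0.05 & ok$r > 0),
       n_participants = nrow(ok),
       group_t = one_sample_t(ok$z, 0),
       excluded = as.character(excluded))
}

#' Target-aligned average uncertainty profile
#'
#' Builds each trial's six-bet profile, circle-shifts it so the target sits
#' at wheel position 0, and averages bin-wise across trials.  This is the
#' "trial-averaged uncertainty profile" that the across-trial first-bet
#' error distribution is compared against.
#'
#' @param trials Rows of a `bet_dataset` (typically one participant).
#' @param params A [penalty_params()] object.
#' @return Numeric vector of 360 mean bin heights (target at bin 0).
#' @export
average_aligned_profile <- function(trials, params = penalty_params()) {
  stopifnot(nrow(trials) >= 1)
  rowMeans(aligned_profile_matrix(trials, params))
}

# 360 x n_trials matrix of target-aligned per-trial profiles.
aligned_profile_matrix <- function(trials, params) {
  b <- bet_matrix(trials)
  vapply(seq_len(nrow(trials)), function(i) {
    rotate_profile(build_profile(b[i, ], params),
                   round(trials$target_deg[i]))
  }, numeric(360))
}

mirror_profile <- function(profile) {
  profile[((-(0:359)) %% 360) + 1L]
}

#' Deterministic pseudo-sample from a target-aligned profile
#'
#' Draws `n` values from the normalized profile, read as a distribution
#' over the signed-error variable on `(-180, 180]`, by inverse-CDF at the
#' equally spaced quantiles `(i - 0.5) / n`.  Deterministic by design so
#' that KS comparisons against it are reproducible without extra
#' randomness.
#'
#' @param profile Numeric vector of 360 bin heights (target at bin 0),
#'   positive total mass.
#' @param n Sample size.
#' @return Sorted numeric vector of length `n` in `(-180.5, 180.5)`.
#' @export
profile_pseudo_sample <- function(profile, n) {
  stopifnot(length(profile) == 360L, n >= 1)
  if (sum(profile) <= 0) stop("zero-mass profile")
  d <- 0:359
  x <- d - 360 * (d > 180)
  ord <- order(x)
  profile_quantiles(profile[ord] / sum(profile), x[ord],
                    (seq_len(n) - 0.5) / n)
}

profile_cdf_fun <- function(profile) {
  d <- 0:359
  x <- d - 360 * (d > 180)
  ord <- order(x)
  p <- profile[ord] / sum(profile)
  edges <- c(min(x) - 0.5, x[ord] + 0.5)
  stats::approxfun(edges, c(0, cumsum(p)), yleft = 0, yright = 1)
}

#' KS comparison of first-bet errors against the drawn profiles
#'
#' Compares a participant's across-trial distribution of first-bet signed
#' errors to their trial-averaged, target-aligned uncertainty profile.  If
#' observers place bets by sampling the same internal distribution that
#' generated their first response, the two distributions should match
#' (small D).  The flipped control mirrors the profile before the
#' comparison: sensitivity to flipping reveals informative asymmetry in
#' the drawn profiles.
#'
#' @param trials Rows of a `bet_dataset` for one participant.
#' @param params A [penalty_params()] object.
#' @param flipped Mirror the profile before comparing?
#' @param flip_axis `"target"` mirrors the averaged profile about the
#'   aligned target (0); `"bet1"` mirrors each trial's profile about that
#'   trial's first bet before averaging.
#' @param variant `"pseudo_sample"` (default): a deterministic inverse-CDF
#'   pseudo-sample of the profile, same size as the error sample, then a
#'   standard two-sample KS test.  `"cdf"`: one-sample KS of the errors
#'   against the profile's piecewise-linear CDF.
#' @param split `"none"` (default) uses all trials on both sides, as in the
#'   original analysis.  `"half"` takes the error sample from odd trials
#'   and the profiles from even trials.  Because every trial's first bet
#'   contributes to both the error sample and the profile, the `"none"`
#'   comparison shares sampling noise between its two sides, which
#'   slightly favors the unflipped orientation even for perfectly
#'   symmetric observers; the split-half comparison removes that
#'   dependence and is the right instrument when the flip effect itself is
#'   the question.
#' @param min_trials Minimum trial count required (default 20).
#' @return A list with `statistic` (D), `p`, `n`, `flipped`, `variant`.
#' @export
profile_vs_error_ks <- function(trials, params = penalty_params(),
                                flipped = FALSE,
                                flip_axis = c("target", "bet1"),
                                variant = c("pseudo_sample", "cdf"),
                                split = c("none", "half"),
                                min_trials = 20) {
  flip_axis <- match.arg(flip_axis)
  variant <- match.arg(variant)
  split <- match.arg(split)
  if (nrow(trials) < min_trials) {
    stop(sprintf("need >= %d trials for the KS comparison", min_trials))
  }
  profs <- aligned_profile_matrix(trials, params)
  ks_from_profiles(profs, bet_errors(trials), flipped, flip_axis, variant,
                   split)
}

ks_from_profiles <- function(profs, errors, flipped, flip_axis, variant,
                             split = "none") {
  err1 <- errors[, 1]
  if (split == "half") {
    idx <- seq_along(err1)
    err_sel <- idx %% 2L == 1L
    prof_sel <- !err_sel
  } else {
    err_sel <- prof_sel <- rep(TRUE, length(err1))
  }
  if (flipped && flip_axis == "bet1") {
    for (i in which(prof_sel)) {
      ax <- 2L * round(err1[i])
      profs[, i] <- profs[((ax - (0:359)) %% 360) + 1L, i]
    }
  }
  avg <- rowMeans(profs[, prof_sel, drop = FALSE])
  if (flipped && flip_axis == "target") avg <- mirror_profile(avg)
  a <- err1[err_sel]
  n <- length(a)
  res <- if (variant == "pseudo_sample") {
    ks_two_sample(a, profile_pseudo_sample(avg, n))
  } else {
    ht <- suppressWarnings(stats::ks.test(a, profile_cdf_fun(avg)))
    list(statistic = unname(ht$statistic), p = ht$p.value, n = n)
  }
  list(statistic = res$statistic, p = res$p, n = n,
       flipped = flipped, variant = variant, split = split)
}

#' Per-bet and cumulative error curves with repeated-measures ANOVA
#'
#' For each participant, the mean absolute error of each individual bet
#' (bet order 1..k) and the mean absolute error of the running circular
#' mean of bets 1..k.  Each curve is submitted to a one-way
#' repeated-measures ANOVA with bet order as the within-subjects factor.
#' A rising individual curve with a falling cumulative curve is the
#' signature that later bets carry information beyond the first response.
#'
#' @param dataset A `bet_dataset` of complete trials.
#' @return A list with `individual` and `cumulative`, each containing
#'   `by_participant` (participants x bets matrix of mean absolute
#'   errors), `curve` (group means), and `anova`
#'   (see [rm_anova_oneway()]); plus `n_excluded`, the number of trials
#'   dropped for an undefined cumulative mean.
#' @export
bet_order_analysis <- function(dataset) {
  errs <- bet_errors(dataset)
  nb <- ncol(errs)
  b <- bet_matrix(dataset)
  cum_err <- matrix(NA_real_, nrow(b), nb)
  bad <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    cm <- tryCatch(cumulative_means(b[i, ]), error = function(e) NULL)
    if (is.null(cm)) bad[i] <- TRUE else {
      cum_err[i, ] <- abs_error(cm, dataset$target_deg[i])
    }
  }
  if (any(bad)) {
    warning(sprintf("excluding %d trial(s) with undefined cumulative means",
                    sum(bad)))
  }
  ids <- unique(dataset$participant_id)
  agg <- function(m, keep) {
    t(vapply(ids, function(id) {
      sel <- dataset$participant_id == id & keep
      colMeans(m[sel, , drop = FALSE])
    }, numeric(nb)))
  }
  ind <- agg(abs(errs), rep(TRUE, nrow(errs)))
  cum <- agg(cum_err, !bad)
  dimnames(ind) <- dimnames(cum) <- list(ids, paste0("bet", seq_len(nb)))
  list(
    individual = list(by_participant = ind, curve = colMeans(ind),
                      anova = rm_anova_oneway(ind)),
    cumulative = list(by_participant = cum, curve = colMeans(cum),
                      anova = rm_anova_oneway(cum)),
    n_excluded = sum(bad))
}

#' Summarize use of the undo mechanic
#'
#' Usage rate (fraction of trials with an undo), the mean absolute error of
#' the undone bets versus the bets that replaced them, and how undo usage
#' distributes across bet indices.  Undone bets that were mis-clicks sit
#' near the 90-degree chance level, far above replacement-bet error.
#'
#' @param dataset A `bet_dataset` (undo columns may be all-NA).
#' @return A list with `rate`, `n_undos`, `undone_mean_error`,
#'   `replacement_mean_error` (NA when there are no undos), and
#'   `by_bet_index` (counts).
#' @export
undo_summary <- function(dataset) {
  has <- !is.na(dataset$undo_bet_index)
  n <- sum(has)
  if (n == 0) {
    return(list(rate = 0, n_undos = 0L, undone_mean_error = NA_real_,
                replacement_mean_error = NA_real_,
                by_bet_index = integer(0)))
  }
  d <- dataset[has, , drop = FALSE]
  b <- bet_matrix(d)
  repl <- b[cbind(seq_len(nrow(d)), d$undo_bet_index)]
  list(rate = mean(has), n_undos = n,
       undone_mean_error = mean(abs_error(d$undo_original_deg, d$target_deg)),
       replacement_mean_error = mean(abs_error(repl, d$target_deg)),
       by_bet_index = table(factor(d$undo_bet_index,
                                   levels = seq_len(ncol(b)))))
}

#' Run the full analysis battery on a dataset
#'
#' Computes, per participant and at the group level: the spread-error
#' correlation analysis, the KS comparison of first-bet errors against the
#' trial-averaged uncertainty profiles (unflipped and flipped, with a
#' paired t-test of the D-values), the bet-order error curves with their
#' ANOVAs, and the undo summary.
#'
#' @param dataset A `bet_dataset`.
#' @param params A [penalty_params()] object.
#' @param spread_measure Passed to [spread_error_analysis()].
#' @param flip_axis,ks_variant,ks_split Passed to the KS comparison (see
#'   [profile_vs_error_ks()]).
#' @param min_trials_ks Minimum trials per participant for the KS block
#'   (participants below it are skipped).
#' @return An object of class `bet_report`.
#' @examples
#' d <- simulate_dataset(observer_params("sampling"),
#'                       n_participants = 3, n_trials = 30, seed = 1)
#' rep <- analyze_dataset(d, min_trials_ks = 20)
#' print(rep)
#' @export
analyze_dataset <- function(dataset, params = penalty_params(),
                            spread_measure = "adjacent",
                            flip_axis = "target",
                            ks_variant = "pseudo_sample",
                            ks_split = "none",
                            min_trials_ks = 20) {
  ids <- unique(dataset$participant_id)
  spread <- spread_error_analysis(dataset, spread_measure, params)
  ks_rows <- lapply(ids, function(id) {
    tr <- dataset[dataset$participant_id == id, , drop = FALSE]
    if (nrow(tr) < min_trials_ks) return(NULL)
    profs <- aligned_profile_matrix(tr, params)
    errs <- bet_errors(tr)
    un <- ks_from_profiles(profs, errs, FALSE, flip_axis, ks_variant, ks_split)
    fl <- ks_from_profiles(profs, errs, TRUE, flip_axis, ks_variant, ks_split)
    data.frame(participant_id = id, n = un$n,
               D = un$statistic, p = un$p,
               D_flipped = fl$statistic, p_flipped = fl$p)
  })
  ks <- do.call(rbind, ks_rows)
  ks_block <- if (is.null(ks) || nrow(ks) < 2) {
    list(per_participant = ks, note = "too few participants with enough trials")
  } else {
    list(per_participant = ks,
         mean_D = mean(ks$D), sd_D = stats::sd(ks$D),
         mean_D_flipped = mean(ks$D_flipped),
         sd_D_flipped = stats::sd(ks$D_flipped),
         n_matching = sum(ks$p > 0.05),
         n_matching_flipped = sum(ks$p_flipped > 0.05),
         flip_t = paired_t(ks$D_flipped, ks$D))
  }
  report <- list(
    n_participants = length(ids),
    n_trials = nrow(dataset),
    params = params,
    spread_error = spread,
    ks = ks_block,
    bet_order = bet_order_analysis(dataset),
    undo = undo_summary(dataset),
    provenance = attr(dataset, "provenance"))
  class(report) <- "bet_report"
  report
}

#' @export
print.bet_report <- function(x, ...) {
  cat(sprintf("Betting-game analysis report: %d participants, %d trials\n\n",
              x$n_participants, x$n_trials))
  se <- x$spread_error
  cat(sprintf("Spread-error correlation (%s): mean r = %.3f, mean z = %.3f\n",
              se$spread_measure, se$mean_r, se$mean_z))
  cat(sprintf("  %d / %d participants with significant positive r;",
              se$n_significant, se$n_participants))
  cat(sprintf(" group t(%d) = %.2f, p = %.3g\n",
              se$group_t$df, se$group_t$statistic, se$group_t$p))
  if (!is.null(x$ks$mean_D)) {
    cat(sprintf("Profile-vs-error KS: mean D = %.3f (SD %.3f), %d / %d matching (p > 0.05)\n",
                x$ks$mean_D, x$ks$sd_D, x$ks$n_matching,
                nrow(x$ks$per_participant)))
    cat(sprintf("  flipped: mean D = %.3f, %d matching; flip effect t(%d) = %.2f, p = %.3g\n",
                x$ks$mean_D_flipped, x$ks$n_matching_flipped,
                x$ks$flip_t$df, x$ks$flip_t$statistic, x$ks$flip_t$p))
  }
  bo <- x$bet_order
  cat("Individual bet error by order: ",
      paste(sprintf("%.1f", bo$individual$curve), collapse = " "), "\n")
  cat(sprintf("  ANOVA F(%d,%d) = %.2f, p = %.3g, eta^2 = %.3f\n",
              bo$individual$anova$df[1], bo$individual$anova$df[2],
              bo$individual$anova$statistic, bo$individual$anova$p,
              bo$individual$anova$eta_sq))
  cat("Cumulative bet error by order:  ",
      paste(sprintf("%.1f", bo$cumulative$curve), collapse = " "), "\n")
  cat(sprintf("  ANOVA F(%d,%d) = %.2f, p = %.3g, eta^2 = %.3f\n",
              bo$cumulative$anova$df[1], bo$cumulative$anova$df[2],
              bo$cumulative$anova$statistic, bo$cumulative$anova$p,
              bo$cumulative$anova$eta_sq))
  if (x$undo$n_undos > 0) {
    cat(sprintf("Undo usage: %.1f%% of trials; undone error %.1f deg vs replacement %.1f deg\n",
                100 * x$undo$rate, x$undo$undone_mean_error,
                x$undo$replacement_mean_error))
  }
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' @param report A `bet_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$params <- unclass(out$params)
  out$undo$by_bet_index <- as.list(out$undo$by_bet_index)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}
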