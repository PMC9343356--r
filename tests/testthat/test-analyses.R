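pp <- penalty_params()

test_that("adjacent_bet_spread is the median consecutive gap on the circle", {
  expect_equal(adjacent_bet_spread(c(0, 10, 20, 30, 40, 50)), 10)
  expect_equal(adjacent_bet_spread(rep(123, 6)), 0)
  expect_equal(adjacent_bet_spread(c(355, 5, 15, 25, 35, 45)), 10)
  m <- rbind(c(0, 10, 20, 30, 40, 50), rep(1, 6))
  expect_equal(adjacent_bet_spread(m), c(10, 0))
})

test_that("average_aligned_profile centers the target and averages binwise", {
  d1 <- manual_dataset(77, matrix(c(80, 74, 77, 79, 75, 78), 1))
  avg <- average_aligned_profile(d1, pp)
  expect_equal(avg, rotate_profile(build_profile(c(80, 74, 77, 79, 75, 78),
                                                 pp), 77))
  # duplicating the trial set leaves the average unchanged
  d2 <- manual_dataset(rep(77, 2), matrix(rep(c(80, 74, 77, 79, 75, 78),
                                              each = 2), 2))
  expect_equal(average_aligned_profile(d2, pp), avg)
  # all bets on target: a stacked profile peaking at bin 0 (recursion value)
  d3 <- manual_dataset(c(10, 250), rbind(rep(10, 6), rep(250, 6)))
  avg3 <- average_aligned_profile(d3, pp)
  expect_equal(which.max(avg3), 1L)
  expect_equal(avg3[1], oracle_stack(pp$standard_peak, pp$exponent,
                                     c(2, 1, 1, 1, 1, 1)), tolerance = 1e-9)
})

test_that("profile pseudo-samples follow the profile's quantiles", {
  prof <- rotate_profile(add_bet(numeric(360), 0, pp), 0)  # Gaussian at 0
  ps <- profile_pseudo_sample(prof, 200)
  expect_equal(length(ps), 200)
  expect_true(!is.unsorted(ps))
  # quantiles of a Gaussian profile with sd 4 match the normal quantiles
  expect_equal(ps[100.5 - 50], qnorm(0.25, 0, 4), tolerance = 0.15)
  expect_equal(stats::median(ps), 0, tolerance = 0.1)
  expect_error(profile_pseudo_sample(numeric(360), 10), "zero-mass")
})

test_that("spread_error_analysis excludes degenerate participants with a warning", {
  # one participant always places the same fixed spread -> r undefined
  set.seed(41)
  n <- 10
  targets <- runif(n, 0, 360)
  bets_fixed <- t(vapply(targets, function(t)
    wrap360(t + rnorm(1, 0, 15) + c(0, 5, 10, 15, 20, 25)), numeric(6)))
  bets_var <- t(vapply(targets, function(t)
    wrap360(t + rnorm(1, 0, 15) + runif(1, 1, 30) * (0:5)), numeric(6)))
  bets_var2 <- t(vapply(targets, function(t)
    wrap360(t + rnorm(1, 0, 15) + runif(1, 1, 30) * (0:5)), numeric(6)))
  d <- rbind(manual_dataset(targets, bets_fixed, id = "fixed"),
             manual_dataset(targets, bets_var, id = "varied1"),
             manual_dataset(targets, bets_var2, id = "varied2"))
  class(d) <- c("bet_dataset", "data.frame")
  expect_warning(res <- spread_error_analysis(d), "degenerate")
  expect_equal(res$excluded, "fixed")
  expect_equal(res$n_participants, 2)
})

test_that("confidence-coupled observers show positive spread-error z; lapse-free fixed-spread observers do not", {
  conf <- simulate_dataset(observer_params("discrete_confidence",
                                           lapse_rate = 0), 10, 80,
                           seed = 42)
  null <- simulate_dataset(observer_params("discrete", lapse_rate = 0),
                           10, 80, seed = 42)
  rc <- spread_error_analysis(conf)
  rn <- spread_error_analysis(null)
  expect_gt(rc$mean_z, 0.2)
  expect_lt(rc$group_t$p, 0.01)
  expect_gt(rn$group_t$p, 0.05)
  expect_lt(abs(rn$mean_z), 0.1)
})

test_that("profile-based spread measures also track first-bet error", {
  conf <- simulate_dataset(observer_params("discrete_confidence",
                                           lapse_rate = 0), 6, 60,
                           seed = 43)
  for (m in c("profile_sd", "profile_iqr")) {
    res <- spread_error_analysis(conf, spread_measure = m)
    expect_gt(res$mean_z, 0.15)
  }
})

test_that("flipping the profile hurts skewed observers, not symmetric ones", {
  sym <- simulate_dataset(observer_params("sampling", skew = 0), 8, 60,
                          seed = 44)
  skw <- simulate_dataset(observer_params("sampling", skew = 0.8), 8, 60,
                          seed = 44)
  dsym <- t(sapply(unique(sym$participant_id), function(id) {
    tr <- sym[sym$participant_id == id, ]
    c(profile_vs_error_ks(tr, pp, flipped = FALSE, split = "half")$statistic,
      profile_vs_error_ks(tr, pp, flipped = TRUE, split = "half")$statistic)
  }))
  dskw <- t(sapply(unique(skw$participant_id), function(id) {
    tr <- skw[skw$participant_id == id, ]
    c(profile_vs_error_ks(tr, pp, flipped = FALSE, split = "half")$statistic,
      profile_vs_error_ks(tr, pp, flipped = TRUE, split = "half")$statistic)
  }))
  expect_gt(mean(dskw[, 2] - dskw[, 1]), 0.05)
  expect_lt(abs(mean(dsym[, 2] - dsym[, 1])), 0.04)
  # D in [0, 1] always
  expect_true(all(c(dsym, dskw) >= 0 & c(dsym, dskw) <= 1))
})

test_that("the KS comparison needs a minimum number of trials", {
  d <- simulate_dataset(observer_params("sampling"), 1, 10, seed = 45)
  expect_error(profile_vs_error_ks(d, pp), ">= 20 trials")
})

test_that("bet1-axis flipping is available and differs from target-axis", {
  d <- simulate_dataset(observer_params("sampling", skew = 0.8), 1, 40,
                        seed = 46)
  a <- profile_vs_error_ks(d, pp, flipped = TRUE, flip_axis = "target")
  b <- profile_vs_error_ks(d, pp, flipped = TRUE, flip_axis = "bet1")
  expect_false(isTRUE(all.equal(a$statistic, b$statistic)))
  # the cdf variant returns the same kind of result
  cc <- profile_vs_error_ks(d, pp, variant = "cdf")
  expect_true(cc$statistic >= 0 && cc$statistic <= 1)
})

test_that("bet_order_analysis: noiseless curves are zero with F = 0", {
  op <- observer_params("sampling", encoding_sd = 1e-9,
                        internal_sd_mean = 1e-9, internal_sd_spread = 0,
                        bet_noise_growth = 0, lapse_rate = 0)
  d <- simulate_dataset(op, 4, 10, seed = 47, participant_jitter = 0)
  res <- bet_order_analysis(d)
  expect_equal(unname(res$individual$curve), rep(0, 6), tolerance = 1e-6)
  expect_equal(unname(res$cumulative$curve), rep(0, 6), tolerance = 1e-6)
  expect_equal(res$individual$anova$statistic, 0, tolerance = 1e-6)
})

test_that("iid sampling with no growth noise follows the 1/sqrt(k) law", {
  op <- observer_params("sampling", encoding_sd = 1e-6,
                        internal_sd_mean = 10, internal_sd_spread = 0,
                        bet_noise_growth = 0, lapse_rate = 0)
  d <- simulate_dataset(op, 8, 300, seed = 48, participant_jitter = 0)
  res <- bet_order_analysis(d)
  k <- 1:6
  expected <- 10 * sqrt(2 / (pi * k))   # mean |N(0, 10/sqrt(k))|
  expect_equal(unname(res$cumulative$curve), expected, tolerance = 0.05)
  # individual curve stays flat
  expect_lt(max(res$individual$curve) - min(res$individual$curve), 0.7)
})

test_that("undo_summary counts usage and contrasts undone vs replacement error", {
  d0 <- simulate_dataset(observer_params("sampling"), 2, 10, seed = 49)
  expect_equal(undo_summary(d0)$rate, 0)
  # hand-built: every trial has one undo
  d1 <- manual_dataset(c(0, 100), rbind(c(0, 2, 4, 6, 8, 10),
                                        c(99, 98, 100, 101, 102, 97)),
                       undo_bet_index = c(2L, 3L),
                       undo_original_deg = c(90, 280))
  us <- undo_summary(d1)
  expect_equal(us$rate, 1)
  expect_equal(us$n_undos, 2L)
  expect_equal(us$undone_mean_error, mean(c(90, 180)))
  expect_equal(us$replacement_mean_error, mean(c(2, 0)))
  expect_equal(as.integer(us$by_bet_index[c("2", "3")]), c(1L, 1L))
})

test_that("analyze_dataset assembles a coherent report", {
  d <- simulate_dataset(observer_params("sampling"), 4, 30, seed = 50)
  rep <- analyze_dataset(d, min_trials_ks = 20)
  expect_s3_class(rep, "bet_report")
  expect_equal(rep$n_participants, 4)
  expect_equal(nrow(rep$ks$per_participant), 4)
  expect_length(rep$bet_order$individual$curve, 6)
  expect_output(print(rep), "Betting-game analysis report")
  tmp <- tempfile(fileext = ".json")
  write_report(rep, tmp)
  parsed <- jsonlite::read_json(tmp)
  expect_equal(parsed$n_participants, 4)
  expect_named(parsed$bet_order, c("individual", "cumulative", "n_excluded"))
})
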