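pp <- penalty_params()

test_that("gaussian_component peaks at standard_peak and scales linearly", {
  g1 <- gaussian_component(0, pp, multiplier = 1)
  expect_equal(g1[1], pp$standard_peak)
  expect_equal(gaussian_component(0, pp, multiplier = 2), 2 * g1)
  # Gaussian shape: value at 3 sd over peak = exp(-9/2)
  g <- gaussian_component(100, pp)
  expect_equal(g[bin_at(100 + 3 * pp$gauss_sd)] / g[bin_at(100)],
               exp(-9 / 2), tolerance = 1e-12)
  # symmetric about the center
  expect_equal(g[bin_at(100 + 7)], g[bin_at(100 - 7)])
  # wraps around the seam
  gs <- gaussian_component(1, pp)
  expect_equal(gs[bin_at(359)], gs[bin_at(3)])
})

test_that("add_bet applies the diminishing-returns penalty at the bet bin", {
  empty <- numeric(360)
  p1 <- add_bet(empty, 50, pp, multiplier = 1)
  expect_equal(p1[bin_at(50)], pp$standard_peak)      # 0^0.4 = 0, gain 1
  # a far-away bet is essentially unpenalized (the ^0.4 in the penalty
  # amplifies the ~1e-15 tail height at 8 sd to a ~1e-6 gain deficit)
  p2 <- add_bet(p1, 50 + 8 * pp$gauss_sd, pp)
  expect_equal(p2[bin_at(82)], pp$standard_peak, tolerance = 1e-5)
  # gain strictly decreases with pre-existing height
  heights <- seq(0, 0.9, by = 0.1)
  gains <- vapply(heights, function(y) {
    prof <- rep(y, 360)
    add_bet(prof, 10, pp)[bin_at(10)] - y
  }, numeric(1))
  expect_true(all(diff(gains) < 0))
  # adding a bet never removes mass anywhere
  expect_true(all(p2 >= p1))
})

test_that("stacked bets on one bin reproduce the scalar recursion", {
  mult <- c(2, 1, 1, 1, 1, 1)
  prof <- build_profile(rep(200, 6), pp)
  expect_equal(prof[bin_at(200)],
               oracle_stack(pp$standard_peak, pp$exponent, mult),
               tolerance = 1e-9)
  expect_true(all(prof < 1))
})

test_that("well-separated bets add almost independently, in any order", {
  centers <- c(0, 60, 120, 180, 240, 300)
  prof <- build_profile(centers, pp)
  comps <- gaussian_component(centers[1], pp, 2)
  for (ct in centers[-1]) comps <- comps + gaussian_component(ct, pp, 1)
  expect_equal(prof, comps, tolerance = 1e-6)
  # permuting bets 2-6 leaves the profile unchanged in the separated limit
  perm <- c(centers[1], centers[c(4, 2, 6, 3, 5)])
  expect_equal(build_profile(perm, pp), prof, tolerance = 1e-6)
})

test_that("build_profile rejects malformed trials", {
  expect_error(build_profile(c(1, 2, 3), pp), "malformed")
  expect_error(build_profile(c(rep(1, 5), NA), pp), "malformed")
})

test_that("score_trial pays 500 x height at the target and rotates freely", {
  expect_equal(score_trial(numeric(360), 10), 0)
  one <- add_bet(numeric(360), 90, pp, multiplier = 2)
  expect_equal(score_trial(one, 90), 500 * 0.2)    # 100 points
  # invariance under joint rotation of bets and target
  bets <- c(40, 45, 38, 50, 41, 43)
  s0 <- score_trial(build_profile(bets, pp), 42)
  for (shift in c(17, 180, 301)) {
    expect_equal(score_trial(build_profile(wrap360(bets + shift), pp),
                             wrap360(42 + shift)), s0, tolerance = 1e-9)
  }
})

test_that("calibrated normalization hits the 200-point maximum exactly", {
  ppc <- penalty_params(normalization = "calibrated")
  expect_equal(ppc$standard_peak, 0.1006, tolerance = 1e-3)
  prof <- build_profile(rep(0, 6), ppc)
  expect_equal(score_trial(prof, 0), 200, tolerance = 1e-9)
  # fixed normalization stays just under the maximum
  expect_lt(score_trial(build_profile(rep(0, 6), pp), 0), 200)
})

test_that("profile_spread recovers component widths and mixture variance", {
  single <- add_bet(numeric(360), 120, pp)
  expect_equal(profile_spread(single, 120, "sd"), pp$gauss_sd,
               tolerance = 0.01)
  # normal-quantile relation between IQR and sd
  expect_equal(profile_spread(single, 120, "iqr"),
               2 * qnorm(0.75) * pp$gauss_sd, tolerance = 0.02)
  # two equal well-separated components at +/- 20 about the target
  two <- add_bet(add_bet(numeric(360), 100, pp), 140, pp)
  expect_equal(profile_spread(two, 120, "sd"),
               sqrt(20^2 + pp$gauss_sd^2), tolerance = 0.02)
  expect_error(profile_spread(numeric(360), 0), "zero-mass")
})
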