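# Statistical primitives with exact contracts.  These are thin, audited
# wrappers over base R's tested routines (t.test, cor, ks.test, aov), so
# every number in an analysis report can be traced to a standard method
# with the conventions fixed here: two-sided tests throughout, asymptotic
# two-sample KS p-values, and eta-squared defined as
# SS_effect / (SS_effect + SS_error).

#' Fisher's variance-stabilizing z-transform
#'
#' `0.5 * log((1 + r) / (1 - r))`; strictly increasing and odd.  Used to
#' aggregate per-participant correlations before group-level testing.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return The transformed value(s).
#' @export
fisher_z <- function(r) {
  stopifnot(is.numeric(r))
  if (any(abs(r) >= 1)) stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' Inverse Fisher z-transform
#'
#' @param z Numeric vector.
#' @return Correlations in `(-1, 1)`.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' One-sample t-test against a fixed mean
#'
#' Two-sided, df = n - 1, with the 95 percent confidence interval of the
#' mean.
#'
#' @param values Numeric vector, n >= 2, nonzero variance.
#' @param mu0 Null mean (default 0).
#' @return A list with `statistic`, `df`, `p`, `mean`, `conf_int`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0) stop("zero variance: t undefined")
  ht <- stats::t.test(values, mu = mu0)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = unname(ht$estimate),
       conf_int = as.numeric(ht$conf.int))
}

#' Paired t-test
#'
#' Two-sided paired comparison, df = n - 1.
#'
#' @param x,y Numeric vectors of equal length (paired observations).
#' @return A list with `statistic`, `df`, `p`, `mean_diff`, `conf_int`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  res <- one_sample_t(x - y, 0)
  names(res)[names(res) == "mean"] <- "mean_diff"
  res
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sided p-value
#' (effective n = n_a n_b / (n_a + n_b)); exact small-sample p-values are
#' deliberately not used so that p-values are comparable across sample
#' sizes.
#'
#' @param a,b Nonempty numeric samples.
#' @return A list with `statistic` (D), `p`, and the sample sizes `n`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n = c(length(a), length(b)))
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject one-way ANOVA: subjects are rows of `values`,
#' the within factor (bet order) its columns.  For `k` levels and `n`
#' subjects, `df = (k - 1, (k - 1)(n - 1))`.  Two effect sizes are
#' reported: `eta_sq = SS_effect / (SS_effect + SS_error)` (the convention
#' used for the headline values) and
#' `eta_sq_total = SS_effect / (SS_subject + SS_effect + SS_error)`.  No
#' sphericity correction is applied.
#'
#' @param values Numeric matrix, subjects x levels, complete (no NA).
#' @return A list with `statistic` (F), `df` (length 2), `p`, `eta_sq`,
#'   `eta_sq_total`, and the per-level means `level_means`.
#' @export
rm_anova_oneway <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("incomplete matrix: repeated-measures ANOVA needs complete cases")
  n <- nrow(values)
  k <- ncol(values)
  stopifnot(n >= 2, k >= 2)
  dat <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    level = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ level + Error(subject), data = dat)
  within <- summary(fit)[["Error: Within"]][[1]]
  ss_effect <- within["level", "Sum Sq"]
  ss_error <- within["Residuals", "Sum Sq"]
  ss_subject <- summary(fit)[["Error: subject"]][[1]]["Residuals", "Sum Sq"]
  denom <- ss_effect + ss_error
  # guard against an all-equal matrix, where both SS are numerical noise
  degenerate <- denom <= 1e-12 * (1 + sum(dat$y^2))
  f <- within["level", "F value"]
  list(statistic = unname(if (degenerate || is.na(f)) 0 else f),
       df = c(within["level", "Df"], within["Residuals", "Df"]),
       p = unname(if (degenerate || is.na(f)) 1 else within["level", "Pr(>F)"]),
       eta_sq = if (degenerate) 0 else ss_effect / denom,
       eta_sq_total = if (degenerate) 0 else ss_effect / (ss_subject + denom),
       level_means = colMeans(values))
}
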