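# Independent oracles used across test files.  These deliberately avoid the
# package's own code paths.

# Scalar stacking recursion, written out longhand: starting at 0, each step
# adds H * m * (1 - y^e).
oracle_stack <- function(h, e, multipliers) {
  y <- 0
  for (m in multipliers) y <- y + h * m * (1 - y^e)
  y
}

# Brute-force two-sample KS D: evaluate both ECDFs at every observed point.
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(fa - fb))
}

# Brute-force one-way repeated-measures ANOVA from raw sums of squares.
oracle_rm_anova_f <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_level <- n * sum((colMeans(m) - grand)^2)
  ss_subject <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_level - ss_subject
  (ss_level / (k - 1)) / (ss_error / ((n - 1) * (k - 1)))
}

# Pearson correlation from the raw covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Grid bin index (1-based) covering an integer degree.
bin_at <- function(deg) (round(deg) %% 360) + 1L

# Small helper: build a one-participant dataset data.frame by hand.
manual_dataset <- function(targets, bets, id = "s001", experiment = 1L,
                           undo_bet_index = NA_integer_,
                           undo_original_deg = NA_real_) {
  stopifnot(is.matrix(bets), nrow(bets) == length(targets))
  d <- data.frame(participant_id = id, experiment = experiment,
                  trial_index = seq_along(targets), target_deg = targets)
  for (k in seq_len(ncol(bets))) d[[paste0("bet", k, "_deg")]] <- bets[, k]
  d$undo_bet_index <- undo_bet_index
  d$undo_original_deg <- undo_original_deg
  class(d) <- c("bet_dataset", "data.frame")
  d
}
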