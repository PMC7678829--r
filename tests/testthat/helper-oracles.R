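# Brute-force oracles, written from the defining formulas and kept
# independent of the implementation paths they check.

# One-way within-subject sums-of-squares partition.
ss_oneway_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = F, df1 = k - 1, df2 = (k - 1) * (n - 1),
       p = stats::pf(F, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

# Two-way within-subject partition with subject-by-factor error terms.
ss_twoway_oracle <- function(arr) {
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  grand <- mean(arr)
  mA <- apply(arr, 2, mean); mB <- apply(arr, 3, mean)
  mS <- apply(arr, 1, mean)
  mSA <- apply(arr, c(1, 2), mean); mSB <- apply(arr, c(1, 3), mean)
  mAB <- apply(arr, c(2, 3), mean)
  ss_A <- n * b * sum((mA - grand)^2)
  ss_B <- n * a * sum((mB - grand)^2)
  ss_SA <- b * sum((mSA - outer(mS, rep(1, a)) - outer(rep(1, n), mA) + grand)^2)
  ss_SB <- a * sum((mSB - outer(mS, rep(1, b)) - outer(rep(1, n), mB) + grand)^2)
  ss_AB <- n * sum((mAB - outer(mA, rep(1, b)) - outer(rep(1, a), mB) + grand)^2)
  ss_tot <- sum((arr - grand)^2)
  ss_S <- a * b * sum((mS - grand)^2)
  ss_SAB <- ss_tot - ss_S - ss_A - ss_B - ss_AB - ss_SA - ss_SB
  FA <- (ss_A / (a - 1)) / (ss_SA / ((a - 1) * (n - 1)))
  FB <- (ss_B / (b - 1)) / (ss_SB / ((b - 1) * (n - 1)))
  FAB <- (ss_AB / ((a - 1) * (b - 1))) / (ss_SAB / ((a - 1) * (b - 1) * (n - 1)))
  list(FA = FA, FB = FB, FAB = FAB)
}

# Cumulative trapezoid 50%-area frequency.
cf50_oracle <- function(freq, P) {
  n <- length(freq)
  areas <- c(0, cumsum(diff(freq) * (P[-n] + P[-1]) / 2))
  half <- 0.5 * areas[n]
  i <- which(areas >= half)[1]
  if (i == 1) return(freq[1])
  freq[i - 1] + (half - areas[i - 1]) / (areas[i] - areas[i - 1]) * (freq[i] - freq[i - 1])
}
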