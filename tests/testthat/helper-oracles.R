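# Independent textbook-formula oracle for Welch's heteroscedastic one-way
# ANOVA, shared by the follow-up and end-to-end validation tests.

welch_oracle <- function(y, g) {
  # textbook Welch one-way formula, computed independently
  groups <- split(y, g)
  k <- length(groups)
  ni <- vapply(groups, length, numeric(1))
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, var, numeric(1))
  wi <- ni / vi
  W <- sum(wi)
  mw <- sum(wi * mi) / W
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  B <- 1 + (2 * (k - 2) / (k^2 - 1)) * sum((1 - wi / W)^2 / (ni - 1))
  f <- A / B
  df2 <- (k^2 - 1) / (3 * sum((1 - wi / W)^2 / (ni - 1)))
  p <- pf(f, k - 1, df2, lower.tail = FALSE)
  list(f = f, df1 = k - 1, df2 = df2, p = p)
}
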