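# Independent oracles used across tests. These deliberately avoid the code
# paths of the package functions they check.

# Moments of a normal(mean, sd) truncated to [lower, upper], by quadrature.
truncnorm_moments <- function(mean, sd, lower, upper) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mean, sd),
                         lower, upper)$value / z
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mean, sd),
                         lower, upper)$value / z
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

# Truncated-normal tail mass above a threshold, by the same quadrature route.
truncnorm_tail_above <- function(thr, mean, sd, lower, upper) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  stats::integrate(function(x) stats::dnorm(x, mean, sd),
                   max(thr, lower), upper)$value / z
}

# Sort-and-interpolate quantile (the type-7 rule), written out by hand.
quantile_type7_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(xs[n])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

# Explicit sum-of-squares decomposition for one-way ANOVA.
anova_f_oracle <- function(value, group) {
  group <- as.factor(group)
  grand <- mean(value)
  means <- tapply(value, group, mean)
  ns <- tapply(value, group, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((value - means[group])^2)
  k <- nlevels(group)
  n <- length(value)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Closed-form simple-regression coefficients from the normal equations.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# All symmetric logical k x k matrices with a FALSE diagonal, as a list.
all_signif_matrices <- function(k) {
  npairs <- k * (k - 1) / 2
  idx <- which(upper.tri(matrix(0, k, k)))
  lapply(seq_len(2^npairs) - 1L, function(code) {
    bits <- as.logical(bitwAnd(code, 2^(seq_len(npairs) - 1L)) > 0)
    m <- matrix(FALSE, k, k, dimnames = list(letters[seq_len(k)], letters[seq_len(k)]))
    m[idx] <- bits
    m | t(m)
  })
}

# Shared-letter predicate for compact-letter-display checks.
shares_letter <- function(cld, g1, g2) {
  l1 <- strsplit(cld$letters[cld$group == g1], "")[[1]]
  l2 <- strsplit(cld$letters[cld$group == g2], "")[[1]]
  length(intersect(l1, l2)) > 0
}

# TRUE iff a letter display is sound (significant pairs never share a letter)
# and complete (non-significant pairs always do) for matrix m.
cld_faithful <- function(m) {
  cld <- acrymoe::compact_letters(m)
  sets <- strsplit(cld$letters, "")
  k <- nrow(m)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      share <- length(intersect(sets[[i]], sets[[j]])) > 0
      if (share == m[i, j]) return(FALSE)
    }
  }
  TRUE
}
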