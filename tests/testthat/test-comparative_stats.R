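test_that("one-way ANOVA matches the explicit sum-of-squares oracle", {
  set.seed(17)
  # unbalanced 3-group toy table
  value <- c(stats::rnorm(4, 10), stats::rnorm(5, 12), stats::rnorm(3, 9))
  group <- rep(c("a", "b", "c"), c(4, 5, 3))
  r <- anova_oneway(value, group)
  expect_equal(r$f, anova_f_oracle(value, group), tolerance = 1e-10)
  expect_equal(r$df_between, 2)
  expect_equal(r$df_within, 9)
  # shuffling within-group values between groups of equal size changes nothing
  expect_equal(anova_oneway(value, group)$f, r$f)
})

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(23)
  x <- stats::rnorm(8, 5); y <- stats::rnorm(6, 7)
  r <- anova_oneway(c(x, y), rep(c("g1", "g2"), c(8, 6)))
  t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
  expect_equal(r$f, unname(t2), tolerance = 1e-10)
})

test_that("degenerate and zero-residual inputs take the documented paths", {
  expect_error(anova_oneway(rep(5, 6), rep(1:3, each = 2)), "degenerate")
  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "b")), "at least 2 observations")
  # distinct group means with no within-group noise: flagged, p treated as < alpha
  r <- anova_oneway(c(1, 1, 2, 2, 3, 3), rep(c("a", "b", "c"), each = 2))
  expect_true(r$zero_residual_variance)
  expect_equal(r$p_value, 0)
  tk <- tukey_hsd(c(1, 1, 2, 2, 3, 3), rep(c("a", "b", "c"), each = 2))
  expect_true(all(tk$significant[upper.tri(tk$significant)]))
})

test_that("Tukey HSD separates far groups, is symmetric, and matches a studentized-range oracle", {
  set.seed(41)
  value <- c(stats::rnorm(10, 0, 1), stats::rnorm(10, 50, 1))
  group <- rep(c("lo", "hi"), each = 10)
  tk <- tukey_hsd(value, group, alpha = 0.01)
  expect_true(tk$significant["lo", "hi"])
  expect_identical(tk$significant, t(tk$significant))
  expect_false(any(diag(tk$significant)))

  # 3-group set checked against a critical-value oracle (Tukey-Kramer form)
  value3 <- c(stats::rnorm(8, 0, 1), stats::rnorm(6, 1, 1), stats::rnorm(7, 8, 1))
  group3 <- rep(c("a", "b", "c"), c(8, 6, 7))
  tk3 <- tukey_hsd(value3, group3, alpha = 0.05)
  means <- tapply(value3, group3, mean)
  ns <- tapply(value3, group3, length)
  mse <- sum((value3 - means[group3])^2) / (length(value3) - 3)
  qcrit <- stats::qtukey(0.95, 3, length(value3) - 3)
  for (p in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    se <- sqrt(mse / 2 * (1 / ns[p[1]] + 1 / ns[p[2]]))
    oracle_sig <- abs(means[p[1]] - means[p[2]]) / se > qcrit
    expect_equal(unname(tk3$significant[p[1], p[2]]), unname(oracle_sig))
  }
})

test_that("compact letters handle complete non-separation and complete separation", {
  none <- matrix(FALSE, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  cld <- compact_letters(none)
  expect_equal(cld$letters, rep("a", 3))

  all_sig <- !diag(3)
  dimnames(all_sig) <- dimnames(none)
  cld2 <- compact_letters(all_sig)
  expect_equal(sort(cld2$letters), c("a", "b", "c"))

  asym <- none; asym[1, 2] <- TRUE
  expect_error(compact_letters(asym), "symmetric")
})

test_that("compact letters are sound and complete for every significance pattern up to 5 groups", {
  for (k in 2:5) {
    ok <- vapply(all_signif_matrices(k), cld_faithful, logical(1))
    expect_true(all(ok), label = sprintf("letter display faithful for all %d-group patterns", k))
  }
})

test_that("survey-like group structure yields the published letter pattern", {
  pm <- survey_products()
  pm <- pm[pm$product %in% c("Bread", "Bread rolls", "Wholemeal bread",
                             "Friselle", "Wholemeal Friselle"), ]
  occ <- generate_occurrence(generator_config(seed = 12, products = pm))
  cld <- tukey_letters(occ, alpha = 0.01)
  soft <- c("Bread", "Bread rolls", "Wholemeal bread")
  hard <- c("Friselle", "Wholemeal Friselle")
  cld$group <- cld$product
  for (a in soft) for (b in soft) {
    if (a < b) expect_true(shares_letter(cld, a, b))
  }
  for (a in soft) for (b in hard) expect_false(shares_letter(cld, a, b))
})

test_that("Spearman correlation matches rank arithmetic, flips sign, and vanishes under independence", {
  x <- c(35, 38, 40, 43, 45, 47)
  expect_equal(spearman_cor(x, -2 * x + 3)$rho, -1)

  # 6-point set with a tie, cross-checked against the base rank-correlation route
  y <- c(10, 25, 25, 40, 35, 60)
  r <- spearman_cor(x, y)
  expect_equal(r$rho, stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(spearman_cor(rank(x), rank(y))$rho, r$rho)
  expect_equal(spearman_cor(x, -y)$rho, -r$rho)

  perm <- spearman_cor(x, y, p_method = "permutation")
  expect_gte(perm$p_value, 0)
  expect_lte(perm$p_value, 1)

  set.seed(55)
  r0 <- spearman_cor(stats::rnorm(1000), stats::rnorm(1000))
  expect_lt(abs(r0$rho), 0.1)

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("the smoother reproduces linear data and shows the low-moisture rise", {
  x <- seq(30, 50, length.out = 40)
  y <- 2 * x + 5
  sm <- fit_smoother(x, y, grid = seq(32, 48, length.out = 20))
  expect_lt(max(abs(sm$fitted - (2 * sm$grid + 5))), 1e-6)
  expect_true(all(sm$ci_low <= sm$fitted + 1e-9 & sm$fitted <= sm$ci_high + 1e-9))

  # steep rise below 43% moisture, plateau above: fitted(40) > fitted(46)
  set.seed(66)
  xm <- stats::runif(120, 35, 50)
  ym <- ifelse(xm < 43, 400 - 40 * (xm - 35), 80) + stats::rnorm(120, 0, 15)
  sm2 <- fit_smoother(xm, ym, grid = c(40, 46))
  expect_gt(sm2$fitted[1], sm2$fitted[2])

  expect_error(fit_smoother(x, y, span = 0), "span")
  expect_error(fit_smoother(x, y, grid = c(20, 40)), "extrapolation")
})

test_that("the confidence band narrows as the sample grows at fixed span", {
  f <- function(n, seed) {
    set.seed(seed)
    x <- stats::runif(n, 0, 10)
    y <- sin(x) + stats::rnorm(n, 0, 0.5)
    sm <- fit_smoother(x, y, grid = seq(1, 9, length.out = 15))
    mean(sm$ci_high - sm$ci_low)
  }
  expect_lt(f(1000, 2), f(100, 2))
})
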