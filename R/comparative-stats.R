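check_groups <- function(value, group) {
  if (length(value) != length(group)) abort_bad_arg("value and group must have equal length.")
  group <- as.factor(group)
  if (nlevels(group) < 2L) abort_bad_arg("need at least 2 groups.")
  if (any(table(group) < 2L)) abort_bad_arg("every group needs at least 2 observations.")
  if (stats::var(value) == 0) {
    abort_bad_arg("all observations are equal: the F statistic is degenerate (0/0).")
  }
  droplevels(group)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA on possibly unbalanced groups,
#' fitted with [stats::aov()]. When the within-group (residual) variance is
#' exactly zero but group means differ, the F statistic is infinite; the
#' result is flagged and the p-value reported as 0 so downstream post-hoc
#' logic treats every contrast as significant.
#'
#' @param value Numeric response vector.
#' @param group Grouping vector; >= 2 groups, each with >= 2 observations.
#' @return A list: `f`, `p_value`, `df_between`, `df_within`,
#'   `zero_residual_variance` flag, and the underlying `aov` fit.
#' @export
#' @examples
#' anova_oneway(c(1, 2, 5, 6, 9, 10), rep(c("a", "b", "c"), each = 2))
anova_oneway <- function(value, group) {
  group <- check_groups(value, group)
  fit <- stats::aov(value ~ group)
  tab <- summary(fit)[[1]]
  total_ss <- sum(tab[, "Sum Sq"])
  zero_res <- tab["Residuals", "Sum Sq"] <= 1e-12 * total_ss
  f <- if (zero_res) Inf else tab["group", "F value"]
  p <- if (zero_res) 0 else tab["group", "Pr(>F)"]
  list(
    f = unname(f), p_value = unname(p),
    df_between = unname(tab["group", "Df"]),
    df_within = unname(tab["Residuals", "Df"]),
    zero_residual_variance = zero_res,
    fit = fit
  )
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs studentized-range tests after a one-way ANOVA, with the
#' Tukey-Kramer adjustment for unequal group sizes (as implemented by
#' [stats::TukeyHSD()]). Returns symmetric matrices; the diagonal (a group
#' against itself) is never significant.
#'
#' @inheritParams anova_oneway
#' @param alpha Familywise significance level; default 0.01.
#' @return A list: `p_values` (symmetric matrix of adjusted p-values, 1 on
#'   the diagonal), `significant` (symmetric logical matrix), `alpha`.
#' @export
tukey_hsd <- function(value, group, alpha = 0.01) {
  check_number(alpha, "alpha", lower = 0, strict = TRUE)
  group <- check_groups(value, group)
  fit <- stats::aov(value ~ group)
  tab <- summary(fit)[[1]]
  zero_res <- tab["Residuals", "Sum Sq"] <= 1e-12 * sum(tab[, "Sum Sq"])
  lev <- levels(group)
  k <- length(lev)
  p <- matrix(1, k, k, dimnames = list(lev, lev))
  if (zero_res) {
    # no residual noise: any difference in means is significant
    gm <- tapply(value, group, mean)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        p[i, j] <- p[j, i] <- if (gm[i] == gm[j]) 1 else 0
      }
    }
  } else {
    tk <- stats::TukeyHSD(fit)$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (r in seq_along(pairs)) {
      a <- pairs[[r]][1]; b <- pairs[[r]][2]
      p[a, b] <- p[b, a] <- tk[r, "p adj"]
    }
  }
  sig <- p < alpha
  diag(sig) <- FALSE
  list(p_values = p, significant = sig, alpha = alpha)
}

#' Compact letter display
#'
#' Encodes a symmetric pairwise significance matrix as letters using the
#' insert-and-absorb algorithm: start with one letter covering all groups;
#' for each significant pair that still shares a letter, duplicate that
#' letter's group set and delete one member from each copy; finally absorb
#' letter sets contained in another. Two groups share a letter if and only if
#' their comparison is non-significant. Letters are assigned in input (row)
#' order of the matrix.
#'
#' @param significant Symmetric logical matrix (`TRUE` = significantly
#'   different), with group names as dimnames; diagonal must be `FALSE`.
#' @return A tibble with columns `group` and `letters` (e.g. `"a"`, `"bc"`).
#' @export
#' @examples
#' m <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2,
#'             dimnames = list(c("x", "y"), c("x", "y")))
#' compact_letters(m)
compact_letters <- function(significant) {
  if (!is.matrix(significant) || nrow(significant) != ncol(significant)) {
    abort_bad_arg("`significant` must be a square matrix.")
  }
  if (!isTRUE(all(significant == t(significant)))) {
    abort_bad_arg("`significant` must be symmetric.")
  }
  if (any(diag(significant))) abort_bad_arg("a group cannot differ from itself.")
  k <- nrow(significant)
  groups <- rownames(significant) %||% as.character(seq_len(k))

  cols <- list(seq_len(k))  # each column: indices of groups carrying that letter
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i || !significant[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, j)), list(setdiff(col, i)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a == b || !keep[a]) next
          if (all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order letters by first group they cover, then assign a, b, c, ...
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  alphabet <- c(letters, paste0(rep(letters, each = 26), rep(letters, 26)))
  lab <- vapply(seq_len(k), function(g) {
    paste0(alphabet[which(vapply(cols, function(col) g %in% col, logical(1)))],
           collapse = "")
  }, character(1))
  tibble::tibble(group = groups, letters = lab)
}

#' Tukey letters for a sample table
#'
#' Convenience wrapper: one-way ANOVA + Tukey HSD + compact letter display on
#' a tidy occurrence table, the encoding used for summary-table superscripts.
#'
#' @param samples Tibble with `product` and `concentration` columns.
#' @param alpha Familywise level for the post-hoc test (default 0.01).
#' @return A tibble `product`, `letters`.
#' @export
tukey_letters <- function(samples, alpha = 0.01) {
  tk <- tukey_hsd(samples$concentration, samples$product, alpha = alpha)
  out <- compact_letters(tk$significant)
  names(out)[1] <- "product"
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The default p-value uses the
#' t approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of
#' freedom (adequate at the survey's n = 66); an exact permutation p-value is
#' available for n <= 8, where complete enumeration is feasible.
#'
#' @param x,y Numeric vectors, length >= 3, neither constant.
#' @param p_method `"t"` (default) or `"permutation"` (exact, n <= 8 only).
#' @return A list: `rho`, `p_value`, `n`, `p_method`.
#' @export
#' @examples
#' spearman_cor(1:10, -(1:10))$rho  # -1
spearman_cor <- function(x, y, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) abort_bad_arg("x and y must have equal length.")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort_bad_arg("need at least 3 complete pairs.")
  if (stats::var(x) == 0 || stats::var(y) == 0) abort_bad_arg("x and y must not be constant.")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (p_method == "t") {
    if (abs(rho) >= 1) {
      0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 8L) abort_bad_arg("exact permutation p-value supported for n <= 8 only.")
    perms <- all_permutations(n)
    null_rho <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    mean(abs(null_rho) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p_value = p, n = n, p_method = p_method)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Locally weighted smoother with confidence band
#'
#' Locally weighted linear regression (LOESS, degree 1) of concentration on a
#' covariate such as dough moisture, evaluated on a grid with a pointwise 95%
#' confidence band from the normal approximation fitted +/- 1.96 standard
#' errors. Grid points outside the observed covariate range are refused —
#' local regression does not extrapolate.
#'
#' @param x Covariate (e.g. moisture %), n >= 10.
#' @param y Response (e.g. concentration ug/kg).
#' @param span LOESS span in (0, 1]; default 0.75.
#' @param grid Evaluation points; default 50 equispaced points over
#'   `range(x)`.
#' @param level Confidence level for the band (default 0.95).
#' @return A tibble: `grid`, `fitted`, `ci_low`, `ci_high`; the span is
#'   attached as attribute `span`.
#' @export
fit_smoother <- function(x, y, span = 0.75, grid = NULL, level = 0.95) {
  if (length(x) != length(y)) abort_bad_arg("x and y must have equal length.")
  if (length(x) < 10L) abort_bad_arg("need at least 10 observations to smooth.")
  if (!is.numeric(span) || span <= 0 || span > 1) abort_bad_arg("span must lie in (0, 1].")
  grid <- grid %||% seq(min(x), max(x), length.out = 50)
  if (any(grid < min(x)) || any(grid > max(x))) {
    abort_bad_arg("grid points outside the data range: extrapolation refused.")
  }
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(fit, newdata = data.frame(x = grid), se = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- tibble::tibble(
    grid = grid,
    fitted = as.numeric(pr$fit),
    ci_low = as.numeric(pr$fit - z * pr$se.fit),
    ci_high = as.numeric(pr$fit + z * pr$se.fit)
  )
  attr(out, "span") <- span
  out
}
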