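#' Substitute censored concentrations
#'
#' Replaces the concentration of records flagged as censored (below the limit
#' of quantification) according to a substitution policy, leaving uncensored
#' records untouched. For censored records the stored concentration is the
#' LOQ placeholder, not a measurement, so substitution must happen before any
#' aggregation.
#'
#' @param samples Occurrence tibble with columns `concentration` and
#'   `censored`.
#' @param policy One of `"zero"` (substitute 0), `"half_loq"` (LOQ/2) or
#'   `"loq"` (the LOQ itself).
#' @param loq Limit of quantification in ug/kg; default 25, the survey
#'   method's LOQ.
#' @return `samples` with censored concentrations substituted.
#' @export
#' @examples
#' s <- tibble::tibble(concentration = c(25, 40), censored = c(TRUE, FALSE))
#' substitute_censored(s, "half_loq")$concentration  # 12.5, 40
substitute_censored <- function(samples, policy = c("half_loq", "zero", "loq"), loq = 25) {
  policy <- match.arg(policy)
  check_number(loq, "loq", lower = 0, strict = TRUE)
  if (!all(c("concentration", "censored") %in% names(samples))) {
    abort_bad_arg("`samples` needs `concentration` and `censored` columns.")
  }
  sub <- switch(policy, zero = 0, half_loq = loq / 2, loq = loq)
  samples$concentration[samples$censored] <- sub
  samples
}

#' Summarise concentrations for one product
#'
#' Computes the summary row used in occurrence-survey tables: n, mean, sample
#' standard deviation (n - 1 denominator), median, 95th percentile, minimum
#' and maximum. The percentile rule defaults to linear interpolation between
#' order statistics (type 7); it is configurable because a 95th percentile on
#' ~20 samples is sensitive to the rule. A single observation yields sd = 0
#' with a warning rather than an error, so tiny fixtures survive the pipeline.
#'
#' @param concentration Numeric vector of concentrations (ug/kg), n >= 1.
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7).
#' @return A one-row tibble: `n`, `mean`, `sd`, `median`, `p95`, `min`, `max`.
#' @export
#' @examples
#' summarize_concentrations(c(31, 55, 90))
summarize_concentrations <- function(concentration, quantile_type = 7) {
  x <- concentration
  if (length(x) == 0L) abort_bad_arg("cannot summarise an empty sample set.")
  if (anyNA(x)) abort_bad_arg("concentrations contain missing values.")
  s <- if (length(x) == 1L) {
    warning("single observation: sd reported as 0 by convention", call. = FALSE)
    0
  } else {
    stats::sd(x)
  }
  tibble::tibble(
    n = length(x),
    mean = mean(x),
    sd = s,
    median = unname(stats::quantile(x, 0.5, type = quantile_type)),
    p95 = unname(stats::quantile(x, 0.95, type = quantile_type)),
    min = min(x),
    max = max(x)
  )
}

#' Per-product summary table of an occurrence survey
#'
#' Applies [summarize_concentrations()] within each product of a tidy sample
#' table, after optional censoring substitution.
#'
#' @param samples Occurrence tibble (see [generate_occurrence()] for the
#'   column contract). Must contain `product` and `concentration`; when a
#'   `censored` column is present, censored records must have been substituted
#'   already or `censor_policy` must be given.
#' @param censor_policy Optional substitution policy forwarded to
#'   [substitute_censored()].
#' @param loq LOQ used for substitution when `censor_policy` is given.
#' @param quantile_type Percentile rule, see [summarize_concentrations()].
#' @return A tibble with one row per product (and its `category` when
#'   available): `product`, `n`, `mean`, `sd`, `median`, `p95`, `min`, `max`.
#' @export
#' @examples
#' occ <- generate_occurrence(generator_config(seed = 7))
#' summarize_products(occ)
summarize_products <- function(samples, censor_policy = NULL, loq = 25,
                               quantile_type = 7) {
  if (!all(c("product", "concentration") %in% names(samples))) {
    abort_bad_arg("`samples` needs `product` and `concentration` columns.")
  }
  if (!is.null(censor_policy)) {
    samples <- substitute_censored(samples, censor_policy, loq)
  }
  grouping <- intersect(c("category", "product"), names(samples))
  samples |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::reframe(summarize_concentrations(.data$concentration, quantile_type)) |>
    dplyr::ungroup()
}
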