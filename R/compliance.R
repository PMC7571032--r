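#' Screen a product summary against its benchmark level
#'
#' Compares one summary statistic with the product's regulatory benchmark
#' level (EU Regulation 2017/2158 values by default). "Should not exceed"
#' reads as strict inequality: a value exactly at the benchmark is compliant.
#' Benchmarks are configuration data, so other regulatory tables can be
#' screened.
#'
#' @param summary One-row product summary (see [summarize_products()]) or any
#'   list-like with the chosen statistic.
#' @param benchmark_level Benchmark level in ug/kg, > 0.
#' @param statistic Which statistic to screen: `"mean"`, `"median"`, `"p95"`
#'   or `"max"`.
#' @return A list with `value`, `benchmark_level`, `exceeds` (logical, strict)
#'   and `margin` (value minus benchmark, ug/kg).
#' @export
#' @examples
#' screen_benchmark(list(median = 55), 50, "median")  # exceeds by 5
screen_benchmark <- function(summary, benchmark_level,
                             statistic = c("median", "mean", "p95", "max")) {
  statistic <- match.arg(statistic)
  check_number(benchmark_level, "benchmark_level", lower = 0, strict = TRUE)
  value <- summary[[statistic]]
  if (is.null(value) || is.na(value)) {
    abort_bad_arg(sprintf("statistic `%s` is absent from the summary.", statistic))
  }
  list(
    statistic = statistic,
    value = value,
    benchmark_level = benchmark_level,
    exceeds = value > benchmark_level,
    margin = value - benchmark_level
  )
}

#' Benchmark screening report for a summary table
#'
#' Vectorised screening of a per-product summary table against a benchmark
#' table, one row per product and statistic.
#'
#' @param summaries Product summary tibble from [summarize_products()].
#' @param benchmarks Tibble with columns `product` and `benchmark_level`
#'   (default: the survey's EU 2017/2158 table).
#' @param statistics Character vector of statistics to screen.
#' @return A tibble: `product`, `statistic`, `value`, `benchmark_level`,
#'   `exceeds`, `margin`.
#' @export
screen_benchmarks <- function(summaries,
                              benchmarks = survey_products()[, c("product", "benchmark_level")],
                              statistics = c("mean", "median")) {
  stats_ok <- statistics %in% c("mean", "median", "p95", "max")
  if (!all(stats_ok)) abort_bad_arg("unknown statistic in `statistics`.")
  joined <- dplyr::inner_join(summaries, benchmarks, by = "product")
  if (nrow(joined) == 0L) abort_bad_arg("no products in common between summaries and benchmarks.")
  long <- tidyr::pivot_longer(
    joined[, c("product", statistics, "benchmark_level")],
    cols = dplyr::all_of(statistics),
    names_to = "statistic", values_to = "value"
  )
  long$exceeds <- long$value > long$benchmark_level
  long$margin <- long$value - long$benchmark_level
  long[, c("product", "statistic", "value", "benchmark_level", "exceeds", "margin")]
}

#' Fraction of individual samples above a benchmark
#'
#' Proportion of samples strictly exceeding the benchmark level.
#'
#' @param concentration Numeric vector of per-sample concentrations (ug/kg),
#'   n >= 1.
#' @param benchmark_level Benchmark level in ug/kg, > 0.
#' @return Proportion in \[0, 1\].
#' @export
#' @examples
#' sample_exceedance_fraction(c(49, 50, 51), 50)  # 1/3
sample_exceedance_fraction <- function(concentration, benchmark_level) {
  check_number(benchmark_level, "benchmark_level", lower = 0, strict = TRUE)
  if (length(concentration) == 0L) abort_bad_arg("no samples supplied.")
  mean(concentration > benchmark_level)
}
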