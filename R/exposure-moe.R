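#' Chronic daily intake
#'
#' Deterministic daily-intake estimate DI = C x Q / BW. With concentration in
#' ug/kg (identically ng/g), consumption in g/day and body weight in kg, the
#' result is in ng/kg bw/day with no further conversion factor.
#'
#' @param c_conc Concentration in ug/kg (= ng/g), >= 0.
#' @param q Daily consumption in g/day, >= 0.
#' @param bw Body weight in kg, > 0.
#' @return Daily intake in ng/kg bw/day.
#' @export
#' @examples
#' daily_intake(100, 150, 60)  # 250 ng/kg bw/day
daily_intake <- function(c_conc, q, bw) {
  if (any(c_conc < 0) || any(q < 0)) abort_bad_arg("concentration and consumption must be >= 0.")
  if (any(bw <= 0)) abort_bad_arg("body weight must be > 0.")
  c_conc * q / bw
}

#' Best/worst-scenario daily-intake grid
#'
#' Crosses consumer percentile (median and 95th-percentile consumer, i.e.
#' which consumption quantile Q enters the formula) with concentration
#' scenario (BS: C is the product's median concentration; WS: C is its 95th
#' percentile) for every product and age group — four intake values per
#' (product, age group) cell.
#'
#' @param summaries Product summary tibble with `product`, `median`, `p95`
#'   columns (ug/kg), e.g. from [summarize_products()] or built from a
#'   published summary table.
#' @param profiles Consumption tibble with `product`, `age_group`,
#'   `q_median`, `q_p95` (g/day) and `bw` (kg), e.g. [survey_consumption()].
#' @return A tibble: `product`, `age_group`, `consumer_percentile`
#'   (`"median"`/`"p95"`), `scenario` (`"BS"`/`"WS"`), `di` (ng/kg bw/day,
#'   full precision) and `di_rounded` (nearest integer, half away from zero,
#'   as intake tables are conventionally printed).
#' @export
#' @examples
#' s <- tibble::tibble(product = "Bread", median = 55, p95 = 82)
#' p <- tibble::tibble(product = "Bread", age_group = "adolescents",
#'                     q_median = 84, q_p95 = 236, bw = 55)
#' scenario_grid(s, p)
scenario_grid <- function(summaries, profiles) {
  needed_s <- c("product", "median", "p95")
  needed_p <- c("product", "age_group", "q_median", "q_p95", "bw")
  if (!all(needed_s %in% names(summaries))) {
    abort_bad_arg("summaries need product, median and p95 columns.")
  }
  if (!all(needed_p %in% names(profiles))) {
    abort_bad_arg("profiles need product, age_group, q_median, q_p95 and bw columns.")
  }
  joined <- dplyr::inner_join(
    profiles[, needed_p], summaries[, needed_s], by = "product"
  )
  if (nrow(joined) == 0L) abort_bad_arg("no products in common between summaries and profiles.")
  missing <- setdiff(profiles$product, summaries$product)
  if (length(missing)) {
    warning("no concentration summary for: ", paste(missing, collapse = ", "),
            "; those cells are omitted.", call. = FALSE)
  }
  cells <- tidyr::expand_grid(
    consumer_percentile = c("median", "p95"),
    scenario = c("BS", "WS")
  )
  out <- tidyr::crossing(joined, cells)
  q <- ifelse(out$consumer_percentile == "median", out$q_median, out$q_p95)
  conc <- ifelse(out$scenario == "BS", out$median, out$p95)
  out$di <- daily_intake(conc, q, out$bw)
  out$di_rounded <- round_half_away(out$di)
  dplyr::arrange(
    out[, c("product", "age_group", "consumer_percentile", "scenario", "di", "di_rounded")],
    .data$product, .data$age_group, .data$consumer_percentile, .data$scenario
  )
}

#' Margin of exposure
#'
#' MOE = BMDL10 / DI with the BMDL10 in mg/kg bw/day and the intake in
#' ng/kg bw/day, hence an explicit 10^6 mg-to-ng conversion. An intake of
#' zero makes the MOE undefined; it is reported as non-computable (`NA`)
#' rather than infinite. Threshold classification uses the unrounded MOE.
#'
#' @param di Daily intake in ng/kg bw/day, > 0.
#' @param bmdl10 Benchmark-dose lower confidence limit in mg/kg bw/day, > 0.
#' @return The dimensionless margin of exposure (full precision).
#' @export
#' @examples
#' margin_of_exposure(351, 0.17)  # ~484: carcinogenic endpoint, highest intake
margin_of_exposure <- function(di, bmdl10) {
  if (any(bmdl10 <= 0)) abort_bad_arg("bmdl10 must be > 0.")
  if (any(di < 0)) abort_bad_arg("daily intake must be >= 0.")
  ifelse(di == 0, NA_real_, bmdl10 * 1e6 / di)
}

#' Classify an MOE against its endpoint threshold
#'
#' Neurotoxicity is of low concern at an MOE of 125 or above (inclusive);
#' carcinogenicity is of low concern only strictly above 10,000. A
#' non-computable MOE classifies as `"not_computable"`.
#'
#' @param moe Margin of exposure (unrounded), or `NA` when non-computable.
#' @param moe_threshold Threshold of low concern.
#' @param inclusive Whether an MOE equal to the threshold already counts as
#'   low concern (`TRUE` for the neurotoxic endpoint, `FALSE` for the
#'   carcinogenic one).
#' @return `"low_concern"`, `"concern"` or `"not_computable"`.
#' @export
#' @examples
#' classify_concern(125, 125, inclusive = TRUE)     # low_concern
#' classify_concern(10000, 10000, inclusive = FALSE) # concern
classify_concern <- function(moe, moe_threshold, inclusive) {
  check_number(moe_threshold, "moe_threshold", lower = 0, strict = TRUE)
  stopifnot(is.logical(inclusive), length(inclusive) == 1L)
  ifelse(
    is.na(moe), "not_computable",
    ifelse(if (inclusive) moe >= moe_threshold else moe > moe_threshold,
           "low_concern", "concern")
  )
}

#' Margin-of-exposure report for an intake grid
#'
#' Crosses every intake cell with every toxicological endpoint and classifies
#' the result. MOE values are computed from the full-precision intake;
#' `moe_rounded` (nearest integer, half away from zero) is for presentation.
#'
#' @param intake Intake tibble with a `di` column, e.g. from
#'   [scenario_grid()] or a published intake table.
#' @param endpoints Endpoint tibble in the format of
#'   [acrylamide_endpoints()] (the default).
#' @return `intake` expanded with `endpoint`, `bmdl10`, `moe`, `moe_rounded`
#'   and `concern` columns.
#' @export
#' @examples
#' moe_report(survey_intake_grid())
moe_report <- function(intake, endpoints = acrylamide_endpoints()) {
  if (!"di" %in% names(intake)) abort_bad_arg("intake table needs a `di` column.")
  needed <- c("endpoint", "bmdl10", "moe_threshold", "threshold_inclusive")
  if (!all(needed %in% names(endpoints))) {
    abort_bad_arg("endpoints need endpoint, bmdl10, moe_threshold, threshold_inclusive.")
  }
  out <- tidyr::crossing(intake, endpoints[, needed])
  out$moe <- margin_of_exposure(out$di, out$bmdl10)
  out$moe_rounded <- round_half_away(out$moe)
  out$concern <- mapply(
    classify_concern, out$moe, out$moe_threshold, out$threshold_inclusive
  )
  out$moe_threshold <- NULL
  out$threshold_inclusive <- NULL
  out
}
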