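#' Survey-calibrated product models
#'
#' Per-product concentration summary statistics, sample counts, recipe ranges
#' and EU Regulation 2017/2158 benchmark levels from a 2020 market survey of
#' Italian baked products (200 specimens: 102 bread-type, 98 sweets).
#' Concentrations are acrylamide in ug/kg; recipe attributes are percentages
#' of the dough/batter before baking. These rows parametrise the synthetic
#' occurrence generator (parent normal mean/sd, truncation bounds) and supply
#' the benchmark table for compliance screening.
#'
#' @return A tibble with one row per product: `product`, `category`
#'   (`"bread"` or `"sweets"`), `n_samples`, `conc_mean`, `conc_sd`,
#'   `conc_median`, `conc_p95`, `conc_min`, `conc_max` (ug/kg),
#'   `benchmark_level` (ug/kg), and recipe range bounds `moisture_lo`,
#'   `moisture_hi`, `sugars_lo`, `sugars_hi`, `salt_lo`, `salt_hi` (%).
#' @export
#' @examples
#' survey_products()
survey_products <- function() {
  tibble::tribble(
    ~product, ~category, ~n_samples,
    ~conc_mean, ~conc_sd, ~conc_median, ~conc_p95, ~conc_min, ~conc_max,
    ~benchmark_level,
    ~moisture_lo, ~moisture_hi, ~sugars_lo, ~sugars_hi, ~salt_lo, ~salt_hi,
    "Bread",              "bread",  22L,  57, 18,  55,  82,  31,  90,  50, 41, 43, 1.0, 1.2, 1.6, 1.8,
    "Bread rolls",        "bread",  22L,  52,  8,  55,  64,  42,  67,  50, 42, 48, 1.0, 1.2, 1.5, 1.7,
    "Wholemeal bread",    "bread",  22L,  61, 10,  60,  80,  44,  88,  50, 41, 45, 1.0, 1.2, 1.6, 1.8,
    "Friselle",           "bread",  18L, 358, 36, 353, 403, 306, 454, 350, 39, 42, 1.1, 1.3, 1.7, 1.9,
    "Wholemeal Friselle", "bread",  18L, 384, 37, 375, 450, 328, 450, 350, 35, 40, 1.2, 1.4, 1.5, 1.8,
    "Butter cookies",     "sweets", 20L, 310, 36, 330, 346, 249, 350, 350, 14, 18,  36,  39, 0.5, 0.8,
    "Baba cake",          "sweets", 20L, 292, 62, 278, 391, 207, 400, 300, 43, 46,   5,   6, 0.0, 0.1,
    "Ice cream wafers",   "sweets", 20L, 337,  5, 336, 344, 330, 346, 350, 34, 35,  22,  24, 0.0, 0.1,
    "Frolla cake",        "sweets", 18L, 362, 11, 356, 380, 350, 380, 300, 30, 32,   3,   5, 0.0, 0.1,
    "Croissants",         "sweets", 20L, 313, 55, 330, 382, 204, 396, 300, 36, 38,  10,  12, 1.0, 1.1
  )
}

#' Default body weights by age group
#'
#' Nominal Italian anthropometric values: 55 kg for adolescents and 70 kg for
#' adults and the elderly (the same weight is used for both adult groups).
#' Fully overridable wherever a `bw_by_group` argument is accepted.
#'
#' @return Named numeric vector of body weights in kg.
#' @export
survey_body_weights <- function() {
  c(adolescents = 55, adults = 70, elderly = 70)
}

#' Toxicological endpoints for acrylamide risk characterisation
#'
#' Benchmark-dose lower confidence limits (BMDL10) and margin-of-exposure
#' thresholds of low concern: 0.43 mg/kg bw/day for peripheral-nerve axonal
#' degeneration in rats (neurotoxicity, MOE threshold 125, low concern at or
#' above the threshold) and 0.17 mg/kg bw/day for Harderian-gland
#' adenocarcinomas in mice (carcinogenicity, MOE threshold 10,000, low
#' concern strictly above the threshold).
#'
#' @return A tibble with columns `endpoint`, `bmdl10` (mg/kg bw/day),
#'   `moe_threshold`, and `threshold_inclusive` (whether an MOE equal to the
#'   threshold already counts as low concern).
#' @export
#' @examples
#' acrylamide_endpoints()
acrylamide_endpoints <- function() {
  tibble::tibble(
    endpoint = c("neurotoxic", "carcinogenic"),
    bmdl10 = c(0.43, 0.17),
    moe_threshold = c(125, 10000),
    threshold_inclusive = c(TRUE, FALSE)
  )
}

#' Published daily-intake grid for bread-type products
#'
#' The daily-intake table of the survey (ng/kg bw/day) for median consumers
#' and consumers at the 95th percentile, across three age groups and the
#' best (BS: median concentration) and worst (WS: 95th-percentile
#' concentration) scenarios. Bread rolls are absent because their consumption
#' is reported jointly with bread in the source database; sweets are absent
#' because reliable consumption rates are lacking.
#'
#' These printed values serve as a regression surface for the exposure
#' pipeline and as inputs for margin-of-exposure worked examples.
#'
#' @return A tibble with columns `product`, `age_group`,
#'   `consumer_percentile` (`"median"`/`"p95"`), `scenario` (`"BS"`/`"WS"`),
#'   `di` (ng/kg bw/day).
#' @export
#' @examples
#' max(survey_intake_grid()$di)  # 351, the highest published intake
survey_intake_grid <- function() {
  grid <- tibble::tribble(
    ~product, ~consumer_percentile,
    ~adolescents_bs, ~adolescents_ws, ~adults_bs, ~adults_ws, ~elderly_bs, ~elderly_ws,
    "Bread",              "median",  84, 125,  59,  88,  71, 105,
    "Wholemeal bread",    "median",  75, 100,  43,  57,  60,  80,
    "Friselle",           "median",  68,  78,  67,  77,  81,  92,
    "Wholemeal Friselle", "median",  50,  70,  86, 103, 114, 137,
    "Bread",              "p95",    236, 351, 189, 281, 165, 246,
    "Wholemeal bread",    "p95",    137, 182, 171, 229, 174, 232,
    "Friselle",           "p95",    173, 197, 161, 184, 197, 225,
    "Wholemeal Friselle", "p95",    230, 276, 214, 257, 213, 255
  )
  long <- tidyr::pivot_longer(
    grid,
    cols = -c("product", "consumer_percentile"),
    names_to = c("age_group", "scenario"),
    names_sep = "_",
    values_to = "di"
  )
  long$scenario <- toupper(long$scenario)
  long[, c("product", "age_group", "consumer_percentile", "scenario", "di")]
}

#' Survey-calibrated consumption profiles
#'
#' Daily consumption quantities (g/day) per product and age group,
#' reconstructed by inverting the intake equation DI = C x Q / BW against the
#' published best-scenario intakes and the published median concentrations:
#' Q = DI_BS x BW / C_median, separately for median consumers (`q_median`)
#' and consumers at the 95th percentile (`q_p95`). The original consumption
#' extractions from the EFSA Comprehensive Database are not recoverable, so
#' this synthetic reconstruction makes the published intake grid an
#' end-to-end regression surface: running the exposure pipeline on these
#' profiles reproduces the best-scenario intake columns exactly.
#'
#' @param bw_by_group Named numeric vector of body weights (kg); defaults to
#'   [survey_body_weights()].
#' @return A tibble with columns `product`, `age_group`, `q_median`, `q_p95`
#'   (g/day), `bw` (kg).
#' @export
#' @examples
#' survey_consumption()
survey_consumption <- function(bw_by_group = survey_body_weights()) {
  grid <- survey_intake_grid()
  bs <- grid[grid$scenario == "BS", ]
  med <- survey_products()[, c("product", "conc_median")]
  bs <- dplyr::inner_join(bs, med, by = "product")
  bs$bw <- unname(bw_by_group[bs$age_group])
  if (anyNA(bs$bw)) abort_bad_arg("`bw_by_group` is missing an age group present in the intake grid.")
  bs$q <- bs$di * bs$bw / bs$conc_median
  wide <- tidyr::pivot_wider(
    bs[, c("product", "age_group", "consumer_percentile", "bw", "q")],
    names_from = "consumer_percentile", values_from = "q",
    names_prefix = "q_"
  )
  out <- wide[, c("product", "age_group", "q_median", "q_p95", "bw")]
  out$q_median <- as.numeric(out$q_median)
  out$q_p95 <- as.numeric(out$q_p95)
  out
}
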