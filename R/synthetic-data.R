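#' Generator configuration
#'
#' Bundles a seed, a product-model table and consumption/body-weight settings
#' for the synthetic-data generators. The defaults reproduce the conditions of
#' the calibrating market survey: the product models of [survey_products()]
#' (200 occurrence samples split 102 bread-type / 98 sweets), three age
#' groups, and nominal body weights of 55 kg (adolescents) and 70 kg (adults
#' and elderly).
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param products Product-model tibble in the format of [survey_products()].
#' @param age_groups Character vector of age-group labels.
#' @param bw_by_group Named numeric vector of body weights (kg), one per age
#'   group.
#' @param consumption_targets Optional tibble with columns `product`,
#'   `age_group`, `q_median`, `q_p95` (g/day); when supplied,
#'   [generate_consumption()] emits exactly these quantities instead of
#'   drawing random ones.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             products = survey_products(),
                             age_groups = c("adolescents", "adults", "elderly"),
                             bw_by_group = survey_body_weights(),
                             consumption_targets = NULL) {
  check_number(seed, "seed")
  validate_product_models(products)
  if (length(age_groups) < 1L) abort_bad_arg("`age_groups` must be non-empty.")
  if (!all(age_groups %in% names(bw_by_group))) {
    abort_bad_arg("`bw_by_group` must name every age group.")
  }
  if (any(bw_by_group[age_groups] <= 0)) abort_bad_arg("body weights must be > 0.")
  structure(
    list(
      seed = as.integer(seed), products = products, age_groups = age_groups,
      bw_by_group = bw_by_group, consumption_targets = consumption_targets
    ),
    class = "generator_config"
  )
}

validate_product_models <- function(products) {
  needed <- c(
    "product", "category", "n_samples", "conc_mean", "conc_sd",
    "conc_min", "conc_max", "moisture_lo", "moisture_hi",
    "sugars_lo", "sugars_hi", "salt_lo", "salt_hi"
  )
  missing <- setdiff(needed, names(products))
  if (length(missing)) {
    abort_bad_arg(paste0("product models lack columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(products) == 0L) abort_bad_arg("product model list is empty.")
  if (any(products$n_samples < 1L)) abort_bad_arg("every product needs n_samples >= 1.")
  if (any(products$conc_sd <= 0)) abort_bad_arg("conc_sd must be > 0.")
  if (any(products$conc_min > products$conc_max)) {
    abort_bad_arg("conc_min must not exceed conc_max.")
  }
  ranges_ok <- products$moisture_lo <= products$moisture_hi &
    products$sugars_lo <= products$sugars_hi &
    products$salt_lo <= products$salt_hi
  if (!all(ranges_ok)) abort_bad_arg("recipe range bounds must be ordered low <= high.")
  invisible(products)
}

# Truncated-normal draws by rejection from the parent normal. The survey's
# truncation bounds sit within ~1.5 parent sd, so acceptance is high; mean/sd
# parametrise the PARENT distribution, not the truncated one.
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  if (lower == upper) return(rep(lower, n))
  accept_p <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (accept_p <= 0) abort_bad_arg("truncation bounds carry no probability mass.")
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / accept_p) + 10L
    draw <- stats::rnorm(m, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate synthetic occurrence samples
#'
#' Fabricates one row per analysed specimen: concentrations are drawn from a
#' normal distribution truncated to the product's observed min-max range, and
#' recipe attributes (moisture, sugars, salt) uniformly within the product's
#' recipe ranges. A single seeded RNG stream is consumed product by product in
#' declaration order, so output is reproducible for a fixed config and
#' unaffected by anything outside the call.
#'
#' @param config A [generator_config()].
#' @return A tibble of occurrence samples: `product`, `category`,
#'   `concentration` (ug/kg), `censored` (all `FALSE`; every survey sample
#'   was above the LOQ), `moisture`, `sugars`, `salt` (%).
#' @export
#' @examples
#' occ <- generate_occurrence(generator_config(seed = 42))
#' nrow(occ)             # 200
#' table(occ$category)   # 102 bread, 98 sweets
generate_occurrence <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  products <- config$products
  withr::with_seed(config$seed, {
    rows <- lapply(seq_len(nrow(products)), function(i) {
      p <- products[i, ]
      n <- p$n_samples
      tibble::tibble(
        product = p$product,
        category = p$category,
        concentration = rtruncnorm_reject(n, p$conc_mean, p$conc_sd, p$conc_min, p$conc_max),
        censored = FALSE,
        moisture = stats::runif(n, p$moisture_lo, p$moisture_hi),
        sugars = stats::runif(n, p$sugars_lo, p$sugars_hi),
        salt = stats::runif(n, p$salt_lo, p$salt_hi)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate synthetic consumption profiles
#'
#' Fabricates per (product, age group) daily-consumption quantities for
#' median consumers and consumers at the 95th percentile, plus body weight.
#' When `consumption_targets` are present in the config they are emitted
#' verbatim (the survey-calibrated route; see [survey_consumption()]).
#' Otherwise `q_median` is drawn uniformly on 20-120 g/day — a realistic span
#' for single bread-type items in a Mediterranean diet — and `q_p95` as
#' `q_median` times a uniform 1.5-3 factor, so the quantile ordering
#' `q_p95 >= q_median` holds by construction.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `product`, `age_group`, `q_median`, `q_p95`
#'   (g/day), `bw` (kg).
#' @export
generate_consumption <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  targets <- config$consumption_targets
  if (!is.null(targets)) {
    needed <- c("product", "age_group", "q_median", "q_p95")
    if (!all(needed %in% names(targets))) {
      abort_bad_arg("consumption_targets must have product, age_group, q_median, q_p95.")
    }
    if (any(targets$q_median < 0)) abort_bad_arg("consumption must be non-negative.")
    if (any(targets$q_p95 < targets$q_median)) {
      abort_bad_arg("q_p95 must be >= q_median in consumption targets.")
    }
    if (!all(targets$age_group %in% config$age_groups)) {
      abort_bad_arg("consumption_targets reference an unknown age group.")
    }
    out <- tibble::as_tibble(targets[, needed])
    out$bw <- unname(config$bw_by_group[out$age_group])
    return(out)
  }
  grid <- tidyr::expand_grid(
    product = config$products$product,
    age_group = config$age_groups
  )
  withr::with_seed(config$seed, {
    grid$q_median <- stats::runif(nrow(grid), 20, 120)
    grid$q_p95 <- grid$q_median * stats::runif(nrow(grid), 1.5, 3)
  })
  grid$bw <- unname(config$bw_by_group[grid$age_group])
  grid
}
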