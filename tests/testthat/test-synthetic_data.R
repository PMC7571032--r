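test_that("default survey fixture emits 200 samples split 102 bread / 98 sweets", {
  occ <- generate_occurrence(generator_config(seed = 11))
  expect_equal(nrow(occ), 200L)
  expect_equal(sum(occ$category == "bread"), 102L)
  expect_equal(sum(occ$category == "sweets"), 98L)
  expect_equal(
    as.vector(table(occ$product)[survey_products()$product]),
    survey_products()$n_samples
  )
})

test_that("generated concentrations and recipe attributes respect their configured ranges", {
  pm <- survey_products()
  occ <- generate_occurrence(generator_config(seed = 3))
  joined <- merge(occ, pm, by = "product")
  expect_true(all(joined$concentration >= joined$conc_min))
  expect_true(all(joined$concentration <= joined$conc_max))
  expect_true(all(joined$moisture >= joined$moisture_lo & joined$moisture <= joined$moisture_hi))
  expect_true(all(joined$sugars >= joined$sugars_lo & joined$sugars <= joined$sugars_hi))
  expect_true(all(joined$salt >= joined$salt_lo & joined$salt <= joined$salt_hi))
})

test_that("degenerate truncation (min = max, n = 1) yields a single exact value", {
  pm <- survey_products()[1, ]
  pm$n_samples <- 1L
  pm$conc_min <- 100
  pm$conc_max <- 100
  occ <- generate_occurrence(generator_config(seed = 5, products = pm))
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$concentration, 100)
})

test_that("generator moments match the quadrature oracle for the truncated normal", {
  pm <- survey_products()[1, ]  # bread: mean 57, sd 18, bounds 31-90
  pm$n_samples <- 5000L
  occ <- generate_occurrence(generator_config(seed = 202, products = pm))
  oracle <- truncnorm_moments(57, 18, 31, 90)
  expect_lt(abs(mean(occ$concentration) - oracle$mean), 1)
  expect_lt(abs(mean(occ$concentration) / oracle$mean - 1), 0.02)
  expect_lt(abs(stats::sd(occ$concentration) / oracle$sd - 1), 0.02)
})

test_that("generators are deterministic under a fixed seed and insensitive to outside RNG state", {
  cfg <- generator_config(seed = 99)
  a <- generate_occurrence(cfg)
  set.seed(1234)  # perturb global state between calls
  b <- generate_occurrence(cfg)
  expect_identical(a, b)
  expect_identical(generate_consumption(cfg), generate_consumption(cfg))
  expect_false(identical(a, generate_occurrence(generator_config(seed = 100))))
})

test_that("generated consumption honours quantile ordering and explicit targets", {
  cons <- generate_consumption(generator_config(seed = 8))
  expect_true(all(cons$q_p95 >= cons$q_median))
  expect_true(all(cons$q_median >= 0))
  expect_true(all(cons$bw > 0))

  targets <- tibble::tibble(
    product = "Bread", age_group = c("adolescents", "adults"),
    q_median = c(84, 59), q_p95 = c(236, 189)
  )
  cfg <- generator_config(seed = 8, consumption_targets = targets)
  out <- generate_consumption(cfg)
  expect_equal(out$q_median, targets$q_median)
  expect_equal(out$q_p95, targets$q_p95)
  expect_equal(out$bw, c(55, 70))
})

test_that("invalid generator configs are rejected", {
  pm <- survey_products()
  expect_error(generator_config(products = pm[0, ]), "empty")
  bad_sd <- pm; bad_sd$conc_sd[1] <- 0
  expect_error(generator_config(products = bad_sd), "conc_sd")
  bad_rng <- pm; bad_rng$conc_min[1] <- bad_rng$conc_max[1] + 1
  expect_error(generator_config(products = bad_rng), "conc_min")
  bad_q <- tibble::tibble(product = "Bread", age_group = "adults",
                          q_median = 100, q_p95 = 50)
  expect_error(
    generate_consumption(generator_config(consumption_targets = bad_q)),
    "q_p95"
  )
})
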