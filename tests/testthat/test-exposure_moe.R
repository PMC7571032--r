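test_that("daily intake follows C x Q / BW with the implicit unit identity", {
  expect_equal(daily_intake(100, 150, 60), 250)
  expect_equal(daily_intake(0, 150, 60), 0)
  expect_error(daily_intake(100, 150, 0), "> 0")
  expect_error(daily_intake(-1, 150, 60), ">= 0")
  # homogeneity in concentration and inverse homogeneity in body weight
  set.seed(4)
  for (i in 1:10) {
    cc <- stats::runif(1, 10, 500); q <- stats::runif(1, 10, 300)
    bw <- stats::runif(1, 40, 90); k <- stats::runif(1, 0.5, 3)
    expect_equal(daily_intake(k * cc, q, bw), k * daily_intake(cc, q, bw))
    expect_equal(daily_intake(cc, q, k * bw), daily_intake(cc, q, bw) / k)
  }
})

test_that("the scenario grid crosses consumers, scenarios and age groups completely", {
  s <- tibble::tibble(product = "Bread", median = 55, p95 = 82)
  p <- tidyr::expand_grid(
    product = "Bread",
    age_group = c("adolescents", "adults", "elderly")
  )
  p$q_median <- c(84, 59, 71) * c(55, 70, 70) / 55
  p$q_p95 <- p$q_median * 2
  p$bw <- c(55, 70, 70)
  g <- scenario_grid(s, p)
  expect_equal(nrow(g), 12L)  # 1 product x 3 groups x 2 consumers x 2 scenarios
  expect_equal(nrow(unique(g[, c("age_group", "consumer_percentile", "scenario")])), 12L)

  # collapsed quantiles collapse all four cells
  s2 <- tibble::tibble(product = "Bread", median = 60, p95 = 60)
  p2 <- tibble::tibble(product = "Bread", age_group = "adults",
                       q_median = 100, q_p95 = 100, bw = 70)
  g2 <- scenario_grid(s2, p2)
  expect_equal(length(unique(g2$di)), 1L)

  expect_warning(
    scenario_grid(s, dplyr::bind_rows(p, tibble::tibble(
      product = "Focaccia", age_group = "adults", q_median = 10, q_p95 = 20, bw = 70
    ))),
    "Focaccia"
  )
})

test_that("worst-scenario intake dominates best-scenario and p95 consumers dominate median consumers", {
  cfg <- survey_config(seed = 3)
  res <- scenario_grid(
    tibble::tibble(product = cfg$products$product,
                   median = cfg$products$conc_median, p95 = cfg$products$conc_p95),
    survey_consumption()
  )
  wide <- tidyr::pivot_wider(res[, 1:5], names_from = "scenario", values_from = "di")
  expect_true(all(wide$WS >= wide$BS))
  by_cons <- tidyr::pivot_wider(res[, c(1:4, 5)],
                                names_from = "consumer_percentile", values_from = "di")
  expect_true(all(by_cons$p95 >= by_cons$median))
})

test_that("margin of exposure applies the mg-to-ng conversion and decreases in intake", {
  expect_equal(round_half_away(margin_of_exposure(351, 0.17)), 484)
  expect_equal(round_half_away(margin_of_exposure(351, 0.43)), 1225)
  expect_equal(margin_of_exposure(0.17e6, 0.17), 1)
  expect_true(is.na(margin_of_exposure(0, 0.17)))
  di <- sort(stats::runif(20, 10, 500))
  moe <- margin_of_exposure(di, 0.17)
  expect_true(all(diff(moe) < 0))
  # fixed intake: endpoint MOEs stand in the BMDL10 ratio
  expect_equal(margin_of_exposure(123.4, 0.43) / margin_of_exposure(123.4, 0.17),
               0.43 / 0.17, tolerance = 1e-12)
})

test_that("concern classification honours the endpoint boundary conventions", {
  expect_equal(classify_concern(125, 125, inclusive = TRUE), "low_concern")
  expect_equal(classify_concern(124.99, 125, inclusive = TRUE), "concern")
  expect_equal(classify_concern(10000, 10000, inclusive = FALSE), "concern")
  expect_equal(classify_concern(10000.01, 10000, inclusive = FALSE), "low_concern")
  expect_equal(classify_concern(NA_real_, 125, inclusive = TRUE), "not_computable")
  expect_equal(classify_concern(484, 10000, inclusive = FALSE), "concern")
})

test_that("the published intake grid classifies as carcinogenic concern and neurotoxic low concern throughout", {
  rep <- moe_report(survey_intake_grid())
  carc <- rep[rep$endpoint == "carcinogenic", ]
  neur <- rep[rep$endpoint == "neurotoxic", ]
  expect_true(all(carc$moe < 10000))
  expect_true(all(carc$concern == "concern"))
  expect_true(all(neur$moe >= 125))
  expect_true(all(neur$concern == "low_concern"))
})
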