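coeffs <- load_dce_coefficients()
profile <- load_clinic_profiles()[2, ]  # Clinic B
workbook <- load_cost_workbook()

project_fixture <- function(scenarios = c("Wi-Fi", "Wi-Fi and food",
                                          "Wi-Fi, food, afternoon and youth")) {
  deltas <- load_uptake_table(modifiable_only = TRUE)
  project_uptake(deltas[match(scenarios, deltas$scenario), ], profile)
}

test_that("currency conversion divides by the exchange rate", {
  expect_equal(convert_currency(c(14, 0, 140)), c(1, 0, 10))
  expect_equal(convert_currency(100, rate = 20), 5)
  expect_equal(convert_currency(convert_currency(123.45) * 14), 123.45 / 14 * 1,
               tolerance = 1e-9)
  expect_error(convert_currency(10, rate = 0),
               class = "choicefrontier_config_error")
  expect_error(convert_currency(10, rate = -2),
               class = "choicefrontier_config_error")
})

test_that("allocation rules reproduce hand-computed amounts", {
  # per-visit supplies at 0.08 USD/visit for 138 additional adolescents
  lines <- cost_lines(tibble::tibble(
    category = "supplies", monthly_amount_zar = 6501.04,
    allocation = "per_visit", params = "unit_cost_zar=1.12"
  ))
  proj <- tibble::tibble(
    scenario = "wifi+youth",
    levels = list(tibble::tibble(attribute = c("wifi", "youth_only"),
                                 level = c("Wi-Fi", "Youth waiting area"))),
    additional_exact = 138, total_per_month = 1669
  )
  out <- scenario_costs(proj, lines, profile)
  expect_equal(out$total_cost_usd, 0.08 * 138, tolerance = 1e-9)  # 11.04

  # food billed for every adolescent but charged to the additional ones
  lines <- cost_lines(tibble::tibble(
    category = "food", monthly_amount_zar = 0,
    allocation = "all_adolescents_billed_to_additional",
    params = "amount_per_adolescent_zar=10;requires=food"
  ))
  proj$levels <- list(tibble::tibble(attribute = "food", level = "Food"))
  proj$additional_exact <- 352.13
  proj$total_per_month <- 1883
  out <- scenario_costs(proj, lines, profile)
  expect_equal(out$total_cost_usd, 10 * 1883 / 14, tolerance = 1e-9)  # ~1345

  # assets are never incremental
  lines <- cost_lines(tibble::tibble(
    category = "assets", monthly_amount_zar = 18009.04,
    allocation = "none_incremental", params = NA_character_
  ))
  expect_equal(scenario_costs(proj, lines, profile)$total_cost_usd, 0)

  # headcount-shared: amount * additional / (headcount + additional)
  lines <- cost_lines(tibble::tibble(
    category = "overheads", monthly_amount_zar = 1400,
    allocation = "shared_all_patients", params = NA_character_
  ))
  proj$additional_exact <- 100
  out <- scenario_costs(proj, lines, profile)
  expect_equal(out$total_cost_usd, 1400 / 14 * 100 / (6000 + 100),
               tolerance = 1e-12)
})

test_that("attribute-gated lines contribute nothing to unrelated scenarios", {
  proj <- project_fixture()
  out <- scenario_costs(proj, workbook, profile)
  wifi_only <- out[out$scenario == "Wi-Fi", ]
  expect_equal(wifi_only$cost_food_usd, 0)
  expect_equal(wifi_only$cost_staff_usd, 0)
  expect_equal(wifi_only$cost_overheads_usd, 0)
  expect_gt(wifi_only$cost_wifi_usd, 0)
  wf <- out[out$scenario == "Wi-Fi and food", ]
  expect_gt(wf$cost_food_usd, 0)
  expect_equal(wf$cost_staff_usd, 0)
  all4 <- out[out$scenario == "Wi-Fi, food, afternoon and youth", ]
  expect_gt(all4$cost_staff_usd, 0)
  expect_gt(all4$cost_overheads_usd, 0)
})

test_that("category columns sum to the total and per-additional uses exact counts", {
  proj <- project_fixture()
  out <- scenario_costs(proj, workbook, profile)
  cat_cols <- setdiff(
    grep("^cost_.*_usd$", names(out), value = TRUE),
    "cost_per_additional_usd"
  )
  expect_equal(rowSums(out[cat_cols]), out$total_cost_usd, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(
    out$cost_per_additional_usd,
    out$total_cost_usd / proj$additional_exact
  )
  # zero additional adolescents with positive cost -> undefined, not infinite
  proj0 <- proj[3, ]
  proj0$additional_exact <- 0
  proj0$additional_per_month <- 0
  out0 <- scenario_costs(proj0, workbook, profile)
  expect_gt(out0$total_cost_usd, 0)  # room + staff still charged
  expect_true(is.na(out0$cost_per_additional_usd))
})

test_that("costs are homogeneous of degree one in the money amounts", {
  proj <- project_fixture()
  base <- scenario_costs(proj, workbook, profile)
  doubled <- workbook
  doubled$monthly_amount_zar <- doubled$monthly_amount_zar * 2
  doubled$params <- lapply(doubled$params, function(p) {
    for (nm in intersect(names(p), c("unit_cost_zar", "amount_per_adolescent_zar"))) {
      p[[nm]] <- p[[nm]] * 2
    }
    p
  })
  out2 <- scenario_costs(proj, doubled, profile)
  expect_equal(out2$total_cost_usd, 2 * base$total_cost_usd, tolerance = 1e-9)
})

test_that("per-visit components scale linearly with additional adolescents", {
  lines <- cost_lines(tibble::tibble(
    category = "supplies", monthly_amount_zar = 6501.04,
    allocation = "per_visit", params = "unit_cost_zar=1.12"
  ))
  proj <- tibble::tibble(
    scenario = c("base", "triple"),
    levels = list(tibble::tibble(attribute = "wifi", level = "Wi-Fi"),
                  tibble::tibble(attribute = "wifi", level = "Wi-Fi")),
    additional_exact = c(50, 150), total_per_month = c(1858, 1958)
  )
  out <- scenario_costs(proj, lines, profile)
  expect_equal(out$total_cost_usd[2], 3 * out$total_cost_usd[1])
})

test_that("configuration errors name the offending piece", {
  lines <- cost_lines(tibble::tibble(
    category = "supplies", monthly_amount_zar = 100,
    allocation = "per_visit", params = NA_character_
  ))
  proj <- project_fixture("Wi-Fi")
  expect_error(scenario_costs(proj, lines, profile),
               regexp = "unit_cost_zar",
               class = "choicefrontier_config_error")
  expect_error(
    cost_lines(tibble::tibble(
      category = "x", monthly_amount_zar = 1,
      allocation = "by_magic", params = NA_character_
    )),
    regexp = "by_magic", class = "choicefrontier_config_error"
  )
  no_headcount <- clinic_profile("C", 1000, 30)
  shared <- cost_lines(tibble::tibble(
    category = "overheads", monthly_amount_zar = 100,
    allocation = "shared_all_patients", params = NA_character_
  ))
  expect_error(
    scenario_costs(project_uptake(
      tibble::tibble(scenario = "s", delta_pp = 5,
                     levels = list(tibble::tibble(attribute = "wifi",
                                                  level = "Wi-Fi"))),
      no_headcount
    ), shared, no_headcount),
    class = "choicefrontier_config_error"
  )
  expect_error(cost_config(exchange_rate = -1),
               class = "choicefrontier_config_error")
})
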