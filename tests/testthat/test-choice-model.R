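coeffs <- load_dce_coefficients()

test_that("choice probabilities are a proper, translation-invariant softmax", {
  expect_equal(choice_probability(c(0, 0)), c(0.5, 0.5))
  expect_equal(choice_probability(c(1.3, 1.3, 1.3)), rep(1 / 3, 3))
  expect_equal(
    choice_probability(c(qlogis(0.306), 0)),
    c(0.306, 0.694),
    tolerance = 1e-12
  )
  set.seed(42)
  for (i in 1:20) {
    u <- stats::rnorm(sample(2:6, 1), sd = 3)
    p <- choice_probability(u)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
    expect_equal(choice_probability(u + 17.3), p, tolerance = 1e-12)
  }
  expect_error(choice_probability(0.5), class = "choicefrontier_input_error")
  expect_error(choice_probability(c(1, Inf)), class = "choicefrontier_input_error")
})

test_that("scenario utility is the sum of switched-level coefficients", {
  sc <- make_scenarios(
    coeffs,
    baseline = character(),
    friendly = "Friendly",
    extras = c("Wi-Fi", "Food")
  )
  u <- scenario_utility(sc, coeffs)
  expect_equal(u$utility, c(0, 0.19, 0.05))
  expect_equal(u$se_utility, c(0, 0.03, sqrt(0.04^2 + 0.03^2)))
  expect_error(
    make_scenarios(coeffs, c("Wi-Fi", "Sauna")),
    class = "choicefrontier_input_error"
  )
  bad <- sc
  bad$levels[[2]] <- tibble::tibble(attribute = "friendly", level = "Rude")
  expect_error(
    scenario_utility(bad, coeffs),
    regexp = "friendly / Rude",
    class = "choicefrontier_input_error"
  )
})

test_that("a supplied covariance matrix replaces the independence assumption", {
  sc <- make_scenarios(coeffs, c("Wi-Fi", "Food"))
  V <- diag(coeffs$std_error^2)
  expect_equal(
    scenario_utility(sc, coeffs, vcov = V)$se_utility,
    scenario_utility(sc, coeffs)$se_utility
  )
  # perfect positive correlation between the two switched levels
  i <- match(c("wifi", "food"), coeffs$attribute)
  V[i[1], i[2]] <- V[i[2], i[1]] <- 0.04 * 0.03
  expect_equal(
    scenario_utility(sc, coeffs, vcov = V)$se_utility,
    0.04 + 0.03
  )
})

test_that("uptake change matches the closed-form logit translation", {
  one <- function(beta, p0) {
    co <- coefficient_set(tibble::tibble(
      attribute = "a", level = "A", coefficient = beta,
      std_error = 0.03, modifiable = TRUE
    ))
    delta_uptake(make_scenarios(co, "A"), co, p0)
  }
  expect_equal(one(0.19, 0.5)$delta_pp, oracle_delta_pp(0.5, 0.19),
               tolerance = 1e-10)
  expect_equal(one(0.19, 0.5)$delta_pp, 4.7357618143, tolerance = 1e-8)
  expect_equal(one(0.19, 0.306)$delta_pp, 4.1762982075, tolerance = 1e-8)
  z <- one(0, 0.306)
  expect_equal(z$delta_pp, 0)
  expect_equal(z$ci_low_pp, -z$ci_high_pp)
  expect_error(one(0.1, 1), class = "choicefrontier_input_error")
  expect_error(one(0.1, 0), class = "choicefrontier_input_error")
})

test_that("confidence interval is symmetric with the 1.959964 normal quantile", {
  d <- delta_uptake(enumerate_scenarios(coeffs), coeffs, 0.306)
  expect_true(all(d$ci_low_pp <= d$delta_pp & d$delta_pp <= d$ci_high_pp))
  expect_equal(d$ci_high_pp - d$delta_pp, 1.959964 * d$se_pp, tolerance = 1e-6)
  expect_equal(d$delta_pp - d$ci_low_pp, 1.959964 * d$se_pp, tolerance = 1e-6)
})

test_that("uptake change is monotone, odd under logistic symmetry, superadditive", {
  one <- function(beta, p0) {
    co <- coefficient_set(tibble::tibble(
      attribute = "a", level = "A", coefficient = beta,
      std_error = 0, modifiable = TRUE
    ))
    delta_uptake(make_scenarios(co, "A"), co, p0)$delta_pp
  }
  betas <- seq(-2, 2, by = 0.25)
  for (p0 in c(0.1, 0.306, 0.5, 0.8)) {
    expect_true(all(diff(vapply(betas, one, 0, p0 = p0)) > 0))
  }
  for (b in c(0.1, 0.5, 1.5)) {
    for (p0 in c(0.2, 0.306, 0.7)) {
      expect_equal(one(-b, p0), -one(b, 1 - p0), tolerance = 1e-10)
    }
  }
  # below the logistic midpoint, combining positive shifts beats adding them
  for (p0 in c(0.1, 0.2, 0.3)) {
    for (b1 in c(0.1, 0.3, 0.5)) {
      for (b2 in c(0.1, 0.3)) {
        if (plogis(qlogis(p0) + b1 + b2) <= 0.5) {
          expect_gte(one(b1 + b2, p0), one(b1, p0) + one(b2, p0))
        }
      }
    }
  }
})

test_that("scenario enumeration covers every one-level-per-attribute bundle", {
  expect_equal(nrow(enumerate_scenarios(coeffs)), 15)
  expect_equal(nrow(enumerate_scenarios(coeffs, only_modifiable = FALSE)), 63)
  one <- coefficient_set(coeffs[2, ])
  expect_equal(nrow(enumerate_scenarios(one)), 1)
  # brute-force subset count for k <= 6 single-level attributes
  for (k in 2:6) {
    co <- coefficient_set(tibble::tibble(
      attribute = letters[1:k], level = LETTERS[1:k],
      coefficient = 0.01 * (1:k), std_error = 0.01, modifiable = TRUE
    ))
    expect_equal(nrow(enumerate_scenarios(co)), 2^k - 1)
  }
  # two levels of one attribute are mutually exclusive
  co <- coefficient_set(tibble::tibble(
    attribute = c("a", "a", "b"), level = c("A1", "A2", "B"),
    coefficient = c(0.1, 0.2, 0.3), std_error = 0.01, modifiable = TRUE
  ))
  expect_equal(nrow(enumerate_scenarios(co)), 5)
  # deterministic order: by bundle size then name
  sc <- enumerate_scenarios(coeffs)
  expect_equal(sc$n_levels, sort(sc$n_levels))
  expect_error(
    enumerate_scenarios(dplyr::mutate(coeffs, modifiable = FALSE)),
    class = "choicefrontier_input_error"
  )
})

test_that("total uptake share adds printed deltas to the baseline share", {
  out <- tabulate_uptake(
    tibble::tibble(delta_pp = c(18.54, 55, 0)), baseline_share = 30.60
  )
  expect_equal(out$total_share_pct, c(49.14, 85.60, 30.60))
  expect_error(tabulate_uptake(tibble::tibble(x = 1), 30.6),
               class = "choicefrontier_input_error")
  expect_error(tabulate_uptake(tibble::tibble(delta_pp = 1), 100),
               class = "choicefrontier_input_error")
})
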