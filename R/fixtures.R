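extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "choicefrontier")
  if (!nzchar(path)) {
    stop_integrity(paste0("packaged fixture missing: ", file))
  }
  path
}

check_fixture <- function(x, file, columns, rows = NULL) {
  missing_cols <- setdiff(columns, names(x))
  if (length(missing_cols) > 0 || (!is.null(rows) && nrow(x) != rows)) {
    stop_integrity(paste0(
      "packaged fixture '", file, "' failed its integrity check"
    ))
  }
  x
}

attrs_to_levels <- function(attributes, coeffs) {
  purrr::map(strsplit(attributes, ";", fixed = TRUE), function(a) {
    i <- match(a, coeffs$attribute)
    tibble::tibble(attribute = coeffs$attribute[i], level = coeffs$level[i])
  })
}

#' Packaged DCE coefficient table
#'
#' Conditional-logit coefficients and standard errors for the six service
#' attributes that facilitated uptake in the adolescent HIV/contraceptive
#' services DCE (805 school-going respondents, Gauteng): Wi-Fi, subsidized
#' food, afternoon hours and youth-only space (modifiable), plus friendly
#' staff and confidentiality (challenging to modify).
#'
#' @return A coefficient tibble (see [coefficient_set()]).
#' @export
load_dce_coefficients <- function() {
  read_coefficients(extdata_path("dce_coefficients.csv"))
}

#' Packaged uptake projection table
#'
#' The published per-scenario uptake projections: percentage-point change
#' from the 30.60% baseline share, standard error, confidence interval, and
#' total projected share, for single attributes and printed combinations.
#' The printed deltas are authoritative inputs here: they are *not*
#' reproducible from the rounded published coefficients via the logit
#' translation, so downstream projections key on this table rather than on
#' [delta_uptake()] output.
#'
#' @param modifiable_only Keep only the 15 combinations of the four
#'   modifiable attributes (default `FALSE`).
#' @return A tibble with `scenario`, `levels` (list-column for cost gating),
#'   `coefficient`, `delta_pp`, `se`, `p_value`, `ci_low_pp`, `ci_high_pp`,
#'   `total_share_pct`.
#' @export
load_uptake_table <- function(modifiable_only = FALSE) {
  file <- "uptake_table.csv"
  x <- readr::read_csv(
    extdata_path(file),
    col_types = readr::cols(
      scenario = readr::col_character(),
      attributes = readr::col_character(),
      .default = readr::col_double()
    )
  )
  check_fixture(
    x, file,
    c("scenario", "attributes", "coefficient", "delta_pp", "se", "p_value",
      "ci_low_pp", "ci_high_pp", "total_share_pct"),
    rows = 20
  )
  coeffs <- load_dce_coefficients()
  x$levels <- attrs_to_levels(x$attributes, coeffs)
  if (modifiable_only) {
    modif <- coeffs$attribute[coeffs$modifiable]
    keep <- purrr::map_lgl(x$levels, function(lv) all(lv$attribute %in% modif))
    x <- x[keep, ]
    if (nrow(x) != 15) {
      stop_integrity("expected 15 modifiable scenario rows in the uptake table")
    }
  }
  dplyr::relocate(x, "scenario", "levels")
}

#' Packaged clinic profiles
#'
#' Baseline adolescent client volumes for the two costing clinics: 1531
#' adolescents per month at Clinic A and 1808 at Clinic B, both at a 30.60%
#' baseline uptake share.  The total monthly headcount column is a synthetic
#' round figure (the source tables do not print it) used only by
#' headcount-shared cost allocations.
#'
#' @return A tibble with one row per clinic (see [clinic_profile()]).
#' @export
load_clinic_profiles <- function() {
  x <- read_clinic_profiles(extdata_path("clinic_profiles.csv"))
  check_fixture(x, "clinic_profiles.csv", "clinic", rows = 2)
}

#' Packaged clinic strategy tables
#'
#' The published cost-effectiveness tables for the 15 modifiable intervention
#' combinations at each clinic: additional adolescents per month, total
#' adolescents, percent change, cost per additional adolescent, total monthly
#' cost (USD), and the label/ICER printed in the source.  `printed_label` and
#' `printed_icer` reproduce the source as printed; run [build_frontier()] for
#' this package's own classification.
#'
#' @param clinic `"A"` or `"B"`.
#' @return A tibble with 15 strategies, including `name`, `levels`
#'   (list-column), `effect` (= `additional`), `effect_exact`
#'   (baseline x percent change) and `cost` (= `total_cost_usd`) columns
#'   ready for [build_frontier()].
#' @export
load_strategy_table <- function(clinic = c("A", "B")) {
  clinic <- match.arg(clinic)
  file <- paste0("clinic_", tolower(clinic), "_strategies.csv")
  x <- readr::read_csv(
    extdata_path(file),
    col_types = readr::cols(
      name = readr::col_character(),
      attributes = readr::col_character(),
      printed_label = readr::col_character(),
      .default = readr::col_double()
    )
  )
  check_fixture(
    x, file,
    c("name", "attributes", "additional", "total", "pct_change",
      "cost_per_additional_usd", "total_cost_usd", "printed_icer",
      "printed_label"),
    rows = 15
  )
  coeffs <- load_dce_coefficients()
  profile <- load_clinic_profiles()
  baseline <- profile$baseline_adolescents_per_month[profile$clinic == clinic]
  x$levels <- attrs_to_levels(x$attributes, coeffs)
  x$effect <- x$additional
  x$effect_exact <- baseline * x$pct_change / 100
  x$cost <- x$total_cost_usd
  dplyr::relocate(x, "name", "levels")
}

#' Packaged clinic cost workbook (synthetic reconstruction)
#'
#' Monthly cost lines by category with allocation rules, reconstructed to the
#' scale of the published Clinic B per-category cost summary (amounts
#' converted to ZAR at 14/USD; per-visit unit costs from the printed
#' per-visit column; subsidized food at ZAR 10 per adolescent).  The original
#' clinic workbooks are not published line-by-line, so this fixture is a
#' synthetic stand-in suitable for exercising the allocation formulas, not
#' for regenerating the published totals.
#'
#' @return A tibble of cost lines (see [cost_lines()]).
#' @export
load_cost_workbook <- function() {
  x <- read_cost_workbook(extdata_path("cost_workbook_clinic_b_synthetic.csv"))
  check_fixture(x, "cost_workbook_clinic_b_synthetic.csv", "category", rows = 6)
}

#' Packaged sensitivity tables (as printed)
#'
#' The published lower-confidence-bound sensitivity tables for each clinic,
#' shipped verbatim for reference.  Several of their cells are internally
#' inconsistent in the source (misaligned cost-per-patient columns,
#' counts floored at 1 for negative projected uptake), so they are reference
#' material rather than a validation target.
#'
#' @param clinic `"A"` or `"B"`.
#' @return A tibble of 15 strategies as printed.
#' @export
load_sensitivity_table <- function(clinic = c("A", "B")) {
  clinic <- match.arg(clinic)
  file <- paste0("sensitivity_clinic_", tolower(clinic), ".csv")
  x <- readr::read_csv(
    extdata_path(file),
    col_types = readr::cols(
      name = readr::col_character(),
      printed_label = readr::col_character(),
      .default = readr::col_double()
    )
  )
  check_fixture(x, file, c("name", "additional", "total_cost_usd"), rows = 15)
}
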