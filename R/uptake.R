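#' Clinic profile
#'
#' Describes the clinic the uptake projection is scaled to: how many
#' adolescents currently use HIV/contraceptive services per month, what share
#' of the adolescent catchment that represents, and the clinic's total monthly
#' headcount across all patients (used by headcount-shared cost allocations).
#'
#' @param clinic Clinic label.
#' @param baseline_adolescents_per_month Adolescent clients per month at
#'   baseline (>= 0).
#' @param baseline_uptake_share_pct Baseline uptake share in percent, strictly
#'   inside (0, 100).
#' @param total_monthly_headcount Total patients of all ages per month
#'   (optional, `NA` if unknown).
#' @return A one-row tibble.
#' @examples
#' clinic_profile("A", 1531, 30.60, 5000)
#' @export
clinic_profile <- function(clinic, baseline_adolescents_per_month,
                           baseline_uptake_share_pct,
                           total_monthly_headcount = NA_real_) {
  if (!is.numeric(baseline_adolescents_per_month) ||
      baseline_adolescents_per_month < 0) {
    stop_input("`baseline_adolescents_per_month` must be >= 0")
  }
  if (!is.numeric(baseline_uptake_share_pct) ||
      baseline_uptake_share_pct <= 0 || baseline_uptake_share_pct >= 100) {
    stop_input("`baseline_uptake_share_pct` must be strictly inside (0, 100)")
  }
  tibble::tibble(
    clinic = as.character(clinic),
    baseline_adolescents_per_month = as.numeric(baseline_adolescents_per_month),
    baseline_uptake_share_pct = as.numeric(baseline_uptake_share_pct),
    total_monthly_headcount = as.numeric(total_monthly_headcount)
  )
}

#' Read clinic profiles from a CSV file
#'
#' @param path CSV with columns `clinic`, `baseline_adolescents_per_month`,
#'   `baseline_uptake_share_pct`, `total_monthly_headcount`.
#' @return A tibble with one row per clinic.
#' @export
read_clinic_profiles <- function(path) {
  if (!file.exists(path)) {
    stop_input(paste0("clinic profile file not found: ", path))
  }
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      clinic = readr::col_character(),
      .default = readr::col_double()
    )
  )
  purrr::pmap_dfr(x, clinic_profile)
}

#' Additional adolescents implied by an uptake change
#'
#' The percentage-point uptake change is applied multiplicatively to the
#' clinic's baseline adolescent count:
#' `additional = round_half_out(N_base * delta_pp / 100)`, clamped below at
#' `floor`.  The default floor of 0 treats a negative projected change as "no
#' additional uptake"; `floor = 1` reproduces published sensitivity tables
#' that report one additional adolescent for negative changes.
#'
#' @param baseline_n Baseline adolescent count (scalar or vector).
#' @param delta_pp Uptake change in percentage points (vectorised).
#' @param floor Lower clamp for the count (default 0).
#' @return Numeric vector of whole-person counts.
#' @examples
#' additional_adolescents(1531, c(2.71, 9.0, 23.0))  # 41 138 352
#' additional_adolescents(1808, 23.0)                # 416
#' @export
additional_adolescents <- function(baseline_n, delta_pp, floor = 0) {
  if (any(!is.finite(delta_pp))) {
    stop_input("`delta_pp` must be finite")
  }
  pmax(round_half_out(baseline_n * delta_pp / 100), floor)
}

#' Project per-scenario uptake counts for a clinic
#'
#' @param deltas A tibble with columns `scenario` and `delta_pp` (and
#'   optionally `levels`, carried through for cost gating).
#' @param profile A one-row clinic profile ([clinic_profile()]).
#' @param floor Lower clamp for additional counts (default 0; see
#'   [additional_adolescents()]).
#' @return `deltas` plus `clinic`, `additional_exact` (unrounded, clamped),
#'   `additional_per_month` (whole persons) and `total_per_month`
#'   (baseline + additional).
#' @examples
#' profile <- clinic_profile("A", 1531, 30.60)
#' project_uptake(tibble::tibble(scenario = "x", delta_pp = 9), profile)
#' @export
project_uptake <- function(deltas, profile, floor = 0) {
  if (!is.data.frame(profile) || nrow(profile) != 1) {
    stop_input("`profile` must be a one-row clinic profile")
  }
  if (!all(c("scenario", "delta_pp") %in% names(deltas))) {
    stop_input("`deltas` must contain `scenario` and `delta_pp` columns")
  }
  n0 <- profile$baseline_adolescents_per_month
  out <- tibble::as_tibble(deltas)
  out$clinic <- profile$clinic
  out$additional_exact <- pmax(n0 * out$delta_pp / 100, floor)
  out$additional_per_month <- additional_adolescents(n0, out$delta_pp, floor)
  out$total_per_month <- n0 + out$additional_per_month
  out
}

#' Annualise a monthly uptake projection
#'
#' @param projection Output of [project_uptake()].
#' @return `projection` with an `additional_per_year` column
#'   (`additional_per_month * 12`).
#' @export
annualize_uptake <- function(projection) {
  if (!"additional_per_month" %in% names(projection)) {
    stop_input("`projection` must contain `additional_per_month`")
  }
  dplyr::mutate(
    tibble::as_tibble(projection),
    additional_per_year = .data$additional_per_month * 12
  )
}
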