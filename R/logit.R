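#' Conditional-logit choice probabilities
#'
#' Softmax of a vector of alternative utilities: the probability of choosing
#' alternative *i* among *J* alternatives is `exp(u_i) / sum_j exp(u_j)`.
#' Computed with max-subtraction so it is numerically stable and exactly
#' invariant to adding a constant to all utilities.
#'
#' @param utilities Numeric vector of at least two finite utilities.
#' @return A probability vector of the same length, summing to 1.
#' @examples
#' choice_probability(c(0, 0))
#' choice_probability(c(qlogis(0.306), 0))  # c(0.306, 0.694)
#' @export
choice_probability <- function(utilities) {
  if (!is.numeric(utilities) || length(utilities) < 2) {
    stop_input("need at least 2 alternatives to form choice probabilities")
  }
  if (any(!is.finite(utilities))) {
    stop_input("utilities must all be finite")
  }
  e <- exp(utilities - max(utilities))
  e / sum(e)
}

#' Scenario utilities under reference coding
#'
#' The linear utility index of a scenario is the sum of the coefficients of
#' its switched-on levels; baseline (reference) levels contribute zero.  The
#' standard error of the combined index is, by default, the square root of the
#' summed squared level standard errors -- i.e. coefficients are treated as
#' independent, since published DCE tables rarely report the covariance
#' matrix.  Supply `vcov` to use a full covariance matrix instead (rows and
#' columns in the order of `coeffs`).
#'
#' @param scenarios A scenario tibble ([enumerate_scenarios()]).
#' @param coeffs A coefficient tibble ([coefficient_set()]).
#' @param vcov Optional coefficient covariance matrix, `nrow(coeffs)` square.
#' @return `scenarios` with numeric columns `utility` and `se_utility`.
#' @export
scenario_utility <- function(scenarios, coeffs, vcov = NULL) {
  coeffs <- coefficient_set(coeffs)
  if (!is.data.frame(scenarios) || !"levels" %in% names(scenarios)) {
    stop_input("`scenarios` must be a scenario tibble with a `levels` list-column")
  }
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    if (!all(dim(vcov) == nrow(coeffs))) {
      stop_input("`vcov` must be square with one row per coefficient")
    }
  }
  key <- paste(coeffs$attribute, coeffs$level, sep = "\r")
  stats <- purrr::map(scenarios$levels, function(lv) {
    if (nrow(lv) == 0) {
      return(c(utility = 0, se = 0))
    }
    i <- match(paste(lv$attribute, lv$level, sep = "\r"), key)
    if (anyNA(i)) {
      bad <- lv[is.na(i), ]
      stop_input(paste0(
        "unknown attribute/level pair: ", bad$attribute[1], " / ", bad$level[1]
      ))
    }
    u <- sum(coeffs$coefficient[i])
    se <- if (is.null(vcov)) {
      sqrt(sum(coeffs$std_error[i]^2))
    } else {
      ind <- as.numeric(seq_len(nrow(coeffs)) %in% i)
      sqrt(drop(t(ind) %*% vcov %*% ind))
    }
    c(utility = u, se = se)
  })
  scenarios$utility <- purrr::map_dbl(stats, 1)
  scenarios$se_utility <- purrr::map_dbl(stats, 2)
  scenarios
}

#' Incremental uptake from a utility shift
#'
#' Translates scenario utilities into percentage-point changes in the
#' probability of using the service, under a two-alternative contrast: the
#' status-quo alternative's utility is fixed so that the baseline choice
#' probability equals `baseline_prob`, and the modified service adds the
#' scenario's utility on the log-odds scale.  The change is
#' `100 * (plogis(qlogis(p0) + u) - p0)`.
#'
#' The standard error is obtained by the delta method on the percentage-point
#' scale, `100 * p * (1 - p) * se(u)` evaluated at the shifted probability
#' `p`, and the confidence interval is symmetric about the point estimate.
#'
#' @param scenarios A scenario tibble.
#' @param coeffs A coefficient tibble.
#' @param baseline_prob Baseline uptake probability, strictly inside (0, 1).
#' @param conf_level Confidence level for the interval (default 0.95, i.e.
#'   `z = 1.959964`).
#' @param vcov Optional coefficient covariance matrix (see
#'   [scenario_utility()]).
#' @return `scenarios` with columns `utility`, `se_utility`, `delta_pp`,
#'   `se_pp`, `ci_low_pp`, `ci_high_pp` (all uptake columns in percentage
#'   points).
#' @examples
#' coeffs <- load_dce_coefficients()
#' sc <- enumerate_scenarios(coeffs)
#' delta_uptake(sc, coeffs, baseline_prob = 0.306)
#' @export
delta_uptake <- function(scenarios, coeffs, baseline_prob,
                         conf_level = 0.95, vcov = NULL) {
  if (!is.numeric(baseline_prob) || length(baseline_prob) != 1 ||
      !is.finite(baseline_prob) || baseline_prob <= 0 || baseline_prob >= 1) {
    stop_input("`baseline_prob` must be a single probability strictly in (0, 1)")
  }
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1) {
    stop_input("`conf_level` must be in (0, 1)")
  }
  out <- scenario_utility(scenarios, coeffs, vcov = vcov)
  p_new <- plogis(qlogis(baseline_prob) + out$utility)
  z <- qnorm(1 - (1 - conf_level) / 2)
  out$delta_pp <- 100 * (p_new - baseline_prob)
  out$se_pp <- 100 * p_new * (1 - p_new) * out$se_utility
  out$ci_low_pp <- out$delta_pp - z * out$se_pp
  out$ci_high_pp <- out$delta_pp + z * out$se_pp
  out
}

#' Total uptake share per scenario
#'
#' Adds the projected total share of adolescents using services: the baseline
#' share plus the scenario's percentage-point change, reported to two
#' decimals.
#'
#' @param deltas A tibble with a `delta_pp` column (e.g. from
#'   [delta_uptake()] or [load_uptake_table()]).
#' @param baseline_share Baseline uptake share in percent, inside (0, 100).
#' @return `deltas` with an added `total_share_pct` column.
#' @examples
#' tabulate_uptake(tibble::tibble(delta_pp = c(18.54, 55)), 30.60)
#' @export
tabulate_uptake <- function(deltas, baseline_share) {
  if (!is.numeric(baseline_share) || length(baseline_share) != 1 ||
      baseline_share <= 0 || baseline_share >= 100) {
    stop_input("`baseline_share` must be a single percentage in (0, 100)")
  }
  if (!"delta_pp" %in% names(deltas)) {
    stop_input("`deltas` must contain a `delta_pp` column")
  }
  dplyr::mutate(
    tibble::as_tibble(deltas),
    total_share_pct = round(baseline_share + .data$delta_pp, 2)
  )
}
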