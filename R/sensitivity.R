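#' One-way sensitivity analysis on the uptake confidence bounds
#'
#' Re-runs the uptake -> cost -> frontier pipeline with every scenario's
#' uptake change replaced by the chosen bound of its confidence interval.
#' This probes possible over-estimation of real-world uptake from stated
#' preferences: at the lower bound, space- and staff-hungry interventions can
#' fall off the frontier while interventions whose costs are shared across
#' patients stay cost-effective.
#'
#' @param deltas Per-scenario uptake tibble with `scenario`, `delta_pp`,
#'   `levels`, and (for non-point bounds) `ci_low_pp` / `ci_high_pp`.
#' @param profile Clinic profile ([clinic_profile()]).
#' @param lines Cost workbook lines ([cost_lines()]).
#' @param config Costing configuration ([cost_config()]).
#' @param bound Which uptake value to use: `"point"` (the base case),
#'   `"lower"` or `"upper"` CI bound.
#' @param floor Lower clamp for additional counts; 0 by default, 1 reproduces
#'   published sensitivity tables that floor negative projections at one
#'   person.
#' @param use_exact_effects Run the dominance engine on unrounded counts.
#' @return An object of class `uptake_sensitivity`: list with `bound`,
#'   `table` (projection joined with costs), and `frontier` (a
#'   [build_frontier()] result).
#' @examples
#' deltas <- load_uptake_table(modifiable_only = TRUE)
#' profile <- load_clinic_profiles()[2, ]
#' lines <- load_cost_workbook()
#' run_sensitivity(deltas, profile, lines, bound = "lower")
#' @export
run_sensitivity <- function(deltas, profile, lines, config = cost_config(),
                            bound = c("point", "lower", "upper"),
                            floor = 0, use_exact_effects = FALSE) {
  bound <- match.arg(bound)
  deltas <- tibble::as_tibble(deltas)
  if (bound != "point") {
    col <- if (bound == "lower") "ci_low_pp" else "ci_high_pp"
    if (!col %in% names(deltas) || anyNA(deltas[[col]])) {
      missing_sc <- if (col %in% names(deltas)) {
        deltas$scenario[is.na(deltas[[col]])]
      } else {
        deltas$scenario
      }
      stop_input(paste0(
        "missing ", bound, " confidence bound for scenario(s): ",
        paste(missing_sc, collapse = ", ")
      ))
    }
    deltas$delta_pp <- deltas[[col]]
  }
  projection <- project_uptake(deltas, profile, floor = floor)
  costs <- scenario_costs(projection, lines, profile, config)
  tab <- dplyr::left_join(projection, costs, by = "scenario")
  strategies <- tibble::tibble(
    name = tab$scenario,
    effect = tab$additional_per_month,
    effect_exact = tab$additional_exact,
    cost = tab$total_cost_usd
  )
  frontier <- build_frontier(strategies, use_exact_effects = use_exact_effects)
  tab <- dplyr::left_join(
    tab,
    frontier$strategies[c("name", "status", "icer")],
    by = c(scenario = "name")
  )
  structure(
    list(bound = bound, floor = floor, table = tab, frontier = frontier),
    class = "uptake_sensitivity"
  )
}

#' @export
print.uptake_sensitivity <- function(x, ...) {
  cat("Uptake sensitivity analysis (bound = ", x$bound,
      ", floor = ", x$floor, ")\n", sep = "")
  print(x$frontier)
  invisible(x)
}
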