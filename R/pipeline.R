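#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run in one place so the run log can
#' record exactly which conventions were in effect (rounding, exchange rate,
#' comparator, clamping) -- precisely the choices cost-effectiveness tables
#' usually leave implicit.
#'
#' @param clinic `"A"` or `"B"` (selects the packaged profile) -- ignored if
#'   `clinic_profiles` is a path.
#' @param deltas `"fixtures"` to use the packaged published uptake table, or
#'   a path to a CSV in the same layout.
#' @param cost_workbook `"fixtures"` for the packaged table-derived strategy
#'   costs, `"workbook"` for the packaged synthetic cost workbook, or a path
#'   to a workbook CSV.
#' @param clinic_profiles Optional path to a clinic profile CSV.
#' @param config A [cost_config()].
#' @param bound Sensitivity bound for the run: `"point"`, `"lower"` or
#'   `"upper"`.
#' @param floor Lower clamp for additional counts (0, or 1 for compatibility
#'   with published sensitivity tables).
#' @param use_exact_effects Run ICERs on unrounded effects.
#' @param out_dir Output directory (created if needed).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(clinic = "B",
                            deltas = "fixtures",
                            cost_workbook = "fixtures",
                            clinic_profiles = NULL,
                            config = cost_config(),
                            bound = c("point", "lower", "upper"),
                            floor = 0,
                            use_exact_effects = FALSE,
                            out_dir = tempfile("choicefrontier_run_")) {
  bound <- match.arg(bound)
  if (!inherits(config, "cost_config")) {
    stop_config("`config` must be created by cost_config()")
  }
  if (identical(cost_workbook, "fixtures") && bound != "point") {
    stop_config(
      "fixture-cost mode cannot recost a confidence bound; use the workbook"
    )
  }
  for (arg in c("deltas", "cost_workbook")) {
    v <- get(arg)
    if (!identical(v, "fixtures") && !identical(v, "workbook") &&
        !file.exists(v)) {
      stop_input(paste0("`", arg, "` file not found: ", v))
    }
  }
  structure(
    list(
      clinic = clinic, deltas = deltas, cost_workbook = cost_workbook,
      clinic_profiles = clinic_profiles, config = config, bound = bound,
      floor = floor, use_exact_effects = use_exact_effects, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full translation pipeline
#'
#' Executes scenario enumeration, uptake projection, costing, frontier
#' construction and (optionally) the confidence-bound sensitivity run, and
#' writes three files to the output directory: `strategies.csv` (the
#' clinic-table-shaped report), `report.json` (full-precision machine-readable
#' results) and `run_log.txt` (every convention flag in effect).  The
#' pipeline is a pure function of its inputs and configuration: repeated runs
#' produce byte-identical outputs.
#'
#' In `cost_workbook = "fixtures"` mode the published per-strategy total
#' costs are used directly (so the frontier reproduces the published
#' arithmetic); this mode supports only `bound = "point"`, since costs cannot
#' be re-derived for changed counts.  In workbook mode costs are recomputed
#' from the cost lines at whichever bound is requested.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `projection`, `costs` (workbook mode),
#'   `frontier`, `table` and `paths`.
#' @examples
#' res <- run_pipeline(pipeline_config(clinic = "B"))
#' res$frontier
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("`config` must be created by pipeline_config()")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir, c("strategies.csv", "report.json", "run_log.txt"))
  names(paths) <- c("strategies", "report", "log")
  on_fail <- function(e) {
    unlink(paths[file.exists(paths)])
    abort(
      paste0("pipeline failed: ", conditionMessage(e)),
      class = "choicefrontier_pipeline_error", parent = e
    )
  }
  result <- tryCatch(run_pipeline_impl(config, paths), error = on_fail)
  invisible(result)
}

run_pipeline_impl <- function(config, paths) {
  profiles <- if (is.null(config$clinic_profiles)) {
    load_clinic_profiles()
  } else {
    read_clinic_profiles(config$clinic_profiles)
  }
  profile <- profiles[profiles$clinic == config$clinic, ]
  if (nrow(profile) != 1) {
    stop_input(paste0("no clinic profile named '", config$clinic, "'"))
  }

  if (identical(config$cost_workbook, "fixtures")) {
    if (config$bound != "point") {
      stop_config(
        "fixture-cost mode cannot recost a confidence bound; use the workbook"
      )
    }
    strategies <- load_strategy_table(config$clinic)
    frontier <- build_frontier(
      strategies,
      use_exact_effects = config$use_exact_effects
    )
    tab <- dplyr::left_join(
      strategies[c("name", "additional", "total", "pct_change",
                   "cost_per_additional_usd", "total_cost_usd")],
      frontier$strategies[c("name", "status", "icer")],
      by = "name"
    )
    projection <- costs <- NULL
  } else {
    deltas <- if (identical(config$deltas, "fixtures")) {
      load_uptake_table(modifiable_only = TRUE)
    } else {
      x <- readr::read_csv(config$deltas, col_types = readr::cols())
      x$levels <- attrs_to_levels(x$attributes, load_dce_coefficients())
      x
    }
    lines <- if (identical(config$cost_workbook, "workbook")) {
      load_cost_workbook()
    } else {
      read_cost_workbook(config$cost_workbook)
    }
    sens <- run_sensitivity(
      deltas, profile, lines,
      config = config$config, bound = config$bound, floor = config$floor,
      use_exact_effects = config$use_exact_effects
    )
    projection <- sens$table
    costs <- sens$table
    frontier <- sens$frontier
    tab <- dplyr::transmute(
      sens$table,
      name = .data$scenario,
      additional = .data$additional_per_month,
      total = .data$total_per_month,
      pct_change = .data$delta_pp,
      cost_per_additional_usd = .data$cost_per_additional_usd,
      total_cost_usd = .data$total_cost_usd,
      status = .data$status,
      icer = .data$icer
    )
  }

  readr::write_csv(tab, paths["strategies"], na = "")
  jsonlite::write_json(
    list(
      clinic = config$clinic,
      flags = list(
        bound = config$bound, floor = config$floor,
        use_exact_effects = config$use_exact_effects,
        exchange_rate = config$config$exchange_rate,
        afternoon_hours_fraction = config$config$afternoon_hours_fraction,
        room_share = config$config$room_share,
        cost_source = if (identical(config$cost_workbook, "fixtures")) {
          "fixtures"
        } else {
          "workbook"
        }
      ),
      strategies = tab,
      frontier = frontier$frontier[c("name", "effect", "cost", "icer")]
    ),
    paths["report"],
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  writeLines(c(
    "choicefrontier pipeline run",
    paste0("clinic: ", config$clinic),
    paste0("deltas: ", config$deltas),
    paste0("cost source: ", config$cost_workbook),
    paste0("bound: ", config$bound),
    paste0("count floor: ", config$floor),
    paste0("rounding: half away from zero; ICER effects ",
           if (config$use_exact_effects) "unrounded" else "rounded"),
    paste0("exchange rate (ZAR/USD): ", config$config$exchange_rate),
    paste0("afternoon staff-time fraction: ",
           config$config$afternoon_hours_fraction),
    paste0("counselling-room overhead share: ", config$config$room_share),
    "comparator: zero-cost, zero-effect baseline"
  ), paths["log"])

  list(
    projection = projection, costs = costs, frontier = frontier,
    table = tab, paths = paths
  )
}
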