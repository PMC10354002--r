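ALLOCATION_KINDS <- c(
  "none_incremental", "per_visit", "shared_all_patients",
  "extra_room_overhead", "afternoon_staff_time",
  "all_adolescents_billed_to_additional"
)

#' Costing configuration
#'
#' Knobs of the cost-allocation model that published clinic costings usually
#' leave implicit.
#'
#' @param exchange_rate Local-currency units per USD (default 14 ZAR/USD, the
#'   2019 mid-year rate).
#' @param afternoon_hours_fraction Fraction of the monthly staff bill
#'   attributable to the afternoon service extension (default 0.02: roughly
#'   two extra hours per day covered by a skeleton roster).
#' @param room_share One counselling room's share of facility overheads
#'   (default 0.08).
#' @return A list of class `cost_config`.
#' @export
cost_config <- function(exchange_rate = 14,
                        afternoon_hours_fraction = 0.02,
                        room_share = 0.08) {
  if (!is.numeric(exchange_rate) || exchange_rate <= 0) {
    stop_config("`exchange_rate` must be > 0")
  }
  if (!is.numeric(afternoon_hours_fraction) || afternoon_hours_fraction < 0 ||
      afternoon_hours_fraction > 1) {
    stop_config("`afternoon_hours_fraction` must be in [0, 1]")
  }
  if (!is.numeric(room_share) || room_share < 0 || room_share > 1) {
    stop_config("`room_share` must be in [0, 1]")
  }
  structure(
    list(
      exchange_rate = exchange_rate,
      afternoon_hours_fraction = afternoon_hours_fraction,
      room_share = room_share
    ),
    class = "cost_config"
  )
}

#' Read a costing configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [cost_config()].
#' @return A `cost_config` list.
#' @export
read_cost_config <- function(path) {
  if (!file.exists(path)) {
    stop_config(paste0("cost config file not found: ", path))
  }
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(cost_config)))
  if (length(unknown) > 0) {
    stop_config(paste0("unknown cost config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(cost_config, vals)
}

#' Convert local currency to USD
#'
#' @param amount_zar Amount in local currency (ZAR).
#' @param rate Exchange rate in ZAR per USD (default 14).
#' @return Amount in USD.
#' @examples
#' convert_currency(c(14, 140))  # 1 10
#' @export
convert_currency <- function(amount_zar, rate = 14) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop_config("exchange `rate` must be a single positive number")
  }
  if (any(!is.finite(amount_zar))) {
    stop_input("`amount_zar` must be finite")
  }
  amount_zar / rate
}

# "a|b" -> c("a","b"); numbers parsed, everything else kept as character
parse_params <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) {
    return(list())
  }
  pairs <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop_config(paste0("malformed param entry: '", pairs[bad][1], "'"))
  }
  vals <- lapply(kv, function(p) {
    v <- strsplit(trimws(p[2]), "|", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  setNames(vals, vapply(kv, function(p) trimws(p[1]), ""))
}

#' Read a cost workbook from a CSV file
#'
#' A cost workbook has one line per cost category with its total monthly
#' amount in local currency and the allocation rule that converts it into an
#' incremental cost for a scenario.  The `params` column holds rule-specific
#' settings as `name=value` pairs separated by `;` (multiple values joined by
#' `|`), e.g. `unit_cost_zar=1.12` or `requires_any=youth_only|afternoon`.
#'
#' @param path CSV with columns `category`, `monthly_amount_zar`,
#'   `allocation`, `params`.
#' @return A tibble of cost lines with `params` parsed into a list-column.
#' @export
read_cost_workbook <- function(path) {
  if (!file.exists(path)) {
    stop_input(paste0("cost workbook not found: ", path))
  }
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      category = readr::col_character(),
      monthly_amount_zar = readr::col_double(),
      allocation = readr::col_character(),
      params = readr::col_character()
    )
  )
  cost_lines(x)
}

#' Validate a table of cost lines
#'
#' @param x A data frame with columns `category`, `monthly_amount_zar`,
#'   `allocation`, and either a `params` character column (`name=value;...`)
#'   or an already-parsed `params` list-column.
#' @return A validated tibble of cost lines.
#' @export
cost_lines <- function(x) {
  required <- c("category", "monthly_amount_zar", "allocation")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_input(paste0(
      "cost workbook is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)
  unknown <- setdiff(x$allocation, ALLOCATION_KINDS)
  if (length(unknown) > 0) {
    stop_config(paste0(
      "unknown allocation rule(s): ", paste(unknown, collapse = ", "),
      " (valid: ", paste(ALLOCATION_KINDS, collapse = ", "), ")"
    ))
  }
  if (any(!is.finite(x$monthly_amount_zar) | x$monthly_amount_zar < 0)) {
    stop_input("`monthly_amount_zar` must be finite and >= 0")
  }
  if (!"params" %in% names(x)) {
    x$params <- vector("list", nrow(x))
  } else if (is.character(x$params)) {
    x$params <- lapply(x$params, parse_params)
  }
  x$params <- lapply(x$params, function(p) if (is.null(p)) list() else p)
  x
}

need_param <- function(params, name, category) {
  if (is.null(params[[name]])) {
    stop_config(paste0(
      "cost line '", category, "' needs param `", name, "` for its allocation rule"
    ))
  }
  params[[name]]
}

# Monthly incremental cost of one line for one scenario, in ZAR.
# `attrs` is the character vector of attribute keys switched on.
allocate_line_zar <- function(category, monthly_amount_zar, allocation, params,
                              attrs, additional_exact, total_per_month,
                              headcount, config) {
  gate_ok <- TRUE
  if (!is.null(params$requires)) {
    gate_ok <- all(params$requires %in% attrs)
  }
  if (!gate_ok) {
    return(0)
  }
  switch(allocation,
    none_incremental = 0,
    per_visit = {
      unit <- need_param(params, "unit_cost_zar", category)
      unit * additional_exact
    },
    shared_all_patients = {
      if (!is.finite(headcount) || headcount <= 0) {
        stop_config(paste0(
          "cost line '", category,
          "' is shared over all patients but the clinic profile has no ",
          "`total_monthly_headcount`"
        ))
      }
      monthly_amount_zar * additional_exact / (headcount + additional_exact)
    },
    extra_room_overhead = {
      gate <- params$requires_any %||% c("youth_only", "afternoon")
      if (any(gate %in% attrs)) config$room_share * monthly_amount_zar else 0
    },
    afternoon_staff_time = {
      gate <- params$requires_any %||% "afternoon"
      if (any(gate %in% attrs)) {
        monthly_amount_zar * config$afternoon_hours_fraction
      } else {
        0
      }
    },
    all_adolescents_billed_to_additional = {
      unit <- need_param(params, "amount_per_adolescent_zar", category)
      unit * total_per_month
    },
    stop_config(paste0("unknown allocation rule: ", allocation))
  )
}

#' Incremental monthly cost of each scenario
#'
#' Applies each cost line's allocation rule to each projected scenario and
#' converts to USD.  Rules follow an incremental-cost logic: only costs that
#' change because of the modification are counted, attribute-gated lines
#' (food, Wi-Fi, afternoon staffing, youth-only space) contribute zero to
#' scenarios that do not switch the relevant attribute, and costs shared over
#' all patients are scaled by the additional patients' share of the expanded
#' headcount.
#'
#' The cost per additional adolescent divides the total by the *unrounded*
#' additional count; it is `NA` when a scenario has positive cost but no
#' additional uptake.
#'
#' @param projection Output of [project_uptake()] whose rows carry a `levels`
#'   list-column (scenario attribute bundles).
#' @param lines Cost lines ([cost_lines()] / [read_cost_workbook()]).
#' @param profile The clinic profile used for the projection.
#' @param config A [cost_config()].
#' @return A tibble with one row per scenario: `cost_<category>_usd` columns,
#'   `total_cost_usd` and `cost_per_additional_usd`.
#' @export
scenario_costs <- function(projection, lines, profile, config = cost_config()) {
  lines <- cost_lines(lines)
  if (nrow(lines) == 0) {
    stop_input("cost workbook has no lines")
  }
  if (!inherits(config, "cost_config")) {
    stop_config("`config` must be created by cost_config()")
  }
  needed <- c("scenario", "levels", "additional_exact", "total_per_month")
  missing_cols <- setdiff(needed, names(projection))
  if (length(missing_cols) > 0) {
    stop_input(paste0(
      "projection is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  headcount <- profile$total_monthly_headcount
  per_scenario <- purrr::pmap(
    projection[needed],
    function(scenario, levels, additional_exact, total_per_month) {
      attrs <- levels$attribute
      zar <- purrr::pmap_dbl(
        lines[c("category", "monthly_amount_zar", "allocation", "params")],
        function(category, monthly_amount_zar, allocation, params) {
          allocate_line_zar(
            category, monthly_amount_zar, allocation, params,
            attrs, additional_exact, total_per_month, headcount, config
          )
        }
      )
      usd <- convert_currency(zar, config$exchange_rate)
      by_cat <- vapply(split(usd, lines$category), sum, 0)
      total <- sum(usd)
      per_add <- if (additional_exact > 0) {
        total / additional_exact
      } else if (total == 0) {
        0
      } else {
        NA_real_
      }
      tibble::tibble(
        scenario = scenario,
        !!!setNames(as.list(by_cat), paste0("cost_", names(by_cat), "_usd")),
        total_cost_usd = total,
        cost_per_additional_usd = per_add
      )
    }
  )
  dplyr::bind_rows(per_scenario)
}
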