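#' Validate a coefficient table
#'
#' A coefficient table holds one row per non-reference attribute level of a
#' discrete choice experiment, with the conditional-logit coefficient (the
#' utility shift relative to the reference level of that attribute) and its
#' standard error.  Reference levels are implicit: under dummy coding they
#' contribute zero utility, so the baseline service configuration always has
#' utility 0.
#'
#' @param x A data frame with columns `attribute` (short machine key, e.g.
#'   `"wifi"`), `level` (display label), `coefficient`, `std_error` and
#'   `modifiable` (logical: can the attribute realistically be changed and
#'   costed at a clinic?).
#' @return A validated tibble with those five columns.
#' @examples
#' coefficient_set(tibble::tibble(
#'   attribute = c("wifi", "food"), level = c("Wi-Fi", "Food"),
#'   coefficient = c(0.03, 0.02), std_error = c(0.04, 0.03),
#'   modifiable = TRUE
#' ))
#' @export
coefficient_set <- function(x) {
  required <- c("attribute", "level", "coefficient", "std_error", "modifiable")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_input(paste0(
      "coefficient table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)[required]
  if (anyDuplicated(x[c("attribute", "level")]) > 0) {
    dup <- x[duplicated(x[c("attribute", "level")]), ]
    stop_input(paste0(
      "duplicate (attribute, level) pair: ",
      dup$attribute[1], " / ", dup$level[1]
    ))
  }
  if (any(!is.finite(x$coefficient))) {
    stop_input("coefficients must be finite")
  }
  if (any(!is.finite(x$std_error) | x$std_error < 0)) {
    stop_input("standard errors must be finite and >= 0")
  }
  if (any(is.na(x$modifiable))) {
    stop_input("`modifiable` must be TRUE or FALSE for every level")
  }
  x
}

#' Read a coefficient table from a CSV file
#'
#' @param path Path to a comma-separated file with columns `attribute`,
#'   `level`, `coefficient`, `std_error`, `modifiable`.
#' @return A validated coefficient tibble (see [coefficient_set()]).
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) {
    stop_input(paste0("coefficient table not found: ", path))
  }
  coefficient_set(readr::read_csv(
    path,
    col_types = readr::cols(
      attribute = readr::col_character(),
      level = readr::col_character(),
      coefficient = readr::col_double(),
      std_error = readr::col_double(),
      modifiable = readr::col_logical()
    )
  ))
}

#' Enumerate intervention scenarios
#'
#' Builds every non-empty bundle of attribute levels that can be switched on
#' relative to the baseline service, at most one level per attribute.  With
#' `k` single-level attributes this yields `2^k - 1` mutually exclusive
#' combinations -- e.g. the 15 combinations of the four modifiable attributes
#' (Wi-Fi, subsidized food, afternoon hours, youth-only space).
#'
#' @param coeffs A coefficient tibble (see [coefficient_set()]).
#' @param only_modifiable Restrict to levels flagged `modifiable` (default
#'   `TRUE`).
#' @return A tibble with columns `scenario` (name: level labels joined by
#'   `" + "`), `n_levels`, and `levels`, a list-column of tibbles with the
#'   switched `attribute`/`level` pairs.  Rows are ordered by bundle size,
#'   then alphabetically by name.
#' @examples
#' coeffs <- load_dce_coefficients()
#' nrow(enumerate_scenarios(coeffs))                         # 15
#' nrow(enumerate_scenarios(coeffs, only_modifiable = FALSE)) # 63
#' @export
enumerate_scenarios <- function(coeffs, only_modifiable = TRUE) {
  coeffs <- coefficient_set(coeffs)
  sel <- if (only_modifiable) dplyr::filter(coeffs, .data$modifiable) else coeffs
  k <- nrow(sel)
  if (k < 1) {
    stop_input("no attribute levels match the filter; nothing to enumerate")
  }
  if (k > 16) {
    stop_input("refusing to enumerate more than 2^16 scenario combinations")
  }
  idx_sets <- unlist(
    lapply(seq_len(k), function(s) combn(k, s, simplify = FALSE)),
    recursive = FALSE
  )
  # at most one level per attribute
  idx_sets <- purrr::keep(idx_sets, function(i) !anyDuplicated(sel$attribute[i]))
  out <- tibble::tibble(
    scenario = purrr::map_chr(idx_sets, function(i) {
      paste(sort(sel$level[i]), collapse = " + ")
    }),
    n_levels = lengths(idx_sets),
    levels = purrr::map(idx_sets, function(i) {
      tibble::tibble(attribute = sel$attribute[i], level = sel$level[i])
    })
  )
  dplyr::arrange(out, .data$n_levels, .data$scenario)
}

#' Build a scenario table from level labels
#'
#' Convenience constructor for ad-hoc scenarios: each element of `...` is a
#' character vector of level labels (as in the coefficient table) switched on
#' together.
#'
#' @param coeffs A coefficient tibble.
#' @param ... Named or unnamed character vectors of level labels; names become
#'   scenario names (default: labels joined by `" + "`).
#' @return A scenario tibble as produced by [enumerate_scenarios()].
#' @examples
#' coeffs <- load_dce_coefficients()
#' make_scenarios(coeffs, c("Wi-Fi", "Food"), baseline = character())
#' @export
make_scenarios <- function(coeffs, ...) {
  coeffs <- coefficient_set(coeffs)
  bundles <- list(...)
  if (length(bundles) == 0) {
    stop_input("supply at least one bundle of level labels")
  }
  nm <- names(bundles) %||% rep("", length(bundles))
  rows <- purrr::map(seq_along(bundles), function(i) {
    lv <- bundles[[i]]
    hit <- coeffs[match(lv, coeffs$level), ]
    if (length(lv) > 0 && anyNA(hit$attribute)) {
      stop_input(paste0(
        "unknown level label(s): ",
        paste(lv[is.na(hit$attribute)], collapse = ", ")
      ))
    }
    if (anyDuplicated(hit$attribute) > 0) {
      stop_input("a scenario may switch at most one level per attribute")
    }
    name <- if (nzchar(nm[[i]])) nm[[i]] else paste(sort(lv), collapse = " + ")
    tibble::tibble(
      scenario = name,
      n_levels = length(lv),
      levels = list(tibble::tibble(attribute = hit$attribute, level = hit$level))
    )
  })
  dplyr::bind_rows(rows)
}
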