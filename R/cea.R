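as_strategy_row <- function(x, arg) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) {
      stop_input(paste0("`", arg, "` must be a single strategy (one row)"))
    }
    x <- as.list(x)
  }
  if (is.null(x$cost) || is.null(x$effect)) {
    stop_input(paste0("`", arg, "` must have `cost` and `effect` components"))
  }
  x
}

#' Incremental cost-effectiveness ratio of one strategy versus another
#'
#' `(cost_a - cost_b) / (effect_a - effect_b)`: the extra cost per extra
#' adolescent expected to use services when moving from strategy `b` to
#' strategy `a`.  By default effects are used as given (typically whole-person
#' counts, matching published tables); set `use_exact_effects = TRUE` to use
#' an `effect_exact` component when present.
#'
#' @param a,b One-row data frames or lists with `cost` and `effect`
#'   (optionally `effect_exact`).
#' @param use_exact_effects Use unrounded effects if available.
#' @return The ICER in cost units per effect unit.
#' @examples
#' pairwise_icer(list(cost = 1465.56, effect = 138), list(cost = 516.65, effect = 41))
#' @export
pairwise_icer <- function(a, b, use_exact_effects = FALSE) {
  a <- as_strategy_row(a, "a")
  b <- as_strategy_row(b, "b")
  eff <- function(s) {
    if (use_exact_effects && !is.null(s$effect_exact)) s$effect_exact else s$effect
  }
  de <- eff(a) - eff(b)
  if (de == 0) {
    stop_input(
      "strategies have equal effects; resolve the pair by dominance, not an ICER"
    )
  }
  (a$cost - b$cost) / de
}

validate_strategies <- function(strategies, use_exact_effects = FALSE) {
  if (!is.data.frame(strategies) ||
      !all(c("name", "effect", "cost") %in% names(strategies))) {
    stop_input("`strategies` must have columns `name`, `effect`, `cost`")
  }
  x <- tibble::as_tibble(strategies)
  if (anyDuplicated(x$name) > 0) {
    stop_input("strategy names must be unique")
  }
  x$effect_used <- if (use_exact_effects && "effect_exact" %in% names(x)) {
    x$effect_exact
  } else {
    x$effect
  }
  if (any(!is.finite(x$effect_used) | x$effect_used < 0)) {
    stop_input("effects must be finite and >= 0")
  }
  if (any(!is.finite(x$cost) | x$cost < 0)) {
    stop_input("costs must be finite and >= 0")
  }
  x
}

# TRUE for rows strictly dominated by another strategy or by the zero-cost,
# zero-effect baseline: some competitor costs no more and achieves no less,
# with at least one comparison strict.
strictly_dominated <- function(effect, cost) {
  n <- length(effect)
  e <- c(effect, 0)
  co <- c(cost, 0)
  vapply(seq_len(n), function(i) {
    j <- setdiff(seq_len(n + 1), i)
    any(co[j] <= cost[i] & e[j] >= effect[i] & (co[j] < cost[i] | e[j] > effect[i]))
  }, TRUE)
}

#' Flag strictly dominated strategies
#'
#' A strategy is dominated when some other strategy (or doing nothing, the
#' implicit zero-cost zero-effect baseline) is at least as effective and no
#' more costly, with at least one comparison strict.  The result does not
#' depend on input order.
#'
#' @param strategies Tibble with `name`, `effect`, `cost` (and optionally
#'   `effect_exact`).
#' @param use_exact_effects Compare on unrounded effects if available.
#' @return `strategies` with a logical `dominated` column.
#' @export
eliminate_dominated <- function(strategies, use_exact_effects = FALSE) {
  x <- validate_strategies(strategies, use_exact_effects)
  x$dominated <- strictly_dominated(x$effect_used, x$cost)
  x$effect_used <- NULL
  x
}

# Extended (weak) dominance on strategies already free of strict dominance:
# survivors are the vertices of the lower-left convex hull of (effect, cost)
# anchored at the origin; equivalently, walking up the cost ordering, any
# strategy whose ICER against its predecessor is >= the ICER of its successor
# against it is removed and the ladder recomputed.  Exact (cost, effect) ties
# keep the lexicographically first name.
weakly_dominated <- function(name, effect, cost) {
  n <- length(effect)
  # a strategy indistinguishable from doing nothing ties with the baseline
  weak <- effect == 0 & cost == 0
  key <- paste(cost, effect)
  # a duplicate of a kept point is weakly dominated by the tie-break rule
  ord_rank <- order(key, name)
  is_first <- rep(FALSE, n)
  seen <- character(0)
  for (i in ord_rank) {
    if (key[i] %in% seen) {
      weak[i] <- TRUE
    } else {
      seen <- c(seen, key[i])
    }
  }
  alive <- which(!weak)
  repeat {
    o <- alive[order(cost[alive], effect[alive], name[alive])]
    e <- c(0, effect[o])
    co <- c(0, cost[o])
    icer <- diff(co) / diff(e)
    drop <- which(head(icer, -1) >= icer[-1])
    if (length(drop) == 0) {
      break
    }
    weak[o[drop[1]]] <- TRUE
    alive <- which(!weak)
    if (length(alive) <= 1) {
      break
    }
  }
  weak
}

#' Flag weakly (extendedly) dominated strategies
#'
#' Assumes strictly dominated strategies have already been removed (use
#' [eliminate_dominated()] first, or [build_frontier()] for the whole
#' procedure).  Surviving strategies form the lower-left convex hull of the
#' (effect, cost) points anchored at the zero-cost zero-effect origin, so the
#' ICER ladder along them is strictly increasing.
#'
#' @inheritParams eliminate_dominated
#' @return `strategies` with a logical `weakly_dominated` column.
#' @export
eliminate_extended_dominance <- function(strategies, use_exact_effects = FALSE) {
  x <- validate_strategies(strategies, use_exact_effects)
  if (any(strictly_dominated(x$effect_used, x$cost))) {
    stop_input(
      "remove strictly dominated strategies before extended-dominance pruning"
    )
  }
  x$weakly_dominated <- weakly_dominated(x$name, x$effect_used, x$cost)
  x$effect_used <- NULL
  x
}

#' Build the cost-effectiveness frontier
#'
#' Runs the full incremental analysis over a strategy set: strictly dominated
#' strategies are removed first, extended dominance prunes the rest down to
#' the lower convex hull of the effect-cost plane, survivors are ordered by
#' increasing cost, and each receives the ICER against its frontier
#' predecessor (the first against the zero-cost, zero-effect "do nothing"
#' baseline).
#'
#' @param strategies Tibble with `name`, `effect` (additional adolescents per
#'   month), `cost` (total monthly cost, USD) and optionally `effect_exact`.
#' @param use_exact_effects Compute ICERs and dominance on unrounded effects.
#' @return An object of class `cea_frontier` with components `strategies`
#'   (every strategy with a `status` label among `non_dominated`, `dominated`,
#'   `weakly_dominated`, and `icer` for frontier members) and `frontier` (the
#'   ordered survivors).  Supports [tidy()], [glance()], [autoplot()] and
#'   `print()`.
#' @examples
#' frontier <- build_frontier(load_strategy_table("B"))
#' tidy(frontier)
#' @export
build_frontier <- function(strategies, use_exact_effects = FALSE) {
  x <- validate_strategies(strategies, use_exact_effects)
  x$status <- "non_dominated"
  x$status[strictly_dominated(x$effect_used, x$cost)] <- "dominated"
  alive <- x$status == "non_dominated"
  if (any(alive)) {
    weak <- weakly_dominated(
      x$name[alive], x$effect_used[alive], x$cost[alive]
    )
    x$status[which(alive)[weak]] <- "weakly_dominated"
  }
  x$icer <- NA_real_
  surv <- which(x$status == "non_dominated")
  surv <- surv[order(x$cost[surv], x$effect_used[surv])]
  if (length(surv) > 0) {
    e <- c(0, x$effect_used[surv])
    co <- c(0, x$cost[surv])
    x$icer[surv] <- diff(co) / diff(e)
  }
  frontier <- x[surv, ]
  structure(
    list(
      strategies = tibble::as_tibble(x[setdiff(names(x), "effect_used")]),
      frontier = tibble::as_tibble(frontier[setdiff(names(frontier), "effect_used")]),
      use_exact_effects = use_exact_effects
    ),
    class = "cea_frontier"
  )
}

#' @export
print.cea_frontier <- function(x, ...) {
  n <- nrow(x$strategies)
  cat("Cost-effectiveness frontier:", nrow(x$frontier), "of", n,
      "strategies non-dominated\n")
  if (nrow(x$frontier) > 0) {
    f <- x$frontier
    cat(paste0(
      "  ", format(f$name), "  effect ", format(f$effect),
      "  cost $", formatC(f$cost, format = "f", digits = 2),
      "  ICER $", formatC(f$icer, format = "f", digits = 2), "\n"
    ), sep = "")
  }
  invisible(x)
}

#' @describeIn build_frontier One row per strategy with its status label and
#'   (for frontier members) the ICER against the frontier predecessor.
#' @param x A `cea_frontier` object.
#' @param ... Unused.
#' @export
tidy.cea_frontier <- function(x, ...) {
  x$strategies
}

#' @describeIn build_frontier One-row summary of the frontier.
#' @export
glance.cea_frontier <- function(x, ...) {
  tibble::tibble(
    n_strategies = nrow(x$strategies),
    n_frontier = nrow(x$frontier),
    n_dominated = sum(x$strategies$status == "dominated"),
    n_weakly_dominated = sum(x$strategies$status == "weakly_dominated"),
    first_icer = if (nrow(x$frontier) > 0) x$frontier$icer[1] else NA_real_,
    last_icer = if (nrow(x$frontier) > 0) {
      x$frontier$icer[nrow(x$frontier)]
    } else {
      NA_real_
    }
  )
}

#' @describeIn build_frontier Effect-cost scatter with the frontier drawn
#'   from the origin through the surviving strategies.
#' @param object A `cea_frontier` object.
#' @export
autoplot.cea_frontier <- function(object, ...) {
  strategies <- object$strategies
  hull <- dplyr::bind_rows(
    tibble::tibble(name = "baseline", effect = 0, cost = 0),
    object$frontier[c("name", "effect", "cost")]
  )
  ggplot2::ggplot(strategies, ggplot2::aes(x = .data$effect, y = .data$cost)) +
    ggplot2::geom_line(data = hull, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 2) +
    ggplot2::labs(
      x = "Additional adolescents using services per month",
      y = "Total monthly cost (USD)",
      colour = NULL,
      title = "Cost-effectiveness frontier"
    ) +
    ggplot2::theme_minimal()
}
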