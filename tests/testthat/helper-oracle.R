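# Independent brute-force oracle for the efficiency frontier: starting from
# the do-nothing origin, repeatedly step to the strategy with the smallest
# cost-per-effect slope among those with strictly larger effect (ties: largest
# effect, then lexicographically smallest name).  The visited strategies are
# the vertices of the lower-left convex hull, i.e. the non-dominated set.
oracle_frontier_names <- function(strategies) {
  eff <- strategies$effect
  cost <- strategies$cost
  nm <- strategies$name
  cur_e <- 0
  cur_c <- 0
  out <- character(0)
  repeat {
    cand <- which(eff > cur_e)
    if (length(cand) == 0) {
      break
    }
    slope <- (cost[cand] - cur_c) / (eff[cand] - cur_e)
    best <- cand[slope == min(slope)]
    best <- best[eff[best] == max(eff[best])]
    best <- best[order(nm[best])][1]
    out <- c(out, nm[best])
    cur_e <- eff[best]
    cur_c <- cost[best]
  }
  out
}

# random strategy sets with deliberate ties to exercise tie-breaking
random_strategies <- function(n, tie_prone = TRUE) {
  effect <- if (tie_prone) {
    sample(0:8, n, replace = TRUE)
  } else {
    round(stats::runif(n, 0, 10), 3)
  }
  cost <- if (tie_prone) {
    sample(0:12, n, replace = TRUE)
  } else {
    round(stats::runif(n, 0, 15), 3)
  }
  tibble::tibble(
    name = paste0("s", sprintf("%02d", seq_len(n))),
    effect = effect,
    cost = cost
  )
}

# closed-form uptake change, written out independently of the package
oracle_delta_pp <- function(p0, beta) {
  odds <- p0 / (1 - p0) * exp(beta)
  100 * (odds / (1 + odds) - p0)
}

# tiny deterministic choice dataset: one binary attribute, explicit rows
manual_choice_data <- function(chosen_first = TRUE, n_tasks = 30) {
  tibble::tibble(
    respondent = rep(seq_len(n_tasks), each = 2),
    task = rep(seq_len(n_tasks), each = 2),
    alternative = rep(1:2, n_tasks),
    x = rep(c(1L, 0L), n_tasks),
    chosen = rep(if (chosen_first) c(1L, 0L) else c(0L, 1L), n_tasks)
  )
}
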