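feature_columns <- function(data) {
  setdiff(names(data), c("respondent", "task", "alternative", "chosen"))
}

#' Generate a random choice-experiment design
#'
#' Builds choice tasks with `n_alternatives` hypothetical service profiles
#' each.  Every attribute of `coeffs` is assigned a level uniformly at random
#' per alternative (the reference level and each listed level are equally
#' likely), and tasks whose alternatives are all identical are rejected and
#' redrawn.  Dummy (reference) coding matches the coefficient table, so a
#' profile's utility is the sum of the coefficients of its switched-on
#' levels.  Random rather than D-optimal designs are used: they are ample for
#' parameter-recovery validation.
#'
#' @param coeffs Coefficient tibble ([coefficient_set()]).
#' @param n_respondents,n_tasks Number of respondents and tasks per
#'   respondent.
#' @param n_alternatives Alternatives per task (>= 2, default 2).
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return A long tibble with columns `respondent`, `task` (global id),
#'   `alternative`, and one 0/1 dummy column per coefficient row.  The
#'   attribute/level-to-column mapping is stored in the `"coding"` attribute.
#' @examples
#' coeffs <- load_dce_coefficients()
#' design <- generate_design(coeffs, n_respondents = 10, n_tasks = 4, seed = 1)
#' @export
generate_design <- function(coeffs, n_respondents, n_tasks,
                            n_alternatives = 2, seed) {
  coeffs <- coefficient_set(coeffs)
  if (missing(seed) || !is.numeric(seed)) {
    stop_input("an integer `seed` is required for design generation")
  }
  if (n_alternatives < 2) {
    stop_input("need at least 2 alternatives per task")
  }
  if (n_respondents < 1 || n_tasks < 1) {
    stop_input("`n_respondents` and `n_tasks` must be >= 1")
  }
  if (nrow(coeffs) < 1) {
    stop_design("cannot build distinct alternatives without any attribute levels")
  }
  coding <- dplyr::mutate(
    coeffs[c("attribute", "level")],
    column = make.unique(.data$attribute, sep = "_")
  )
  n_total <- n_respondents * n_tasks
  n_rows <- n_total * n_alternatives
  attrs <- split(seq_len(nrow(coding)), coding$attribute)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  draw_rows <- function(n) {
    # one column per dummy; attributes with m levels pick uniformly among
    # reference + m levels
    X <- matrix(0L, nrow = n, ncol = nrow(coding))
    for (ix in attrs) {
      pick <- sample.int(length(ix) + 1L, n, replace = TRUE) - 1L
      for (j in seq_along(ix)) {
        X[, ix[j]] <- as.integer(pick == j)
      }
    }
    X
  }
  X <- draw_rows(n_rows)
  task_id <- rep(seq_len(n_total), each = n_alternatives)
  for (iter in seq_len(1000)) {
    prof <- apply(X, 1, paste, collapse = "")
    distinct <- tapply(prof, task_id, function(p) length(unique(p)))
    bad <- which(distinct == 1)
    if (length(bad) == 0) {
      break
    }
    if (iter == 1000) {
      stop_design("could not draw tasks with distinct alternatives")
    }
    rows <- which(task_id %in% bad)
    X[rows, ] <- draw_rows(length(rows))
  }
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- coding$column
  out <- dplyr::bind_cols(
    tibble::tibble(
      respondent = rep(rep(seq_len(n_respondents), each = n_tasks),
                       each = n_alternatives),
      task = task_id,
      alternative = rep(seq_len(n_alternatives), times = n_total)
    ),
    out
  )
  attr(out, "coding") <- coding
  out
}

#' Simulate choices from a design
#'
#' Samples each task's chosen alternative from the conditional-logit
#' (softmax) probabilities implied by the design's dummy columns and the true
#' coefficients.
#'
#' @param design Output of [generate_design()].
#' @param coeffs The true coefficient tibble used generatively.
#' @param seed Integer seed for the choice draws.
#' @return `design` with a 0/1 `chosen` column (exactly one per task);
#'   attributes `true_coefficients` and `seed` record the simulation truth.
#' @export
simulate_choices <- function(design, coeffs, seed) {
  coeffs <- coefficient_set(coeffs)
  if (missing(seed) || !is.numeric(seed)) {
    stop_input("an integer `seed` is required for choice simulation")
  }
  feats <- feature_columns(design)
  if (length(feats) != nrow(coeffs)) {
    stop_input("design dummy columns do not match the coefficient table")
  }
  X <- as.matrix(design[feats])
  eta <- drop(X %*% coeffs$coefficient)
  n_alt <- length(unique(design$alternative))
  n_task <- nrow(design) / n_alt
  E <- matrix(eta, nrow = n_task, ncol = n_alt, byrow = TRUE)
  P <- exp(E - apply(E, 1, max))
  P <- P / rowSums(P)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  u <- stats::runif(n_task)
  cum <- t(apply(P, 1, cumsum))
  pick <- 1L + rowSums(cum < u)
  chosen <- integer(nrow(design))
  chosen[(seq_len(n_task) - 1L) * n_alt + pick] <- 1L
  out <- dplyr::mutate(design, chosen = chosen)
  attr(out, "coding") <- attr(design, "coding")
  attr(out, "true_coefficients") <- coeffs
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Conditional-logit log-likelihood
#'
#' `sum over tasks of [ beta'x_chosen - log sum_j exp(beta'x_j) ]`, the
#' likelihood of the observed choices under a conditional logit.  Concave in
#' `beta`, and invariant to adding a constant to all alternatives of a task.
#'
#' @param beta Coefficient vector, one entry per design dummy column.
#' @param data A simulated (or observed) choice dataset in the long format of
#'   [simulate_choices()].
#' @return The log-likelihood (scalar).
#' @examples
#' coeffs <- load_dce_coefficients()
#' d <- simulate_choices(generate_design(coeffs, 5, 2, seed = 1), coeffs, seed = 2)
#' conditional_logit_loglik(rep(0, 6), d)  # -10 * log(2)
#' @export
conditional_logit_loglik <- function(beta, data) {
  feats <- feature_columns(data)
  if (length(beta) != length(feats)) {
    stop_input(paste0(
      "coefficient vector has length ", length(beta),
      " but the design has ", length(feats), " dummy columns"
    ))
  }
  if (!"chosen" %in% names(data)) {
    stop_input("`data` must have a `chosen` column")
  }
  X <- as.matrix(data[feats])
  eta <- drop(X %*% beta)
  gi <- match(data$task, unique(data$task))
  m <- as.vector(tapply(eta, gi, max))
  lse <- m + log(drop(rowsum(exp(eta - m[gi]), gi)))
  sum(eta[data$chosen == 1]) - sum(lse)
}

#' Fit a conditional logit by maximum likelihood
#'
#' Newton-Raphson on the analytic gradient and observed information; standard
#' errors are the square roots of the diagonal of the inverse observed
#' information at the optimum.  Convergence requires the gradient max-norm to
#' fall below `tol`.
#'
#' @param data A long-format choice dataset ([simulate_choices()] or
#'   equivalent) with `task`, `chosen` and dummy columns.
#' @param tol Gradient max-norm at convergence (default 1e-6).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return An object of class `clogit_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`), `loglik`, `vcov`,
#'   `n_tasks`, `iterations`, `converged`.  Supports [tidy()], [glance()]
#'   and `print()`.
#' @export
fit_conditional_logit <- function(data, tol = 1e-6, max_iter = 50) {
  feats <- feature_columns(data)
  if (length(feats) == 0) {
    stop_input("no dummy columns to estimate")
  }
  if (!"chosen" %in% names(data)) {
    stop_input("`data` must have a `chosen` column")
  }
  X <- as.matrix(data[feats])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- feats[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_estimation(paste0(
      "design matrix is rank deficient; collinear column(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  gi <- match(data$task, unique(data$task))
  y <- as.numeric(data$chosen)
  k <- ncol(X)
  beta <- rep(0, k)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    m <- as.vector(tapply(eta, gi, max))
    e <- exp(eta - m[gi])
    s <- drop(rowsum(e, gi))
    p <- e / s[gi]
    grad <- drop(crossprod(X, y - p))
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    B <- rowsum(p * X, gi)                    # E[x | task]
    info <- crossprod(X, p * X) - crossprod(B) # observed information
    step <- tryCatch(
      solve(info, grad),
      error = function(e) {
        stop_estimation(
          "observed information is singular; the likelihood may be flat or separated"
        )
      }
    )
    beta <- beta + step
    if (any(!is.finite(beta)) || max(abs(beta)) > 15) {
      stop_estimation(paste0(
        "estimates diverged (|beta| > 15); the data are likely perfectly ",
        "separated"
      ))
    }
  }
  if (!converged) {
    stop_estimation(paste0(
      "Newton-Raphson did not converge in ", max_iter,
      " iterations (gradient max-norm ", formatC(max(abs(grad)), digits = 3),
      ")"
    ))
  }
  eta <- drop(X %*% beta)
  m <- as.vector(tapply(eta, gi, max))
  e <- exp(eta - m[gi])
  s <- drop(rowsum(e, gi))
  p <- e / s[gi]
  B <- rowsum(p * X, gi)
  info <- crossprod(X, p * X) - crossprod(B)
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  z <- beta / se
  structure(
    list(
      coefficients = tibble::tibble(
        term = feats,
        estimate = unname(beta),
        std_error = unname(se),
        statistic = unname(z),
        p_value = 2 * stats::pnorm(-abs(z))
      ),
      loglik = conditional_logit_loglik(beta, data),
      vcov = vcov,
      n_tasks = length(unique(data$task)),
      iterations = iter,
      converged = converged
    ),
    class = "clogit_fit"
  )
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat("Conditional logit fit:", x$n_tasks, "tasks, log-likelihood",
      formatC(x$loglik, format = "f", digits = 2), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @describeIn fit_conditional_logit Coefficient table in broom layout.
#' @param x,object A `clogit_fit` object.
#' @param ... Unused.
#' @export
tidy.clogit_fit <- function(x, ...) {
  x$coefficients
}

#' @describeIn fit_conditional_logit One-row model summary.
#' @export
glance.clogit_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_tasks = x$n_tasks,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a choice experiment at known coefficients and refits
#' the conditional logit, summarising bias, the empirical spread of the
#' estimates, the average model standard error, and 95% confidence-interval
#' coverage per coefficient.  A master seed fans out into independent design
#' and simulation streams so any single replicate is reproducible in
#' isolation.
#'
#' @param coeffs True coefficient tibble.
#' @param n_reps Number of simulate-and-fit replicates (>= 2).
#' @param n_respondents,n_tasks,n_alternatives Design dimensions per
#'   replicate (defaults 805 respondents x 8 tasks x 2 alternatives, the
#'   scale of the survey the packaged coefficients come from).
#' @param seed Master seed.
#' @param conf_level Nominal CI level for the coverage column (default 0.95).
#' @return A tibble with one row per coefficient: `term`, `true`,
#'   `mean_estimate`, `bias`, `empirical_se`, `mean_se`, `coverage`.
#' @export
recovery_experiment <- function(coeffs, n_reps, n_respondents = 805,
                                n_tasks = 8, n_alternatives = 2, seed,
                                conf_level = 0.95) {
  coeffs <- coefficient_set(coeffs)
  if (n_reps < 2) {
    stop_input("`n_reps` must be >= 2")
  }
  if (missing(seed) || !is.numeric(seed)) {
    stop_input("an integer master `seed` is required")
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  design_seeds <- sample.int(.Machine$integer.max, n_reps)
  sim_seeds <- sample.int(.Machine$integer.max, n_reps)
  z <- qnorm(1 - (1 - conf_level) / 2)
  fits <- purrr::map(seq_len(n_reps), function(r) {
    design <- generate_design(
      coeffs, n_respondents, n_tasks, n_alternatives, seed = design_seeds[r]
    )
    dat <- simulate_choices(design, coeffs, seed = sim_seeds[r])
    fit_conditional_logit(dat)$coefficients
  })
  est <- dplyr::bind_rows(fits, .id = "rep")
  truth <- tibble::tibble(
    term = make.unique(coeffs$attribute, sep = "_"),
    true = coeffs$coefficient
  )
  est <- dplyr::left_join(est, truth, by = "term")
  dplyr::summarise(
    dplyr::group_by(est, .data$term),
    true = .data$true[1],
    mean_estimate = mean(.data$estimate),
    bias = mean(.data$estimate - .data$true),
    empirical_se = stats::sd(.data$estimate),
    mean_se = mean(.data$std_error),
    coverage = mean(abs(.data$estimate - .data$true) <= z * .data$std_error),
    .groups = "drop"
  )
}
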