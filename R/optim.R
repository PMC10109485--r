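#' Reliability of an interval constraint against an allowable value
#'
#' The deterministic transform of the interval constraint `S <= b`: the
#' possibility degree
#' \deqn{pr(S \le b) = \frac{b - S^L}{2 S^\omega}}
#' of the response interval `S` lying below the scalar allowable `b`.  The
#' interval constraint at reliability level \eqn{\lambda} is satisfied iff
#' this value is at least \eqn{\lambda}; algebraically, a value of 1 is
#' equivalent to `S.upper == b`, and values above 1 mean the whole interval
#' sits below the allowable.
#'
#' @param S_interval Response [interval()] of the constraint function.
#' @param b Allowable value (same units).
#' @return Single numeric reliability value.
#' @examples
#' reliability_constraint(interval(40.99, 45.50), 45.5)  # 1.0
#' @export
reliability_constraint <- function(S_interval, b) rpdi(S_interval, b)

#' Define the interval optimization problem for the operating parameters
#'
#' The nonlinear interval program: choose the midpoints of the controllable
#' operating-parameter intervals (burning temperature `t1`, stick diameter
#' `d`, stick distance `h`; radii fixed by the manufacturing/operating
#' tolerances) to maximize the thermal-penetration objective `HPM` while
#' the skin-surface-temperature interval `ST` satisfies the reliability
#' constraint `pr(ST <= b) >= lambda`.  Skin moisture `omega_c` is an
#' uncontrolled uncertainty: its interval is fixed, not designed.
#'
#' Midpoint bounds shrink the design domain by each radius so every
#' candidate interval stays inside the domain.
#'
#' @param model Surrogate ([rbnn()] with responses `HPM`, `ST`) or named
#'   list of indicator functions (see [analyze_uncertainty()]).
#' @param lambda Required reliability level (> 0).
#' @param allowable Allowable skin surface temperature `b`, deg C.
#' @param domain Outer design [box()] over all four parameters.
#' @param radii Named radii of all four parameter intervals.
#' @param design_vars Names of the controllable parameters (midpoints to
#'   optimize); the rest are uncontrolled with midpoint fixed at the domain
#'   centre.
#' @param objective Which scalar of the HPM interval to maximize:
#'   its midpoint (`"midpoint"`, the default), lower bound (`"lower"`,
#'   robust) or upper bound (`"upper"`, optimistic).
#' @return A list of class `"interval_problem"`.
#' @export
interval_problem <- function(model, lambda = 1.0, allowable = 45.5,
                             domain = design_domain(),
                             radii = reference_constants()$radii,
                             design_vars = c("t1", "d", "h"),
                             objective = c("midpoint", "lower", "upper")) {
  stopifnot(lambda > 0, all(design_vars %in% names(domain)),
            setequal(names(radii), names(domain)))
  objective <- match.arg(objective)
  radii <- radii[names(domain)]
  mid_lo <- box_lower(domain) + radii
  mid_hi <- box_upper(domain) - radii
  if (any(mid_lo[design_vars] > mid_hi[design_vars]))
    stop("interval radii exceed the design-domain half-width: the feasible ",
         "midpoint box is empty", call. = FALSE)
  uncontrolled <- setdiff(names(domain), design_vars)
  structure(list(
    model = model, fns = indicator_functions(model),
    lambda = lambda, allowable = allowable,
    domain = domain, radii = radii,
    design_vars = design_vars, uncontrolled = uncontrolled,
    mid_lower = mid_lo[design_vars], mid_upper = mid_hi[design_vars],
    fixed_mid = box_mid(domain)[uncontrolled],
    objective = objective
  ), class = "interval_problem")
}

## uncertainty box of one candidate midpoint vector (design vars only)
candidate_box <- function(problem, midpoints) {
  mids <- c(setNames(midpoints, problem$design_vars), problem$fixed_mid)
  mids <- mids[names(problem$domain)]
  uncertainty_box(mids, problem$radii)
}

## evaluate a candidate: response intervals, objective scalar, reliability
evaluate_candidate <- function(problem, midpoints, method = "multistart",
                               n_starts = 8L, seed = 1L, refine = "all") {
  bx <- candidate_box(problem, midpoints)
  H <- response_interval(problem$fns$HPM$f, bx, method = method,
                         n_starts = n_starts, seed = seed,
                         gr = problem$fns$HPM$gr, refine = refine)
  S <- response_interval(problem$fns$ST$f, bx, method = method,
                         n_starts = n_starts, seed = seed,
                         gr = problem$fns$ST$gr, refine = refine)
  obj <- switch(problem$objective,
                midpoint = int_mid(H), lower = int_lower(H),
                upper = int_upper(H))
  pr <- reliability_constraint(S, problem$allowable)
  list(box = bx, HPM = H, ST = S, objective = obj, reliability = pr,
       violation = max(0, problem$lambda - pr))
}

#' Solve the interval optimization by nested global/local search
#'
#' The nested solver for the reliability-constrained interval program: a
#' real-coded genetic algorithm searches the midpoints of the controllable
#' parameter intervals (outer level); every fitness evaluation builds the
#' candidate's uncertainty box (midpoints +/- fixed radii plus the
#' uncontrolled moisture interval) and computes the HPM and ST response
#' intervals by bounded multistart local optimization (inner level).  The
#' constraint `pr(ST <= b) >= lambda` is handled by an adaptive penalty on
#' the fitness, so populations that start infeasible still converge.  The
#' returned best candidate is re-evaluated with the tensor-grid oracle as
#' an independent feasibility certificate.
#'
#' @param problem An [interval_problem()].
#' @param pop,generations GA population size and generation count.
#' @param pc,pm Crossover and (per-gene) mutation probabilities.
#' @param eta_c,eta_m SBX crossover / polynomial mutation distribution
#'   indices.
#' @param inner_starts Random interior starts of the inner response-interval
#'   optimization (the box centre and corners are always used).
#' @param seed Integer seed; identical seeds reproduce identical results.
#' @param verify_grid_n Tensor-grid resolution of the final verification.
#' @return A list of class `"interval_optim"`: optimal `midpoints`, `HPM`
#'   and `ST` intervals, `objective`, achieved `reliability`, `feasible`
#'   flag, the grid-verified `reliability_verified`, and solver
#'   `diagnostics`.
#' @examples
#' ps <- make_pseudo_simulator(seed = 1)
#' fit <- rbnn(latin_hypercube(40, seed = 1),
#'             evaluate_responses(latin_hypercube(40, seed = 1),
#'                                simulator_pseudo(ps))[, c("HPM", "ST")])
#' \donttest{
#' sol <- interval_optim(interval_problem(fit, lambda = 1),
#'                       pop = 20, generations = 30, seed = 42)
#' sol
#' }
#' @export
interval_optim <- function(problem, pop = 40L, generations = 100L,
                           pc = 0.9, pm = NULL, eta_c = 15, eta_m = 20,
                           inner_starts = 2L, seed = 42L,
                           verify_grid_n = 9L) {
  stopifnot(inherits(problem, "interval_problem"))
  nvar <- length(problem$design_vars)
  if (is.null(pm)) pm <- 1 / nvar
  n_eval <- 0L
  fitness_of <- function(mid) {
    n_eval <<- n_eval + 1L
    ev <- evaluate_candidate(problem, mid, n_starts = inner_starts,
                             seed = seed, refine = "best")
    penalty_scale <- 1000 * max(1, abs(ev$objective))
    list(fitness = ev$objective - penalty_scale * ev$violation, eval = ev)
  }
  ga <- ga_maximize(fitness_of, lower = problem$mid_lower,
                    upper = problem$mid_upper, pop = pop,
                    generations = generations, pc = pc, pm = pm,
                    eta_c = eta_c, eta_m = eta_m, seed = seed)
  best <- ga$best_eval
  feasible <- best$violation <= 1e-9
  verify <- evaluate_candidate(problem, ga$best_x, method = "grid",
                               seed = seed)
  structure(list(
    midpoints = setNames(ga$best_x, problem$design_vars),
    HPM = best$HPM, ST = best$ST,
    objective = best$objective,
    reliability = best$reliability,
    feasible = feasible,
    ST_verified = verify$ST,
    HPM_verified = verify$HPM,
    reliability_verified = verify$reliability,
    lambda = problem$lambda,
    problem = problem,
    diagnostics = list(generations = generations, pop = pop,
                       evaluations = n_eval, seed = seed,
                       best_fitness = ga$best_fitness,
                       history = ga$history)
  ), class = "interval_optim")
}

#' @export
print.interval_optim <- function(x, ...) {
  cat(sprintf("interval optimization at lambda = %.2f (%s)\n", x$lambda,
              if (x$feasible) "feasible" else "INFEASIBLE"))
  cat("  optimal midpoints:",
      paste(sprintf("%s = %.3f", names(x$midpoints), x$midpoints),
            collapse = ", "), "\n")
  cat("  HPM:", format(x$HPM), "degC\n")
  cat("  ST :", format(x$ST), "degC\n")
  cat(sprintf("  reliability %.4f (grid-verified %.4f), allowable %.1f degC\n",
              x$reliability, x$reliability_verified,
              x$problem$allowable))
  invisible(x)
}

#' @export
summary.interval_optim <- function(object, ...) {
  cat("nested interval optimization result\n")
  print(object)
  d <- object$diagnostics
  cat(sprintf("  solver: %d generations x %d population, %d inner evaluations, seed %d\n",
              d$generations, d$pop, d$evaluations, d$seed))
  invisible(object)
}

#' Sweep the reliability level of the interval optimization
#'
#' Solves the interval program once per reliability level, sharing the
#' surrogate, with per-level seeds derived deterministically from the base
#' seed.  Raising \eqn{\lambda} tightens the surface-temperature constraint
#' and therefore trades thermal penetration for reliability: the optimal
#' objective is non-increasing in \eqn{\lambda}, and for \eqn{\lambda \ge 1}
#' the optimized ST interval lies entirely below the allowable value.
#'
#' @param problem An [interval_problem()] (its `lambda` is overridden per
#'   row).
#' @param lambdas Numeric vector of reliability levels.
#' @param seed Base seed; level i uses `seed + i - 1`.
#' @param ... Passed to [interval_optim()].
#' @return A data frame of class `"rpdi_sweep"` with one row per level
#'   (`lambda`, `ST_lo`, `ST_hi`, `HPM_lo`, `HPM_hi`, `objective`,
#'   `reliability`, `feasible`); full results in `attr(, "results")`.
#' @export
rpdi_sweep <- function(problem, lambdas = c(0.8, 0.9, 1.0, 1.1),
                       seed = 42L, ...) {
  stopifnot(length(lambdas) >= 1)
  results <- lapply(seq_along(lambdas), function(i) {
    p <- problem
    p$lambda <- lambdas[i]
    interval_optim(p, seed = seed + i - 1L, ...)
  })
  out <- data.frame(
    lambda = lambdas,
    ST_lo = vapply(results, function(r) int_lower(r$ST), numeric(1)),
    ST_hi = vapply(results, function(r) int_upper(r$ST), numeric(1)),
    HPM_lo = vapply(results, function(r) int_lower(r$HPM), numeric(1)),
    HPM_hi = vapply(results, function(r) int_upper(r$HPM), numeric(1)),
    objective = vapply(results, `[[`, numeric(1), "objective"),
    reliability = vapply(results, `[[`, numeric(1), "reliability"),
    feasible = vapply(results, `[[`, logical(1), "feasible")
  )
  attr(out, "results") <- results
  class(out) <- c("rpdi_sweep", "data.frame")
  out
}

#' @export
print.rpdi_sweep <- function(x, digits = 4, ...) {
  cat("optimal solutions under different reliability levels\n")
  y <- data.frame(
    lambda = x$lambda,
    ST = sprintf("[%.*f, %.*f]", 2, x$ST_lo, 2, x$ST_hi),
    HPM = sprintf("[%.*f, %.*f]", 2, x$HPM_lo, 2, x$HPM_hi),
    reliability = round(x$reliability, digits),
    feasible = x$feasible
  )
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
plot.rpdi_sweep <- function(x, ...) {
  graphics::plot(range(x$lambda), range(c(x$ST_lo, x$ST_hi)), type = "n",
                 xlab = "reliability level lambda",
                 ylab = "optimized ST interval (degC)",
                 main = "Reliability level sweep", ...)
  graphics::arrows(x$lambda, x$ST_lo, x$lambda, x$ST_hi,
                   angle = 90, code = 3, length = 0.05)
  graphics::abline(h = 45.5, lty = 2)
  invisible(x)
}

## ---------------------------------------------------------------------
## real-coded genetic algorithm: tournament selection, SBX crossover,
## polynomial mutation, elitism.  Maximizes fitness_of(x)$fitness.
ga_maximize <- function(fitness_of, lower, upper, pop = 40L,
                        generations = 100L, pc = 0.9, pm = 0.25,
                        eta_c = 15, eta_m = 20, seed = 42L) {
  nvar <- length(lower)
  span <- upper - lower
  with_seed(seed, {
    P <- matrix(runif(pop * nvar, lower, upper), ncol = nvar, byrow = TRUE)
    evals <- apply(P, 1, fitness_of)
    fit <- vapply(evals, `[[`, numeric(1), "fitness")
    best_i <- which.max(fit)
    best_x <- P[best_i, ]; best_f <- fit[best_i]; best_e <- evals[[best_i]]$eval
    history <- numeric(generations)
    for (gen in seq_len(generations)) {
      # binary tournament
      parents <- matrix(NA_real_, pop, nvar)
      for (s in seq_len(pop)) {
        a <- sample.int(pop, 2)
        parents[s, ] <- P[if (fit[a[1]] >= fit[a[2]]) a[1] else a[2], ]
      }
      # SBX crossover on consecutive pairs
      Q <- parents
      for (s in seq(1, pop - 1, by = 2)) {
        if (runif(1) < pc) {
          cr <- sbx_pair(parents[s, ], parents[s + 1, ], lower, upper, eta_c)
          Q[s, ] <- cr[[1]]; Q[s + 1, ] <- cr[[2]]
        }
      }
      # polynomial mutation
      for (s in seq_len(pop))
        Q[s, ] <- poly_mutate(Q[s, ], lower, upper, pm, eta_m)
      evals_q <- apply(Q, 1, fitness_of)
      fit_q <- vapply(evals_q, `[[`, numeric(1), "fitness")
      # elitism: keep the best-so-far in slot of the worst child
      worst <- which.min(fit_q)
      Q[worst, ] <- best_x
      fit_q[worst] <- best_f
      evals_q[[worst]] <- list(fitness = best_f, eval = best_e)
      P <- Q; fit <- fit_q; evals <- evals_q
      gi <- which.max(fit)
      if (fit[gi] > best_f) {
        best_f <- fit[gi]; best_x <- P[gi, ]; best_e <- evals[[gi]]$eval
      }
      history[gen] <- best_f
    }
    list(best_x = best_x, best_fitness = best_f, best_eval = best_e,
         history = history)
  })
}

sbx_pair <- function(p1, p2, lower, upper, eta) {
  u <- runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

poly_mutate <- function(x, lower, upper, pm, eta) {
  hit <- runif(length(x)) < pm
  if (!any(hit)) return(x)
  u <- runif(sum(hit))
  span <- (upper - lower)[hit]
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  x[hit] <- pmin(pmax(x[hit] + delta * span, lower[hit]), upper[hit])
  x
}
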