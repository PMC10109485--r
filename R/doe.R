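#' Latin hypercube design over the operating-parameter domain
#'
#' Draws an n-point Latin hypercube design over a [box()] of parameter
#' ranges: each column has exactly one point in each of the n
#' equal-probability strata of its dimension.  With `optimize = TRUE`
#' (the default) `candidates` random Latin designs are generated and the
#' one with the largest minimum pairwise distance in the unit cube is kept
#' (the maximin space-filling criterion).  Identical seed, domain and
#' settings reproduce the identical table.
#'
#' @param n Number of design points (>= 2).
#' @param domain A [box()]; defaults to the standard four-parameter
#'   operating domain of [design_domain()].
#' @param seed Integer seed controlling the sampling.
#' @param optimize If `TRUE`, keep the maximin-best of `candidates` designs.
#' @param candidates Number of random Latin designs scored under maximin.
#' @return A data frame (class `"design_table"`) with one named column per
#'   parameter; the generating domain in `attr(, "domain")`.
#' @examples
#' d <- latin_hypercube(10, seed = 1)
#' summary(d$t1)
#' @export
latin_hypercube <- function(n, domain = design_domain(), seed = 1L,
                            optimize = TRUE, candidates = 100L) {
  if (!inherits(domain, "box")) stop("domain must be a 'box'", call. = FALSE)
  if (n < 2) stop("a Latin hypercube design needs n >= 2 points", call. = FALSE)
  dim <- length(domain)
  best <- NULL; best_score <- -Inf
  with_seed(seed, {
    n_cand <- if (optimize) candidates else 1L
    for (i in seq_len(n_cand)) {
      u <- lhs::randomLHS(n, dim)
      score <- min(dist(u))
      if (score > best_score) { best <- u; best_score <- score }
    }
  })
  lo <- box_lower(domain); hi <- box_upper(domain)
  out <- as.data.frame(sweep(sweep(best, 2, hi - lo, `*`), 2, lo, `+`))
  names(out) <- names(domain)
  attr(out, "domain") <- domain
  attr(out, "maximin_distance") <- best_score
  class(out) <- c("design_table", "data.frame")
  out
}

#' The standard operating-parameter design domain
#'
#' The outer box of the four uncertain operating parameters: moxa burning
#' temperature `t1` in \[600, 650\] deg C, stick diameter `d` in \[12, 18\]
#' mm, stick-to-skin distance `h` in \[25, 35\] mm and skin moisture content
#' `omega_c` in \[29, 52\] percent.
#'
#' @return A [box()] with elements `t1`, `d`, `h`, `omega_c`.
#' @export
design_domain <- function() reference_constants()$design_domain

## run body with a locally-set RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Evaluate indicator responses over a design table
#'
#' Batch driver for the design of experiments: calls the simulator once per
#' design row and collects the two indicator responses.  Failures are
#' recorded per row (response columns set to `NA`, message kept) rather
#' than silently dropped; more than `max_failure_rate` of failing rows
#' aborts the run.
#'
#' @param design A [latin_hypercube()] table (or any data frame with
#'   columns `t1`, `d`, `h`, `omega_c`).
#' @param simulator A function `f(t1, d, h, omega_c)` returning a numeric
#'   vector with named elements `HPM` and `ST` (see [simulator_pde()] and
#'   [simulator_pseudo()]).
#' @param max_failure_rate Abort threshold for the fraction of failed rows.
#' @return A data frame (class `"response_table"`) with columns `HPM`,
#'   `ST`, `ok`, `message`, row-aligned with `design`.
#' @export
evaluate_responses <- function(design, simulator, max_failure_rate = 0.1) {
  stopifnot(is.data.frame(design),
            all(c("t1", "d", "h", "omega_c") %in% names(design)))
  n <- nrow(design)
  HPM <- ST <- rep(NA_real_, n)
  ok <- rep(TRUE, n)
  msg <- rep("", n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      simulator(design$t1[i], design$d[i], design$h[i], design$omega_c[i]),
      error = function(e) e)
    if (inherits(res, "error") || anyNA(res) || any(!is.finite(res))) {
      ok[i] <- FALSE
      msg[i] <- if (inherits(res, "error")) conditionMessage(res)
                else "non-finite response"
    } else {
      HPM[i] <- res[["HPM"]]; ST[i] <- res[["ST"]]
    }
  }
  if (mean(!ok) > max_failure_rate)
    stop(sum(!ok), " of ", n, " simulator evaluations failed (over ",
         100 * max_failure_rate, "% budget); first failure: ",
         msg[!ok][1], call. = FALSE)
  out <- data.frame(HPM = HPM, ST = ST, ok = ok, message = msg)
  class(out) <- c("response_table", "data.frame")
  out
}

#' Surrogate fit quality metrics
#'
#' Computes the error measures used to accept a surrogate: per-sample
#' relative error \eqn{RE_i = (y_i - \hat y_i)/y_i} (reported as its
#' min/max range in percent), the sum of squared errors
#' \eqn{SSE = \sum (y_i - \hat y_i)^2}, total sum of squares
#' \eqn{SST = \sum (y_i - \bar y)^2}, coefficient of determination
#' \eqn{R^2 = 1 - SSE/SST} and \eqn{RMSE = \sqrt{SSE/k}}.
#'
#' @param y Observed (simulated) responses.
#' @param y_hat Surrogate predictions, same length.
#' @return A list of class `"fit_metrics"`: `RE` (length-2, percent),
#'   `RMSE`, `R2`, `SSE`, `SST`, `k`.
#' @examples
#' fit_metrics(c(1, 2, 3), c(1, 2, 4))  # SSE 1, SST 2, R2 0.5
#' @export
fit_metrics <- function(y, y_hat) {
  stopifnot(is.numeric(y), is.numeric(y_hat), length(y) == length(y_hat),
            length(y) >= 2)
  k <- length(y)
  err <- y - y_hat
  nz <- y != 0
  if (!all(nz))
    warning(sum(!nz), " zero observed value(s) skipped in the relative ",
            "error range", call. = FALSE)
  re <- 100 * err[nz] / y[nz]
  SSE <- sum(err^2)
  SST <- sum((y - mean(y))^2)
  R2 <- if (SST > 0) 1 - SSE / SST else NA_real_
  if (SST == 0)
    warning("constant observations: R^2 undefined (SST = 0)", call. = FALSE)
  structure(list(
    RE = if (length(re)) range(re) else c(NA_real_, NA_real_),
    RMSE = sqrt(SSE / k), R2 = R2, SSE = SSE, SST = SST, k = k
  ), class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("fit metrics (k = %d): RE [%.3f%%, %.3f%%], RMSE %.4g, R2 %s\n",
              x$k, x$RE[1], x$RE[2], x$RMSE,
              if (is.na(x$R2)) "undefined" else sprintf("%.4f", x$R2)))
  invisible(x)
}
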