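#' Closed-form pseudo-simulator of the moxibustion indicators
#'
#' Builds a cheap, smooth, closed-form stand-in for the bioheat solver,
#' used to exercise the design-of-experiments, surrogate and optimization
#' stages quickly.  Only the qualitative structure is contractual, and it
#' is enforced at construction by finite-difference sign checks on a grid:
#' \itemize{
#'   \item ST increases with burning temperature `t1` and stick diameter
#'     `d`, decreases with stick distance `h`;
#'   \item HPM increases with `t1`, `d` and moisture `omega_c`, decreases
#'     with `h`;
#'   \item over the standard operating domain, outputs stay within
#'     physiologic bands: ST in \[38, 62\] deg C, HPM in \[37, 45\] deg C.
#' }
#' Coefficients are drawn per seed from narrow ranges chosen so the
#' invariants hold; a draw violating them is rejected and resampled.
#'
#' @param seed Integer seed selecting the coefficient set.
#' @param noise Amplitude (deg C, standard deviation) of additive Gaussian
#'   observation noise; 0 gives an exactly deterministic function.
#' @return A list of class `"pseudo_simulator"` with elements `coef` and
#'   `fn` (`function(t1, d, h, omega_c) -> c(HPM, ST)`).
#' @examples
#' ps <- make_pseudo_simulator(seed = 1)
#' ps$fn(625, 15, 30, 40.5)
#' @export
make_pseudo_simulator <- function(seed = 1L, noise = 0) {
  stopifnot(noise >= 0)
  domain <- design_domain()
  lo <- box_lower(domain); hi <- box_upper(domain)
  draw <- function() list(
    # ST = base + A1*v1 + A2*u2 - A3*u3 - A4*u4 + A5*u1*u2
    A = c(base = 44, runif(1, 4, 5), runif(1, 3, 4), runif(1, 3.5, 4.5),
          runif(1, 0.5, 1), runif(1, 1, 2)),
    # HPM = base + B1*u1 + B2*u2 - B3*u3 + B4*u4
    B = c(base = 40, runif(1, 1, 1.5), runif(1, 1, 1.5), runif(1, 2, 2.5),
          runif(1, 0.8, 1.2))
  )
  make_fn <- function(cf, local_noise) {
    function(t1, d, h, omega_c) {
      u <- (c(t1, d, h, omega_c) - lo) / (hi - lo)
      v1 <- u[1] * (1.2 - 0.2 * u[1])      # mildly saturating in t1
      A <- cf$A; B <- cf$B
      ST <- A[1] + A[2] * v1 + A[3] * u[2] - A[4] * u[3] - A[5] * u[4] +
        A[6] * u[1] * u[2]
      HPM <- B[1] + B[2] * u[1] + B[3] * u[2] - B[4] * u[3] + B[5] * u[4]
      if (local_noise > 0) {
        ST <- ST + rnorm(1, 0, local_noise)
        HPM <- HPM + rnorm(1, 0, local_noise)
      }
      c(HPM = unname(HPM), ST = unname(ST))
    }
  }
  with_seed(seed, {
    for (attempt in 1:100) {
      cf <- draw()
      fn0 <- make_fn(cf, 0)
      if (pseudo_sim_valid(fn0, domain)) break
      cf <- NULL
    }
    if (is.null(cf))
      stop("could not draw a coefficient set satisfying the monotonicity ",
           "and band invariants", call. = FALSE)
    structure(list(coef = cf, noise = noise, seed = seed,
                   fn = make_fn(cf, noise)),
              class = "pseudo_simulator")
  })
}

## finite-difference sign and band checks on a coarse grid
pseudo_sim_valid <- function(fn, domain) {
  lo <- box_lower(domain); hi <- box_upper(domain)
  axes <- Map(function(a, b) seq(a, b, length.out = 4), lo, hi)
  grid <- as.matrix(do.call(expand.grid, axes))
  eps <- (hi - lo) * 1e-4
  sign_need <- rbind(ST = c(1, 1, -1, NA), HPM = c(1, 1, -1, 1))
  for (g in seq_len(nrow(grid))) {
    x <- grid[g, ]
    v <- fn(x[1], x[2], x[3], x[4])
    if (v[["ST"]] < 38 || v[["ST"]] > 62) return(FALSE)
    if (v[["HPM"]] < 37 || v[["HPM"]] > 45) return(FALSE)
    for (p in 1:4) {
      xp <- x; xp[p] <- min(xp[p] + eps[p], hi[p])
      xm <- x; xm[p] <- max(xm[p] - eps[p], lo[p])
      dv <- fn(xp[1], xp[2], xp[3], xp[4]) - fn(xm[1], xm[2], xm[3], xm[4])
      for (resp in c("ST", "HPM")) {
        want <- sign_need[resp, p]
        if (!is.na(want) && sign(dv[[resp]]) != want) return(FALSE)
      }
    }
  }
  TRUE
}

#' @export
print.pseudo_simulator <- function(x, ...) {
  cat(sprintf("pseudo-simulator (seed %d, noise %.3g degC)\n", x$seed, x$noise))
  invisible(x)
}

#' @rdname simulator_pde
#' @param ps A [make_pseudo_simulator()] object.
#' @export
simulator_pseudo <- function(ps) {
  stopifnot(inherits(ps, "pseudo_simulator"))
  ps$fn
}

#' Toy interval-optimization problems with closed-form optima
#'
#' Self-validating fixtures for the optimization and interval-propagation
#' layers: each toy records its closed-form optimum (or interval bounds),
#' and the stored optimum is re-validated against the closed form on
#' construction.
#'
#' \describe{
#'   \item{`linear`}{1-D, `H(x) = S(x) = x`, allowable 10, radius 1.  At
#'     reliability level 1 the constraint `(10 - (x - 1))/2 >= 1` gives the
#'     optimal midpoint 9; at level 1.5 it gives 8.}
#'   \item{`quadratic`}{1-D, `S(x) = (x - c)^2` with an interior constraint
#'     extremum; its response interval over any box has a piecewise closed
#'     form (`0` inside when the vertex is interior).}
#'   \item{`separable2d`}{2-D separable `f(x, y) = g(x) + h(y)`: interval
#'     bounds are the sums of the per-dimension bounds.}
#' }
#'
#' @return Named list of toy problems; each element is a list whose fields
#'   depend on the toy (see the source and the examples).
#' @examples
#' toys <- make_toy_problems()
#' toys$linear$optimal_midpoint     # 9
#' @export
make_toy_problems <- function() {
  linear <- list(
    name = "linear",
    H = function(x) x, S = function(x) x,
    allowable = 10, radius = 1, lambda = 1,
    domain = box(x = interval(0, 20)),
    optimal_midpoint = 9,
    optimal_S = interval(8, 10),
    # closed-form optimal midpoint at any reliability level lam:
    optimum_at = function(lam) 10 + 1 - 2 * lam
  )
  stopifnot(isTRUE(all.equal(linear$optimum_at(1), linear$optimal_midpoint)),
            isTRUE(all.equal(
              rpdi(interval_cr(linear$optimal_midpoint, linear$radius),
                   linear$allowable), linear$lambda)))

  quadratic <- list(
    name = "quadratic",
    vertex = 0.3,
    S = function(x) (x - 0.3)^2,
    # closed-form response interval of S over [l, u]
    interval_of = function(l, u) {
      c0 <- 0.3
      vals <- c((l - c0)^2, (u - c0)^2)
      if (l <= c0 && c0 <= u) interval(0, max(vals))
      else interval(min(vals), max(vals))
    }
  )
  stopifnot(isTRUE(all.equal(
    unclass(quadratic$interval_of(0, 1))[["upper"]], 0.49)))

  separable2d <- list(
    name = "separable2d",
    f = function(x) (x[1] - 0.25)^2 + sin(pi * x[2]),
    # per-dimension closed-form bounds over [l1,u1] x [l2,u2]
    interval_of = function(l1, u1, l2, u2) {
      g <- quadratic$interval_of          # same quadratic form, vertex 0.3
      gx <- {
        vals <- c((l1 - 0.25)^2, (u1 - 0.25)^2)
        if (l1 <= 0.25 && 0.25 <= u1) interval(0, max(vals))
        else interval(min(vals), max(vals))
      }
      ss <- sin(pi * seq(l2, u2, length.out = 2001))
      hy <- interval(min(ss), max(ss))    # dense-scan bound for sin branch
      if (l2 <= 0.5 && 0.5 <= u2) hy <- interval(int_lower(hy), 1)
      interval(int_lower(gx) + int_lower(hy), int_upper(gx) + int_upper(hy))
    }
  )

  list(linear = linear, quadratic = quadratic, separable2d = separable2d)
}
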