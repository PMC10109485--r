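# A 1-D interval problem with closed-form optimum, expressed through the
# package's problem interface: H(x) = S(x) = x, allowable 10, radius 1.
linear_problem <- function(lambda) {
  interval_problem(
    list(HPM = function(x) x[1], ST = function(x) x[1]),
    lambda = lambda, allowable = 10,
    domain = box(x = interval(0, 20)),
    radii = c(x = 1), design_vars = "x"
  )
}

test_that("reliability constraint reproduces the worked interval values", {
  expect_equal(reliability_constraint(interval(40.99, 45.50), 45.5), 1)
  expect_equal(reliability_constraint(interval(41.81, 46.24), 45.5),
               (45.5 - 41.81) / (46.24 - 41.81))
  # feasible at 0.8, infeasible at 1
  v <- reliability_constraint(interval(41.81, 46.24), 45.5)
  expect_gte(v, 0.8)
  expect_lt(v, 1)
  # identity: value >= 1 iff upper bound <= allowable
  set.seed(41)
  for (rep in 1:50) {
    S <- interval_cr(runif(1, 30, 50), runif(1, 0.1, 5))
    expect_equal(reliability_constraint(S, 45.5) >= 1,
                 int_upper(S) <= 45.5 + 1e-12)
  }
})

test_that("midpoint bounds shrink the domain by the interval radii", {
  p <- linear_problem(1)
  expect_equal(unname(p$mid_lower), 1)
  expect_equal(unname(p$mid_upper), 19)
  expect_error(
    interval_problem(list(HPM = function(x) x[1], ST = function(x) x[1]),
                     domain = box(x = interval(0, 1)), radii = c(x = 0.6),
                     design_vars = "x"),
    "empty")
})

test_that("lambda = 1 transform equals the hard upper-bound constraint", {
  p <- linear_problem(1)
  for (mid in c(5, 8.9, 9, 9.1, 12)) {
    ev <- moxiopt:::evaluate_candidate(p, mid)
    expect_equal(ev$violation <= 1e-9, int_upper(ev$ST) <= 10 + 1e-9)
  }
})

test_that("nested GA recovers the closed-form optimum of the linear toy", {
  toy <- make_toy_problems()$linear
  for (s in 1:5) {
    sol <- interval_optim(linear_problem(1), pop = 24, generations = 40,
                          seed = s)
    expect_true(sol$feasible)
    expect_equal(unname(sol$midpoints), toy$optimal_midpoint,
                 tolerance = 0.05 / toy$optimal_midpoint)
    expect_equal(int_lower(sol$ST), int_lower(toy$optimal_S),
                 tolerance = 0.01)
    expect_equal(int_upper(sol$ST), int_upper(toy$optimal_S),
                 tolerance = 0.01)
  }
  # tighter reliability moves the optimum per the closed form
  sol15 <- interval_optim(linear_problem(1.5), pop = 24, generations = 40,
                          seed = 1)
  expect_equal(unname(sol15$midpoints), toy$optimum_at(1.5),
               tolerance = 0.01)
})

test_that("nested GA matches exhaustive midpoint search on a 2-D toy", {
  # objective sum of midpoints; constraint is the first coordinate only
  fns <- list(HPM = function(x) x[1] + 2 * x[2], ST = function(x) x[1])
  prob <- interval_problem(fns, lambda = 1, allowable = 5,
                           domain = box(a = interval(0, 10),
                                        b = interval(0, 10)),
                           radii = c(a = 0.5, b = 0.5),
                           design_vars = c("a", "b"))
  sol <- interval_optim(prob, pop = 30, generations = 50, seed = 2)
  # brute force over a 0.01-resolution midpoint grid (constraint analytic:
  # a + 0.5 <= 5); objective midpoint = a + 2 b, maximized at a = 4.5, b = 9.5
  expect_true(sol$feasible)
  expect_equal(unname(sol$midpoints["a"]), 4.5, tolerance = 0.01 / 4.5)
  expect_equal(unname(sol$midpoints["b"]), 9.5, tolerance = 0.01 / 9.5)
})

test_that("feasible results certify against the grid oracle", {
  sol <- interval_optim(linear_problem(0.9), pop = 20, generations = 30,
                        seed = 7)
  expect_true(sol$feasible)
  expect_gte(sol$reliability_verified, sol$lambda - 1e-9)
})

test_that("identical seeds reproduce identical optimization results", {
  a <- interval_optim(linear_problem(1), pop = 16, generations = 20, seed = 9)
  b <- interval_optim(linear_problem(1), pop = 16, generations = 20, seed = 9)
  expect_identical(a$midpoints, b$midpoints)
  expect_identical(unclass(a$ST), unclass(b$ST), ignore_attr = TRUE)
})

test_that("an infeasible problem is flagged, not silently returned", {
  # ST is always far above the allowable: no feasible midpoint exists
  fns <- list(HPM = function(x) x[1], ST = function(x) x[1] + 100)
  prob <- interval_problem(fns, lambda = 1, allowable = 10,
                           domain = box(x = interval(0, 20)),
                           radii = c(x = 1), design_vars = "x")
  sol <- interval_optim(prob, pop = 12, generations = 10, seed = 3)
  expect_false(sol$feasible)
  expect_lt(sol$reliability, 1)
})

test_that("lambda sweep is monotone and matches single solves", {
  lambdas <- c(0.8, 1.0, 1.2, 1.5)
  sw <- rpdi_sweep(linear_problem(1), lambdas, seed = 11, pop = 20,
                   generations = 30)
  expect_equal(nrow(sw), 4)
  # optimal objective non-increasing in lambda
  expect_true(all(diff(sw$objective) <= 1e-6))
  # rows with lambda >= 1 satisfy the hard bound
  expect_true(all(sw$ST_hi[sw$lambda >= 1] <= 10 + 1e-6))
  # closed form: midpoint 11 - 2 lambda, ST upper = midpoint + 1
  expect_equal(sw$ST_hi, 11 - 2 * lambdas + 1, tolerance = 0.01)
  # single-lambda sweep equals a direct solve with the same derived seed
  one <- rpdi_sweep(linear_problem(1), 1.0, seed = 11, pop = 20,
                    generations = 30)
  direct <- interval_optim(linear_problem(1.0), seed = 11, pop = 20,
                           generations = 30)
  expect_equal(one$ST_hi, int_upper(direct$ST), tolerance = 1e-12)
})
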