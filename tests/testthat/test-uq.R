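test_that("response intervals of monotone functions hit the endpoints", {
  b <- box(x = interval(0, 1))
  ri <- response_interval(function(x) 3 * x + 1, b)
  expect_equal(int_lower(ri), 1, tolerance = 1e-8)
  expect_equal(int_upper(ri), 4, tolerance = 1e-8)
})

test_that("interior extrema are found despite corner starts", {
  b <- box(x = interval(0, 1))
  ri <- response_interval(function(x) (x - 0.5)^2, b)
  expect_equal(int_lower(ri), 0, tolerance = 1e-8)
  expect_equal(int_upper(ri), 0.25, tolerance = 1e-8)
  # grid oracle agrees
  rg <- response_interval(function(x) (x - 0.5)^2, b, method = "grid",
                          grid_n = 101)
  expect_equal(int_lower(rg), 0, tolerance = 1e-4)
  expect_equal(int_upper(rg), 0.25, tolerance = 1e-8)
})

test_that("quadratic toy matches its piecewise closed form on many boxes", {
  toy <- make_toy_problems()$quadratic
  set.seed(21)
  for (rep in 1:25) {
    l <- runif(1, -1, 1); u <- l + runif(1, 0.1, 1.5)
    b <- box(x = interval(l, u))
    ri <- response_interval(toy$S, b)
    expected <- toy$interval_of(l, u)
    expect_equal(int_lower(ri), int_lower(expected), tolerance = 1e-6)
    expect_equal(int_upper(ri), int_upper(expected), tolerance = 1e-6)
  }
})

test_that("2-D separable toy bounds equal the sum of per-axis bounds", {
  toy <- make_toy_problems()$separable2d
  cases <- list(c(0, 1, 0, 1), c(0.4, 0.9, 0.2, 0.7), c(-0.5, 0.1, 0.8, 1.6))
  for (cs in cases) {
    b <- box(x = interval(cs[1], cs[2]), y = interval(cs[3], cs[4]))
    ri <- response_interval(toy$f, b)
    expected <- toy$interval_of(cs[1], cs[2], cs[3], cs[4])
    expect_equal(int_lower(ri), int_lower(expected), tolerance = 1e-4)
    expect_equal(int_upper(ri), int_upper(expected), tolerance = 1e-4)
  }
})

test_that("4-D synthetic response with algebraic extrema is bounded exactly", {
  # separable with known extrema: sum of shifted squares minus a linear term
  f <- function(x) (x[1] - 0.3)^2 + 2 * (x[2] - 0.7)^2 + 0.5 * x[3] - x[4]
  b <- box(a = interval(0, 1), b = interval(0, 1),
           c = interval(0, 1), d = interval(0, 1))
  ri <- response_interval(f, b, seed = 4)
  expect_equal(int_lower(ri), 0 + 0 + 0 - 1, tolerance = 1e-4)
  expect_equal(int_upper(ri), 0.49 + 2 * 0.49 + 0.5 - 0, tolerance = 1e-4)
})

test_that("multistart bounds are never strictly inside the grid oracle's", {
  set.seed(31)
  fns <- list(
    function(x) sum(sin(3 * x)) + 0.2 * sum(x^2),
    function(x) prod(1 + x) - sum(x),
    function(x) exp(-sum((x - 0.4)^2)) + 0.1 * x[1]
  )
  b <- box(x = interval(0, 1), y = interval(0, 1))
  for (f in fns) {
    ms <- response_interval(f, b, seed = 8)
    gr <- response_interval(f, b, method = "grid", grid_n = 9)
    expect_lte(int_lower(ms), int_lower(gr) + 1e-6)
    expect_gte(int_upper(ms), int_upper(gr) - 1e-6)
  }
})

test_that("screened refinement agrees with full refinement on smooth boxes", {
  fn <- function(x) 40 + 2 * x[1] - 1.5 * x[2] + 0.3 * x[1] * x[2]
  b <- box(x = interval(0.2, 0.6), y = interval(0.1, 0.4))
  full <- response_interval(fn, b, refine = "all")
  fast <- response_interval(fn, b, refine = "best")
  expect_equal(unclass(full), unclass(fast), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("enlarging the box never shrinks the response interval", {
  f <- function(x) sin(2 * x[1]) + cos(3 * x[2]) + x[1] * x[2]
  widths <- seq(0.2, 1, by = 0.2)
  prev <- NULL
  for (w in widths) {
    b <- box(x = interval_cr(0.5, w / 2), y = interval_cr(0.5, w / 2))
    ri <- response_interval(f, b, seed = 2)
    if (!is.null(prev)) {
      expect_lte(int_lower(ri), int_lower(prev) + 1e-9)
      expect_gte(int_upper(ri), int_upper(prev) - 1e-9)
    }
    prev <- ri
  }
})

test_that("degenerate boxes collapse to a point evaluation", {
  b <- box(x = interval(0.4, 0.4), y = interval(0.7, 0.7))
  f <- function(x) x[1]^2 + x[2]
  ri <- response_interval(f, b)
  expect_equal(int_rad(ri), 0)
  expect_equal(int_mid(ri), 0.4^2 + 0.7)
})

test_that("uncertainty analysis flags reliable and unreliable conditions", {
  # surrogate-free functional interface: ST spans the allowable or not
  low <- list(HPM = function(x) 38 + x[1], ST = function(x) 40 + 2 * x[1])
  b <- box(x = interval(0, 1))
  rep_low <- analyze_uncertainty(low, box = b, allowable = 45.5)
  expect_true(rep_low$reliable)
  expect_gte(rep_low$rpdi, 1)

  hot <- list(HPM = function(x) 38 + x[1], ST = function(x) 44 + 3 * x[1])
  rep_hot <- analyze_uncertainty(hot, box = b, allowable = 45.5)
  expect_false(rep_hot$reliable)
  expect_gt(rep_hot$rpdi, 0)
  expect_lt(rep_hot$rpdi, 1)
  expect_output(print(rep_hot), "UNRELIABLE")
})
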