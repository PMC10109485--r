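test_that("interval constructors round-trip bounds, midpoint and radius", {
  i <- interval(600, 650)
  expect_equal(int_mid(i), 625)
  expect_equal(int_rad(i), 25)
  expect_equal(interval_cr(625, 25), i)

  expect_equal(int_rad(interval(5, 5)), 0)
  expect_equal(int_mid(interval(0, 2)), 1)
  expect_equal(int_rad(interval(0, 2)), 1)
  expect_equal(interval_cr(0, 0), interval(0, 0))

  # round-trip identity to floating tolerance on random intervals
  set.seed(7)
  for (rep in 1:50) {
    lo <- runif(1, -1e3, 1e3); hi <- lo + runif(1, 0, 1e3)
    i <- interval(lo, hi)
    j <- interval_cr(int_mid(i), int_rad(i))
    expect_equal(int_lower(j), lo, tolerance = 1e-12)
    expect_equal(int_upper(j), hi, tolerance = 1e-12)
  }
})

test_that("invalid interval arguments are rejected with clear diagnostics", {
  expect_error(interval(650, 600), "reversed bounds")
  expect_error(interval_cr(0, -1), "negative radius")
  expect_error(box(), "at least one interval")
  expect_error(box(interval(0, 1), 3), "must be 'interval'")
})

test_that("closed membership uses an absolute tolerance", {
  i <- interval(0, 1)
  expect_true(int_contains(1, i))
  expect_true(int_contains(1 + 1e-10, i))
  expect_false(int_contains(1 + 1e-6, i))
})

test_that("rpdi reproduces worked interval comparisons", {
  expect_equal(rpdi(interval(2, 4), interval(6, 8)), 1.5)
  expect_equal(rpdi(interval(0, 1), interval(0, 1)), 0.5)
  expect_equal(rpdi(interval(0, 2), interval(1, 5)), 5 / 6)
  expect_equal(rpdi(interval(1, 5), interval(0, 2)), 1 / 6)
})

test_that("degenerate rpdi reduces to (b - lower) / (2 radius)", {
  expect_equal(rpdi_degenerate(interval(0, 2), 2), 1)
  expect_equal(rpdi_degenerate(interval(0, 2), 1), 0.5)
  expect_equal(rpdi_degenerate(interval(40.99, 45.50), 45.5), 1)
  # zero-radius conventions: limit reading, not an error
  expect_identical(rpdi_degenerate(interval(1, 1), 2), Inf)
  expect_identical(rpdi_degenerate(interval(3, 3), 2), -Inf)
  expect_identical(rpdi_degenerate(interval(2, 2), 2), 0.5)
})

test_that("rpdi satisfies its defining features on random intervals", {
  set.seed(11)
  for (rep in 1:200) {
    A <- interval_cr(runif(1, -10, 10), runif(1, 0.01, 5))
    B <- interval_cr(runif(1, -10, 10), runif(1, 0.01, 5))
    # complementarity
    expect_equal(rpdi(A, B) + rpdi(B, A), 1, tolerance = 1e-12)
    # certainty when disjoint
    if (int_upper(A) <= int_lower(B)) expect_gte(rpdi(A, B), 1)
    if (int_upper(B) <= int_lower(A)) expect_lte(rpdi(A, B), 0)
  }
})

test_that("degenerate rpdi is monotone in b and in the interval position", {
  A <- interval(2, 6)
  b <- seq(0, 10, by = 0.5)
  vals <- vapply(b, function(bb) rpdi_degenerate(A, bb), numeric(1))
  expect_true(all(diff(vals) > 0))
  # shifting the interval up at fixed radius lowers the possibility degree
  shifts <- seq(-2, 2, by = 0.25)
  v2 <- vapply(shifts, function(s)
    rpdi_degenerate(interval(2 + s, 6 + s), 5), numeric(1))
  expect_true(all(diff(v2) < 0))
})

test_that("boxes expose vectorized bounds and validate members", {
  b <- box(t1 = interval(600, 650), h = interval(25, 35))
  expect_equal(box_mid(b), c(t1 = 625, h = 30))
  expect_equal(box_rad(b), c(t1 = 25, h = 5))
  expect_equal(box_lower(b), c(t1 = 600, h = 25))
  expect_equal(box_upper(b), c(t1 = 650, h = 35))
})

test_that("uncertainty_box enforces design-domain containment", {
  dom <- box(x = interval(0, 10))
  expect_silent(uncertainty_box(c(x = 5), c(x = 1), dom))
  expect_error(uncertainty_box(c(x = 9.8), c(x = 1), dom),
               "leaves the design domain")
})
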