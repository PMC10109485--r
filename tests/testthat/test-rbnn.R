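# shared small training set on a smooth known function
quad4 <- function(X) rowSums(as.matrix(X)^2)
unit4 <- box(a = interval(0, 1), b = interval(0, 1),
             c = interval(0, 1), d = interval(0, 1))

test_that("zero-regularization network interpolates its training data", {
  d <- latin_hypercube(30, unit4, seed = 1)
  fit <- rbnn(d, quad4(d))
  expect_lt(max(abs(residuals(fit))), 1e-8)
  pred <- predict(fit, d)
  expect_equal(as.numeric(pred), quad4(d), tolerance = 1e-8)
})

test_that("network generalizes a smooth function on held-out points", {
  d <- latin_hypercube(50, unit4, seed = 1)
  fit <- rbnn(d, quad4(d))
  v <- latin_hypercube(20, unit4, seed = 2)
  m <- fit_metrics(quad4(v), as.numeric(predict(fit, v)))
  expect_gte(m$R2, 0.99)
})

test_that("doubling the training set does not hurt held-out accuracy", {
  v <- latin_hypercube(20, unit4, seed = 99)
  r2 <- vapply(c(25, 50), function(n) {
    d <- latin_hypercube(n, unit4, seed = 4)
    fit <- rbnn(d, quad4(d))
    fit_metrics(quad4(v), as.numeric(predict(fit, v)))$R2
  }, numeric(1))
  expect_gte(r2[2], r2[1] - 0.01)
})

test_that("constant responses give constant predictions", {
  d <- latin_hypercube(15, unit4, seed = 3)
  fit <- rbnn(d, rep(5, 15))
  v <- latin_hypercube(10, unit4, seed = 4)
  expect_lt(max(abs(predict(fit, v) - 5)), 1e-8)
})

test_that("predictions are invariant to training-row order", {
  d <- latin_hypercube(25, unit4, seed = 6)
  y <- quad4(d)
  fit1 <- rbnn(d, y)
  perm <- sample(25)
  fit2 <- rbnn(d[perm, ], y[perm])
  v <- latin_hypercube(8, unit4, seed = 7)
  expect_equal(predict(fit1, v), predict(fit2, v), tolerance = 1e-8)
})

test_that("multi-response fits carry named responses through prediction", {
  d <- latin_hypercube(30, unit4, seed = 8)
  Y <- data.frame(HPM = quad4(d), ST = 2 * quad4(d) + 1)
  fit <- rbnn(d, Y)
  expect_equal(fit$response_names, c("HPM", "ST"))
  p <- predict(fit, d)
  expect_equal(p[, "ST"], 2 * p[, "HPM"] + 1, tolerance = 1e-6)
})

test_that("degenerate training inputs are rejected", {
  d <- data.frame(a = c(0, 0, 1), b = c(0, 0, 1))
  expect_error(rbnn(d, c(1, 2, 3)), "duplicate")
  expect_error(rbnn(data.frame(a = c(0, 1), b = c(1, 0)), c(1, 2),
                    width = 0.5), "at least dim")
})

test_that("extrapolation triggers a warning but still predicts", {
  d <- latin_hypercube(20, unit4, seed = 9)
  fit <- rbnn(d, quad4(d))
  far <- data.frame(a = 2, b = 0.5, c = 0.5, d = 0.5)
  expect_warning(p <- predict(fit, far), "extrapolat")
  expect_true(is.finite(p))
})

test_that("rbnn_fun gradient matches finite differences", {
  d <- latin_hypercube(30, unit4, seed = 10)
  fit <- rbnn(d, quad4(d))
  fn <- rbnn_fun(fit)
  x0 <- c(a = 0.3, b = 0.6, c = 0.2, d = 0.8)
  g <- fn$gr(x0)
  eps <- 1e-6
  g_fd <- vapply(seq_along(x0), function(i) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    (fn$f(xp) - fn$f(xm)) / (2 * eps)
  }, numeric(1))
  expect_equal(unname(g), g_fd, tolerance = 1e-5)
  expect_equal(fn$f(x0), as.numeric(predict(fit, t(x0))), tolerance = 1e-10)
})

test_that("JSON serialization round-trips predictions exactly", {
  d <- latin_hypercube(25, unit4, seed = 11)
  Y <- data.frame(HPM = quad4(d), ST = sqrt(quad4(d)))
  fit <- rbnn(d, Y)
  path <- withr::local_tempfile(fileext = ".json")
  rbnn_to_json(fit, path)
  back <- rbnn_from_json(path)
  v <- latin_hypercube(12, unit4, seed = 12)
  expect_equal(predict(back, v), predict(fit, v), tolerance = 1e-12)
  expect_identical(back$response_names, fit$response_names)
})

test_that("model methods expose standard accessors", {
  d <- latin_hypercube(20, unit4, seed = 13)
  fit <- rbnn(d, quad4(d))
  expect_equal(dim(coef(fit)), c(20L, 1L))
  expect_equal(as.numeric(fitted(fit) + residuals(fit)), quad4(d),
               tolerance = 1e-10)
  expect_output(print(fit), "Gaussian RBF network")
  expect_output(print(summary(fit)), "training")
})
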