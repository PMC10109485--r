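# Coarse grids keep these runs fast; solver accuracy itself is covered by
# the analytic-conduction, explicit-oracle and grid-convergence checks.
coarse <- function(duration = 600, ...) {
  suppressWarnings(simulation_config(dr = 1, dz = 1, dt = 2,
                                     duration = duration, ...))
}

test_that("disabled source at equilibrium keeps the field at 37 degC", {
  cfg <- coarse(duration = 120, q_m = 0)
  cfg$source$emissivity <- 0
  field <- run_simulation(cfg)
  expect_lt(max(abs(field$values - 37)), 1e-9)
  expect_lt(max(abs(field$surface_series - 37)), 1e-9)
  expect_lt(max(abs(field$probe_series - 37)), 1e-9)
})

test_that("initial snapshot equals the initial temperature everywhere", {
  cfg <- coarse(duration = 60, initial_temp = 33.5)
  field <- run_simulation(cfg)
  expect_equal(field$times[1], 0)
  expect_true(all(field$values[1, , ] == 33.5))
})

test_that("constant-flux heating matches the semi-infinite conduction law", {
  q0 <- 500
  cfg <- conduction_only_config(q0, dz = 0.5, dt = 0.5, duration = 60)
  field <- run_simulation(cfg)
  for (t_chk in c(20, 40, 60)) {
    i <- which(field$series_times == t_chk)
    analytic <- semi_infinite_surface(t_chk, q0, k = 0.25, rho = 1100,
                                      c = 3000, T0 = 37)
    rise_sim <- field$surface_series[i] - 37
    rise_ana <- analytic - 37
    expect_equal(rise_sim, rise_ana, tolerance = 0.02)
  }
})

test_that("implicit solver agrees with a brute-force explicit integrator", {
  cfg <- suppressWarnings(simulation_config(dr = 2, dz = 1, dt = 0.25,
                                            duration = 120, save_every = 120))
  field <- run_simulation(cfg)
  oracle <- explicit_euler_solve(cfg)
  final <- field$values[dim(field$values)[1], , ]   # (z, r)
  expect_lt(max(abs(final - t(oracle$T))), 0.05)
})

test_that("indicators respond monotonically to the operating parameters", {
  base <- coarse()
  sf_t1 <- suppressWarnings(single_factor_analysis(base, "t1", c(600, 625, 650)))
  expect_true(all(diff(sf_t1$ST) > 0))
  expect_true(all(diff(sf_t1$HPM) > 0))
  sf_d <- suppressWarnings(single_factor_analysis(base, "d", c(12, 15, 18)))
  expect_true(all(diff(sf_d$ST) > 0))
  expect_true(all(diff(sf_d$HPM) > 0))
  sf_h <- suppressWarnings(single_factor_analysis(base, "h", c(25, 30, 35)))
  expect_true(all(diff(sf_h$ST) < 0))
  expect_true(all(diff(sf_h$HPM) < 0))
})

test_that("drier skin heats at the surface faster than moist skin", {
  base <- coarse(duration = 120)
  rate <- vapply(c(29, 40, 52), function(w) {
    f <- run_simulation(suppressWarnings(with_parameters(base, omega_c = w)))
    keep <- f$series_times <= 60
    stats::coef(stats::lm(f$surface_series[keep] ~ f$series_times[keep]))[2]
  }, numeric(1))
  expect_true(all(diff(rate) < 0))
})

test_that("heating-only runs respect the maximum principle and ordering", {
  cfg <- coarse(duration = 300)
  field <- run_simulation(cfg)
  expect_gte(min(field$values), min(cfg$initial_temp, cfg$core_temp))
  ind <- extract_indicators(field)
  expect_gte(ind$ST, ind$HPM)
  expect_gte(ind$HPM, cfg$initial_temp)
})

test_that("stronger perfusion damps the surface temperature", {
  st <- vapply(c(1e-3, 3e-3, 6e-3), function(w) {
    extract_indicators(run_simulation(coarse(duration = 300,
                                             omega_b = w)))$ST
  }, numeric(1))
  expect_true(all(diff(st) < 0))
})

test_that("indicator extraction reads synthetic fields exactly", {
  z <- seq(0, 10, by = 0.5); r <- seq(0.5, 20, by = 0.5)
  vals <- array(37, dim = c(2, length(z), length(r)))
  f_uniform <- temperature_field(r, z, c(0, 10), vals)
  ind <- extract_indicators(f_uniform)
  expect_equal(ind$ST, 37)
  expect_equal(ind$HPM, 37)

  # linear-in-depth field: 37 + z degC per mm, probe at 5 mm reads 42
  vals2 <- vals
  for (j in seq_along(z)) vals2[, j, ] <- 37 + z[j]
  f_linear <- temperature_field(r, z, c(0, 10), vals2)
  ind2 <- extract_indicators(f_linear)
  expect_equal(ind2$HPM, 42)
  expect_equal(ind2$ST, 37)
})

test_that("probe interpolation handles off-grid depths", {
  # probe at 5 mm between cell centres 4.75/5.25 interpolates linearly
  z <- c(4.75, 5.25)
  vals <- array(0, dim = c(1, 2, 1))
  vals[1, , 1] <- c(40, 42)
  f <- temperature_field(r = 1, z = z, times = 0, vals)
  expect_equal(max(f$probe_series), 41)
})

test_that("single-factor analysis validates its arguments", {
  base <- coarse(duration = 60)
  expect_error(single_factor_analysis(base, "bogus", c(1, 2)),
               "unknown parameter")
  expect_error(suppressWarnings(single_factor_analysis(base, "t1", 600)))
})

test_that("with_parameters preserves numerics and swaps operating point", {
  base <- coarse(duration = 240)
  v <- suppressWarnings(with_parameters(base, t1 = 640, omega_c = 33))
  expect_equal(v$t1, 640)
  expect_equal(v$omega_c, 33)
  expect_equal(v$dt, base$dt)
  expect_equal(v$duration, base$duration)
  expect_equal(v$source$h, base$source$h)
  # moisture propagates into the skin layer conductivity
  expect_equal(v$layers[[1]]$k, skin_properties_from_moisture(0.33)$k)
})

test_that("configuration rejects fraction-looking moisture and bad probe", {
  expect_error(simulation_config(omega_c = 0.4), "percent")
  expect_error(simulation_config(probe_depth = 30), "inside")
})
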