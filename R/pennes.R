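#' Run the axisymmetric transient Pennes bioheat simulation
#'
#' Solves the Pennes bioheat equation
#' \deqn{\rho c \frac{\partial T}{\partial t} = \nabla\cdot(k \nabla T)
#'   + \omega_b \rho_b C_b (T_b - T) + q_m}
#' on a cell-centred axisymmetric (r, z) finite-volume grid covering the
#' three tissue layers, with the net radiative flux from the moxa tip as the
#' top boundary condition (free convection is neglected: the tip is the
#' dominant exchange), a fixed core temperature at the bottom, and zero flux
#' on the axis and the lateral wall.  Time integration is backward Euler;
#' the constant symmetric system matrix is factorized once (sparse
#' Cholesky) and reused every step.  The nonlinear T^4 surface term is
#' handled by a per-step fixed-point iteration on the reconstructed surface
#' temperature (tolerance `config$surface_fixed_point_tol`).
#'
#' The skin surface temperature at radial offset r is reconstructed from
#' the first cell row as \eqn{T_s = T_{c} + q\,\Delta z / (2k)} (exact for
#' the cell-centred flux boundary), so the reported surface series refers to
#' z = 0, not to the first cell centre.
#'
#' @param config A [simulation_config()].
#' @return An object of class `"temperature_field"` with elements:
#'   `r`, `z` (cell-centre coordinates, mm), `times` (snapshot times, s),
#'   `values` (array `length(times) x length(z) x length(r)`, deg C),
#'   `series_times`, `surface_series`, `probe_series` (on-axis per-step
#'   series), `fixed_point_iterations`, and the `config`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(dr = 2, dz = 1, dt = 5, duration = 300)
#' field <- run_simulation(cfg)
#' extract_indicators(field)
#' }
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- build_grid(config)
  sys <- assemble_system(config, g)
  ch <- Matrix::Cholesky(sys$A, LDL = FALSE)

  nsteps <- ceiling(config$duration / config$dt)
  times_all <- seq(0, by = config$dt, length.out = nsteps + 1)
  save_stride <- max(1L, round(config$save_every / config$dt))
  snap_idx <- unique(c(seq(1L, nsteps + 1L, by = save_stride), nsteps + 1L))

  Tvec <- rep(config$initial_temp, g$n)
  surface_series <- probe_series <- numeric(nsteps + 1)
  snaps <- array(NA_real_, dim = c(length(snap_idx), g$Nz, g$Nr))
  snap_ptr <- 1L

  top_idx <- g$idx(seq_len(g$Nr), 1L)         # first z row, all radii
  k_top <- g$k_cell[top_idx]
  dz_m <- config$dz / 1000
  probe_w <- probe_weights(g$z, config$probe_depth)

  surf_from <- function(Tv, q) Tv[top_idx] + q * dz_m / (2 * k_top)
  flux_at <- function(t, Ts) {
    if (!is.null(config$flux_override))
      return(config$flux_override(g$r, Ts, t))
    Ta <- moxa_temperature(t, config$source)
    radiative_surface_flux(g$r, Ts, Ta, config$source)
  }

  q0 <- flux_at(0, rep(config$initial_temp, g$Nr))
  surface_series[1] <- surf_from(Tvec, q0)[1]
  probe_series[1] <- sum(probe_w$w * Tvec[g$idx(1L, probe_w$j)])
  if (snap_idx[1] == 1L) {
    snaps[1, , ] <- t(matrix(Tvec, nrow = g$Nr))
    snap_ptr <- 2L
  }

  max_fp <- 0L
  base_rhs_const <- sys$rhs_const
  for (n in seq_len(nsteps)) {
    t_new <- times_all[n + 1]
    Ts <- surf_from(Tvec, flux_at(times_all[n], surf_from(Tvec, 0)))
    Tnew <- Tvec
    for (it in seq_len(25L)) {
      q <- flux_at(t_new, Ts)
      rhs <- base_rhs_const + sys$mass_dt * Tvec
      rhs[top_idx] <- rhs[top_idx] + q * g$area_top
      Tnew <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
      Ts_new <- surf_from(Tnew, q)
      delta <- max(abs(Ts_new - Ts))
      Ts <- Ts_new
      if (delta < config$surface_fixed_point_tol) break
    }
    if (it == 25L && delta >= config$surface_fixed_point_tol)
      warning("surface fixed point not converged at t = ", t_new,
              " s (residual ", signif(delta, 3), " degC)", call. = FALSE)
    max_fp <- max(max_fp, it)
    if (anyNA(Tnew) || any(!is.finite(Tnew)))
      stop("non-finite temperature at t = ", t_new,
           " s; refine the grid or time step", call. = FALSE)
    Tvec <- Tnew
    surface_series[n + 1] <- Ts[1]
    probe_series[n + 1] <- sum(probe_w$w * Tvec[g$idx(1L, probe_w$j)])
    if (snap_ptr <= length(snap_idx) && snap_idx[snap_ptr] == n + 1L) {
      snaps[snap_ptr, , ] <- t(matrix(Tvec, nrow = g$Nr))
      snap_ptr <- snap_ptr + 1L
    }
  }

  structure(list(
    r = g$r, z = g$z, times = times_all[snap_idx], values = snaps,
    series_times = times_all,
    surface_series = surface_series, probe_series = probe_series,
    fixed_point_iterations = max_fp,
    config = config
  ), class = "temperature_field")
}

## cell-centred axisymmetric grid and per-cell properties
build_grid <- function(config) {
  dr <- config$dr; dz <- config$dz
  Nr <- max(2L, round(config$domain_radius / dr))
  Nz <- max(3L, round(config$depth / dz))
  r <- (seq_len(Nr) - 0.5) * dr          # mm
  z <- (seq_len(Nz) - 0.5) * dz          # mm
  th <- vapply(config$layers, `[[`, numeric(1), "thickness")
  layer_of <- findInterval(z, cumsum(th), left.open = TRUE) + 1L
  layer_of <- pmin(layer_of, length(config$layers))
  lay <- function(fld) vapply(config$layers, `[[`, numeric(1), fld)[layer_of]
  rho_c <- lay("rho") * lay("c")
  k_z <- lay("k")
  w_z <- lay("omega_b") * config$blood_density * config$blood_heat_capacity
  qm_z <- lay("q_m")

  idx <- function(i, j) i + (j - 1L) * Nr
  dr_m <- dr / 1000; dz_m <- dz / 1000
  r_m <- r / 1000
  vol <- 2 * pi * r_m * dr_m * dz_m       # per radial cell, any z row
  area_top <- 2 * pi * r_m * dr_m

  list(Nr = Nr, Nz = Nz, n = Nr * Nz, r = r, z = z, idx = idx,
       dr_m = dr_m, dz_m = dz_m, r_m = r_m, vol = vol, area_top = area_top,
       rho_c = rho_c, k_z = k_z, w_z = w_z, qm_z = qm_z,
       k_cell = rep(k_z, each = Nr),
       layer_of = layer_of)
}

## backward-Euler system: A = M/dt + K + W (+ bottom Dirichlet), constant
assemble_system <- function(config, g) {
  Nr <- g$Nr; Nz <- g$Nz; n <- g$n
  ii <- jj <- xx <- list(); p <- 0L
  add <- function(i, j, x) {
    p <<- p + 1L; ii[[p]] <<- i; jj[[p]] <<- j; xx[[p]] <<- x
  }
  diag_acc <- numeric(n)

  # radial conduction faces between (i, j) and (i+1, j)
  for (j in seq_len(Nz)) {
    i <- seq_len(Nr - 1L)
    kf <- 2 * g$k_z[j] * g$k_z[j] / (g$k_z[j] + g$k_z[j])  # uniform k per row
    r_face <- i * g$dr_m
    gcond <- kf * (2 * pi * r_face * g$dz_m) / g$dr_m
    a <- g$idx(i, j); b <- g$idx(i + 1L, j)
    add(a, b, -gcond); add(b, a, -gcond)
    diag_acc[a] <- diag_acc[a] + gcond
    diag_acc[b] <- diag_acc[b] + gcond
  }
  # vertical conduction faces between (i, j) and (i, j+1)
  for (j in seq_len(Nz - 1L)) {
    kf <- 2 * g$k_z[j] * g$k_z[j + 1L] / (g$k_z[j] + g$k_z[j + 1L])
    i <- seq_len(Nr)
    gcond <- kf * (2 * pi * g$r_m * g$dr_m) / g$dz_m
    a <- g$idx(i, j); b <- g$idx(i, j + 1L)
    add(a, b, -gcond); add(b, a, -gcond)
    diag_acc[a] <- diag_acc[a] + gcond
    diag_acc[b] <- diag_acc[b] + gcond
  }

  vol_all <- rep(g$vol, Nz)
  rho_c_all <- rep(g$rho_c, each = Nr)
  w_all <- rep(g$w_z, each = Nr)
  qm_all <- rep(g$qm_z, each = Nr)
  mass_dt <- rho_c_all * vol_all / config$dt
  perf <- w_all * vol_all

  # bottom Dirichlet via half-cell conductance
  bot <- g$idx(seq_len(Nr), Nz)
  g_bot <- g$k_z[Nz] * (2 * pi * g$r_m * g$dr_m) / (g$dz_m / 2)
  diag_acc[bot] <- diag_acc[bot] + g_bot

  diag_total <- diag_acc + mass_dt + perf
  add(seq_len(n), seq_len(n), diag_total)

  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  A <- Matrix::forceSymmetric(A, uplo = "U")

  rhs_const <- perf * config$core_temp + qm_all * vol_all
  rhs_const[bot] <- rhs_const[bot] + g_bot * config$core_temp

  list(A = A, mass_dt = mass_dt, rhs_const = rhs_const)
}

## linear interpolation weights for the probe depth between cell centres
probe_weights <- function(z, depth) {
  if (depth <= z[1]) return(list(j = c(1L, 1L), w = c(1, 0)))
  if (depth >= z[length(z)])
    return(list(j = rep(length(z), 2L), w = c(1, 0)))
  j1 <- max(which(z <= depth)); j2 <- j1 + 1L
  a <- (depth - z[j1]) / (z[j2] - z[j1])
  list(j = c(j1, j2), w = c(1 - a, a))
}

#' @export
print.temperature_field <- function(x, ...) {
  cat("temperature field:", length(x$r), "x", length(x$z),
      "cells (r x z),", length(x$series_times) - 1, "time steps,",
      length(x$times), "stored snapshots\n")
  cat(sprintf("  final on-axis surface %.2f degC, probe %.2f degC\n",
              tail(x$surface_series, 1), tail(x$probe_series, 1)))
  invisible(x)
}

#' @export
plot.temperature_field <- function(x, ...) {
  graphics::plot(x$series_times / 60, x$surface_series, type = "l",
                 xlab = "time (min)", ylab = "temperature (degC)",
                 main = "On-axis temperature history", ...)
  graphics::lines(x$series_times / 60, x$probe_series, lty = 2)
  graphics::legend("bottomright", c("surface (ST)", "5 mm probe (HPM)"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Construct a temperature field from raw values
#'
#' Builds a `"temperature_field"` object from explicit coordinate vectors
#' and a `(time, z, r)` value array, deriving the on-axis surface and probe
#' series from the array.  Used for synthetic fields in tests and for
#' re-loading exported fields; [run_simulation()] builds richer objects with
#' per-step series.
#'
#' @param r,z Cell coordinates, mm.
#' @param times Times, s.
#' @param values Array `length(times) x length(z) x length(r)`, deg C.
#' @param probe_depth Depth of the HPM probe, mm.
#' @return A `"temperature_field"`.
#' @export
temperature_field <- function(r, z, times, values, probe_depth = 5) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(times),
            dim(values)[2] == length(z),
            dim(values)[3] == length(r))
  pw <- probe_weights(z, probe_depth)
  structure(list(
    r = r, z = z, times = times, values = values,
    series_times = times,
    surface_series = values[, 1, 1],
    probe_series = pw$w[1] * values[, pw$j[1], 1] +
      pw$w[2] * values[, pw$j[2], 1],
    fixed_point_iterations = 0L,
    config = NULL
  ), class = "temperature_field")
}

#' Extract the moxibustion efficacy indicators from a simulated field
#'
#' ST (skin surface temperature) is the maximum over the treatment window
#' of the on-axis surface temperature; HPM (thermal penetration) is the
#' maximum of the on-axis temperature at the probe depth (5 mm by default).
#' The maxima are used because the histories plateau well before the end of
#' a standard treatment, so the maximum coincides with the late-time value
#' while remaining well defined for shorter runs.  Lateral and vertical
#' temperature profiles are read from the final stored snapshot.
#'
#' @param field A `"temperature_field"` from [run_simulation()] or
#'   [temperature_field()].
#' @param config Optional [simulation_config()]; defaults to the one stored
#'   in the field.
#' @return A list of class `"indicator_result"`: `ST`, `HPM` (deg C),
#'   `surface_series`, `depth_series`, `lateral_profile`,
#'   `vertical_profile`.
#' @export
extract_indicators <- function(field, config = NULL) {
  stopifnot(inherits(field, "temperature_field"))
  config <- config %||% field$config
  final <- dim(field$values)[1]
  structure(list(
    ST = max(field$surface_series),
    HPM = max(field$probe_series),
    surface_series = data.frame(t = field$series_times,
                                T = field$surface_series),
    depth_series = data.frame(t = field$series_times,
                              T = field$probe_series),
    lateral_profile = data.frame(r = field$r, T = field$values[final, 1, ]),
    vertical_profile = data.frame(z = field$z, T = field$values[final, , 1])
  ), class = "indicator_result")
}

#' @export
print.indicator_result <- function(x, ...) {
  cat(sprintf("indicators: ST %.2f degC (surface), HPM %.2f degC (5 mm probe)\n",
              x$ST, x$HPM))
  invisible(x)
}

#' Single-factor analysis of one operating parameter
#'
#' Varies one operating parameter across the given levels while the other
#' three stay at the base configuration's values, running one simulation
#' per level.  This isolates each parameter's effect on ST and HPM: burning
#' temperature and stick diameter raise both indicators, stick-to-skin
#' distance lowers them, and moisture content trades surface heating rate
#' against penetration.
#'
#' @param config Base [simulation_config()].
#' @param parameter One of `"t1"`, `"d"`, `"h"`, `"omega_c"`.
#' @param levels Numeric vector (length >= 2) of parameter values, in the
#'   parameter's table units (`omega_c` in percent).
#' @return A data frame of class `"single_factor"` with columns `level`,
#'   `ST`, `HPM`; per-level indicator objects in `attr(, "results")`.
#' @export
single_factor_analysis <- function(config, parameter, levels) {
  stopifnot(inherits(config, "simulation_config"))
  if (!parameter %in% c("t1", "d", "h", "omega_c"))
    stop("unknown parameter '", parameter,
         "': expected one of t1, d, h, omega_c", call. = FALSE)
  stopifnot(is.numeric(levels), length(levels) >= 2)
  results <- lapply(levels, function(v) {
    args <- setNames(list(v), parameter)
    cfg <- do.call(with_parameters, c(list(config), args))
    extract_indicators(run_simulation(cfg))
  })
  out <- data.frame(
    level = levels,
    ST = vapply(results, `[[`, numeric(1), "ST"),
    HPM = vapply(results, `[[`, numeric(1), "HPM")
  )
  attr(out, "parameter") <- parameter
  attr(out, "results") <- results
  class(out) <- c("single_factor", "data.frame")
  out
}

#' @export
print.single_factor <- function(x, ...) {
  cat("single-factor analysis of", attr(x, "parameter"), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Indicator evaluation at an operating point
#'
#' Convenience wrapper: build a configuration at the given operating
#' parameters (all numerical settings from `base`), run the simulation and
#' return the two indicators.
#'
#' @param t1,d,h,omega_c Operating parameters (`omega_c` percent).
#' @param base Base [simulation_config()] supplying grid and constants.
#' @return Named numeric vector `c(HPM = , ST = )`, deg C.
#' @export
simulate_indicators <- function(t1, d, h, omega_c,
                                base = simulation_config()) {
  ind <- extract_indicators(run_simulation(
    with_parameters(base, t1 = t1, d = d, h = h, omega_c = omega_c)))
  c(HPM = ind$HPM, ST = ind$ST)
}

#' Simulator function factories
#'
#' Both return a function `f(t1, d, h, omega_c) -> c(HPM, ST)` -- the
#' interface the design-of-experiments driver [evaluate_responses()]
#' expects.  `simulator_pde` wraps the finite-volume Pennes solver at the
#' resolution of its base configuration; `simulator_pseudo` wraps a
#' closed-form pseudo-simulator from [make_pseudo_simulator()].
#'
#' @param base A [simulation_config()] supplying grid and constants.
#' @return A function of the four operating parameters.
#' @export
simulator_pde <- function(base = simulation_config()) {
  force(base)
  function(t1, d, h, omega_c) simulate_indicators(t1, d, h, omega_c, base)
}
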