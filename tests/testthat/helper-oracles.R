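# Independent numerical oracles used across the suite.  These deliberately
# avoid the package's implicit solver path: the explicit integrator below
# re-derives the finite-volume update with forward Euler, and the view
# factor is recomputed by brute-force quadrature of the radiative kernel.

# forward-Euler integration of the axisymmetric Pennes equation
explicit_euler_solve <- function(config, duration = config$duration,
                                 dt = config$dt) {
  th <- vapply(config$layers, `[[`, numeric(1), "thickness")
  dr <- config$dr; dz <- config$dz
  Nr <- max(2L, round(config$domain_radius / dr))
  Nz <- max(3L, round(sum(th) / dz))
  r <- (seq_len(Nr) - 0.5) * dr
  z <- (seq_len(Nz) - 0.5) * dz
  layer_of <- pmin(findInterval(z, cumsum(th), left.open = TRUE) + 1L,
                   length(config$layers))
  prop <- function(f) vapply(config$layers, `[[`, numeric(1), f)[layer_of]
  kz <- prop("k"); rc <- prop("rho") * prop("c")
  wz <- prop("omega_b") * config$blood_density * config$blood_heat_capacity
  qmz <- prop("q_m")
  dr_m <- dr / 1000; dz_m <- dz / 1000; r_m <- r / 1000
  vol <- 2 * pi * r_m * dr_m * dz_m
  a_top <- 2 * pi * r_m * dr_m
  Tb <- config$core_temp
  Tm <- matrix(config$initial_temp, Nr, Nz)
  nsteps <- ceiling(duration / dt)
  for (n in seq_len(nsteps)) {
    t_now <- (n - 1) * dt
    heat <- matrix(0, Nr, Nz)
    for (j in seq_len(Nz)) {                      # radial conduction
      i <- seq_len(Nr - 1)
      g <- kz[j] * (2 * pi * (i * dr_m) * dz_m) / dr_m
      fl <- g * (Tm[i + 1, j] - Tm[i, j])
      heat[i, j] <- heat[i, j] + fl
      heat[i + 1, j] <- heat[i + 1, j] - fl
    }
    for (j in seq_len(Nz - 1)) {                  # vertical conduction
      kf <- 2 * kz[j] * kz[j + 1] / (kz[j] + kz[j + 1])
      g <- kf * (2 * pi * r_m * dr_m) / dz_m
      fl <- g * (Tm[, j + 1] - Tm[, j])
      heat[, j] <- heat[, j] + fl
      heat[, j + 1] <- heat[, j + 1] - fl
    }
    q <- if (!is.null(config$flux_override))
      config$flux_override(r, Tm[, 1], t_now)
    else
      radiative_surface_flux(r, Tm[, 1],
                             moxa_temperature(t_now, config$source),
                             config$source)
    heat[, 1] <- heat[, 1] + q * a_top
    gb <- kz[Nz] * (2 * pi * r_m * dr_m) / (dz_m / 2)
    heat[, Nz] <- heat[, Nz] + gb * (Tb - Tm[, Nz])
    heat <- heat + (vol %o% wz) * (Tb - Tm) + vol %o% qmz
    Tm <- Tm + dt * heat / (vol %o% rc)
    if (anyNA(Tm)) stop("explicit oracle diverged at step ", n)
  }
  list(r = r, z = z, T = Tm)                       # T indexed (r, z)
}

# brute-force double quadrature of the disk-to-element view-factor kernel
view_factor_quadrature <- function(r, R, h, n = 400L) {
  xi <- (seq_len(n) - 0.5) / n * R
  phi <- (seq_len(n) - 0.5) / n * 2 * pi
  dxi <- R / n; dphi <- 2 * pi / n
  total <- 0
  for (p in phi) {
    S2 <- h^2 + r^2 + xi^2 - 2 * r * xi * cos(p)
    total <- total + sum(h^2 * xi / S2^2) * dxi * dphi
  }
  total / pi
}

# surface temperature of a semi-infinite solid under constant surface flux
semi_infinite_surface <- function(t, q0, k, rho, c, T0) {
  alpha <- k / (rho * c)
  T0 + 2 * q0 * sqrt(alpha * t / pi) / k
}

# single uniform layer with no perfusion/metabolism: pure conduction medium
conduction_only_config <- function(q0, dr = 2, dz = 0.5, dt = 0.5,
                                   duration = 60, k = 0.25, rho = 1100,
                                   cp = 3000) {
  simulation_config(
    dr = dr, dz = dz, dt = dt, duration = duration,
    layers = list(tissue_layer("uniform", 25, rho, cp, k,
                               omega_b = 0, q_m = 0)),
    flux_override = function(r, Ts, t) rep(q0, length(r)),
    save_every = duration
  )
}
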