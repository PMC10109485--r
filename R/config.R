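#' Simulation configuration for the bioheat solve
#'
#' Assembles geometry, grid, time stepping, tissue layers and the moxa
#' source into one validated object.  The tissue domain is a 2-D
#' axisymmetric cylinder: `z = 0` at the skin surface increasing downward
#' through skin (2.2 mm), fat (12.4 mm) and muscle (10.4 mm); `r = 0` on the
#' moxibustion axis.  The skin layer's thermophysical properties are derived
#' from the moisture content via [skin_properties_from_moisture()]; fat and
#' muscle use fixed reference constants (moisture is never varied for them).
#'
#' The four operating parameters are given in the units the parameter
#' tables print: `t1` deg C, `d` and `h` mm, `omega_c` **percent** (converted
#' to a fraction internally, once, at this boundary).
#'
#' @param t1 Maximum moxa burning temperature, deg C.
#' @param d Moxa stick diameter, mm.
#' @param h Stick-to-skin distance, mm.
#' @param omega_c Skin moisture content, percent (29--52 in the standard
#'   domain).
#' @param domain_radius Radial extent of the tissue cylinder, mm.
#' @param dr,dz Grid spacing, mm.
#' @param dt Time step, s.
#' @param duration Treatment duration, s.
#' @param core_temp Body-core (= arterial blood) temperature `T_b`, deg C;
#'   fixed Dirichlet value at the bottom of the domain.
#' @param blood_heat_capacity `C_b`, J kg^-1 K^-1.
#' @param blood_density `rho_b`, kg m^-3 (the volumetric perfusion rate is
#'   multiplied by `rho_b * C_b` in the Pennes sink term).
#' @param omega_b Volumetric blood perfusion rate applied to every layer,
#'   s^-1.
#' @param q_m Metabolic heat production applied to every layer, W m^-3.
#' @param initial_temp Uniform initial tissue temperature, deg C.
#' @param probe_depth Depth of the thermal-penetration (HPM) probe, mm.
#' @param source Optional [moxa_source()]; by default one is built from
#'   `t1`, `d`, `h` with standard floor temperature (200 deg C), period
#'   (500 s) and effective exchange emissivity (0.35).
#' @param layers Optional list of three [tissue_layer()]s overriding the
#'   standard skin/fat/muscle stack.
#' @param flux_override Optional `function(r_mm, surface_temp, t)` returning
#'   a boundary flux in W m^-2; replaces the radiative source (used for
#'   analytic verification runs).
#' @param save_every Interval between stored full-field snapshots, s.
#' @param surface_fixed_point_tol Convergence tolerance of the per-step
#'   fixed-point iteration on the radiating surface temperature, deg C.
#' @return A list of class `"simulation_config"`.
#' @examples
#' cfg <- simulation_config(dr = 2, dz = 1, dt = 10, duration = 60)
#' cfg
#' @export
simulation_config <- function(t1 = 625, d = 15, h = 30, omega_c = 40.5,
                              domain_radius = 40, dr = 0.5, dz = 0.5,
                              dt = 1, duration = 1200,
                              core_temp = 37, blood_heat_capacity = 3770,
                              blood_density = 1060,
                              omega_b = 3e-3, q_m = 420,
                              initial_temp = 37, probe_depth = 5,
                              source = NULL, layers = NULL,
                              flux_override = NULL,
                              save_every = 60,
                              surface_fixed_point_tol = 1e-6) {
  stopifnot(duration > 0, dt > 0, dr > 0, dz > 0, domain_radius > 0,
            probe_depth > 0)
  if (omega_c <= 1)
    stop("omega_c = ", omega_c, " looks like a fraction; the configuration ",
         "takes moisture content in percent (e.g. 40.5)", call. = FALSE)
  if (is.null(source)) source <- moxa_source(t1 = t1, d = d, h = h)
  if (is.null(layers)) {
    sp <- skin_properties_from_moisture(omega_c / 100)
    fx <- reference_constants()
    th <- fx$layer_thickness
    layers <- list(
      tissue_layer("skin", th[["skin"]], sp$rho, sp$c, sp$k,
                   omega_b = omega_b, q_m = q_m),
      tissue_layer("fat", th[["fat"]], fx$fat$rho, fx$fat$c, fx$fat$k,
                   omega_b = omega_b, q_m = q_m),
      tissue_layer("muscle", th[["muscle"]], fx$muscle$rho, fx$muscle$c,
                   fx$muscle$k, omega_b = omega_b, q_m = q_m)
    )
  }
  depth <- sum(vapply(layers, `[[`, numeric(1), "thickness"))
  if (probe_depth >= depth)
    stop("probe_depth (", probe_depth, " mm) must lie inside the ", depth,
         " mm deep tissue domain", call. = FALSE)
  for (ly in layers)
    if (ly$thickness < 3 * dz)
      warning("layer '", ly$name, "' (", ly$thickness, " mm) is resolved by ",
              "fewer than 3 cells at dz = ", dz, " mm", call. = FALSE)
  structure(list(
    t1 = t1, d = d, h = h, omega_c = omega_c,
    layers = layers, source = source,
    domain_radius = domain_radius, depth = depth,
    dr = dr, dz = dz, dt = dt, duration = duration,
    core_temp = core_temp,
    blood_heat_capacity = blood_heat_capacity,
    blood_density = blood_density,
    initial_temp = initial_temp, probe_depth = probe_depth,
    flux_override = flux_override,
    save_every = save_every,
    surface_fixed_point_tol = surface_fixed_point_tol
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("bioheat simulation configuration\n")
  cat(sprintf("  operating point: t1 %.1f degC, d %.2f mm, h %.2f mm, omega_c %.1f%%\n",
              x$t1, x$d, x$h, x$omega_c))
  cat(sprintf("  domain: radius %.0f mm x depth %.1f mm (%s)\n",
              x$domain_radius, x$depth,
              paste(vapply(x$layers, function(l)
                sprintf("%s %.1f", l$name, l$thickness), character(1)),
                collapse = " / ")))
  cat(sprintf("  grid: dr %.2g mm, dz %.2g mm, dt %.2g s, duration %.0f s\n",
              x$dr, x$dz, x$dt, x$duration))
  cat(sprintf("  core %.1f degC, initial %.1f degC, HPM probe at %.1f mm\n",
              x$core_temp, x$initial_temp, x$probe_depth))
  invisible(x)
}

#' Variant of a configuration with some operating parameters replaced
#'
#' Rebuilds a [simulation_config()] with new values of the four operating
#' parameters, keeping every numerical setting (grid, duration, constants)
#' of the base configuration.
#'
#' @param config A [simulation_config()].
#' @param t1,d,h,omega_c Replacement values; `NULL` keeps the base value.
#' @return A new `simulation_config`.
#' @export
with_parameters <- function(config, t1 = NULL, d = NULL, h = NULL,
                            omega_c = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  simulation_config(
    t1 = t1 %||% config$t1, d = d %||% config$d, h = h %||% config$h,
    omega_c = omega_c %||% config$omega_c,
    domain_radius = config$domain_radius, dr = config$dr, dz = config$dz,
    dt = config$dt, duration = config$duration,
    core_temp = config$core_temp,
    blood_heat_capacity = config$blood_heat_capacity,
    blood_density = config$blood_density,
    omega_b = config$layers[[1]]$omega_b, q_m = config$layers[[1]]$q_m,
    initial_temp = config$initial_temp, probe_depth = config$probe_depth,
    flux_override = config$flux_override,
    save_every = config$save_every,
    surface_fixed_point_tol = config$surface_fixed_point_tol
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
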