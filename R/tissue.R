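#' Skin thermophysical properties as a function of moisture content
#'
#' Skin density, heat capacity and thermal conductivity drift with the
#' water content of the tissue (which varies between patients and with
#' age).  The empirical relations used here are, with \eqn{\omega_c} the
#' moisture fraction and \eqn{\rho} expressed in g cm^-3 inside the
#' parenthesised terms:
#' \deqn{\rho = (1.3 - 0.3\,\omega_c) \cdot 1000 \; kg\,m^{-3}}
#' \deqn{c = 4.19\,(0.37 + 0.67\,\omega_c/\rho_{g/cc}) \cdot 1000 \; J\,kg^{-1}K^{-1}}
#' \deqn{k = 0.419\,(0.133 + 1.36\,\omega_c/\rho_{g/cc}) \; W\,m^{-1}K^{-1}}
#'
#' @param omega_c Skin moisture content as a fraction in (0, 1).  Parameter
#'   tables in this field usually print percent (29--52); divide by 100.
#' @return A list with elements `rho` (kg m^-3), `c` (J kg^-1 K^-1) and
#'   `k` (W m^-1 K^-1), class `"skin_properties"`.
#' @examples
#' skin_properties_from_moisture(0.40)  # rho 1180, c ~2502, k ~0.25
#' @export
skin_properties_from_moisture <- function(omega_c) {
  stopifnot(is.numeric(omega_c), length(omega_c) == 1L, is.finite(omega_c))
  if (omega_c <= 0 || omega_c >= 1)
    stop("omega_c = ", omega_c, " is outside (0, 1); moisture content must ",
         "be a fraction (tables often print percent: divide by 100)",
         call. = FALSE)
  rho_gcc <- 1.3 - 0.3 * omega_c           # g cm^-3
  structure(list(
    rho = rho_gcc * 1000,
    c   = 4.19 * (0.37 + 0.67 * omega_c / rho_gcc) * 1000,
    k   = 0.419 * (0.133 + 1.36 * omega_c / rho_gcc)
  ), class = "skin_properties")
}

#' @export
print.skin_properties <- function(x, ...) {
  cat(sprintf("skin properties: rho %.1f kg/m^3, c %.1f J/(kg K), k %.4f W/(m K)\n",
              x$rho, x$c, x$k))
  invisible(x)
}

#' Tissue layer description
#'
#' One horizontal layer of the three-layer (skin / fat / muscle) tissue
#' domain.  Perfusion is volumetric (m^3 blood per m^3 tissue per second)
#' and enters the Pennes sink term as
#' \eqn{\omega_b \rho_b C_b (T_b - T)}.
#'
#' @param name Layer label.
#' @param thickness Layer thickness in mm.
#' @param rho Density, kg m^-3.
#' @param c Constant-pressure heat capacity, J kg^-1 K^-1.
#' @param k Thermal conductivity, W m^-1 K^-1.
#' @param omega_b Volumetric blood perfusion rate, s^-1.
#' @param q_m Metabolic heat production, W m^-3.
#' @return A list of class `"tissue_layer"`.
#' @export
tissue_layer <- function(name, thickness, rho, c, k,
                         omega_b = 3e-3, q_m = 420) {
  stopifnot(thickness > 0, rho > 0, c > 0, k > 0, omega_b >= 0, q_m >= 0)
  structure(list(name = name, thickness = thickness, rho = rho, c = c,
                 k = k, omega_b = omega_b, q_m = q_m),
            class = "tissue_layer")
}

#' Reference constants of the standard moxibustion operating model
#'
#' Returns, as plain R data, every published constant the pipeline needs:
#' the fat and muscle layer properties, the single-factor parameter levels,
#' the expected skin properties at the three tabulated moisture contents
#' (the oracle for [skin_properties_from_moisture()]), the
#' operating-parameter design domain and interval radii, the layer
#' thicknesses, the 45.5 deg C allowable skin-surface temperature, and the
#' published optimized response intervals at the four reliability levels
#' (used for internal-consistency checks of the RPDI formula).
#'
#' @return A named list; see the element names in the source for the layout.
#' @examples
#' fx <- reference_constants()
#' fx$allowable_ST           # 45.5
#' fx$design_domain$t1       # [600, 650]
#' @export
reference_constants <- function() {
  list(
    layer_thickness = c(skin = 2.2, fat = 12.4, muscle = 10.4),  # mm
    fat    = list(c = 2348, rho = 911,  k = 0.21),
    muscle = list(c = 3421, rho = 1090, k = 0.49),
    # single-factor levels: t1 deg C, d mm (stick diameter; the quoted
    # "radius 6/7.5/9 mm" values are d/2), h mm, omega_c percent
    levels = list(
      t1      = c(600, 625, 650),
      d       = c(12, 15, 18),
      h       = c(25, 30, 35),
      omega_c = c(29, 40, 52)
    ),
    # expected skin properties per moisture content (percent)
    skin_table = data.frame(
      omega_c_pct = c(29, 40, 52),
      c   = c(2222, 2502, 2826),
      rho = c(1213, 1180, 1144),
      k   = c(0.19, 0.25, 0.32)
    ),
    design_domain = box(
      t1      = interval(600, 650),   # moxa burning temperature, deg C
      d       = interval(12, 18),     # moxa stick thickness (diameter), mm
      h       = interval(25, 35),     # stick-to-skin distance, mm
      omega_c = interval(29, 52)      # skin moisture content, percent
    ),
    radii = c(t1 = 2.5, d = 0.15, h = 0.8, omega_c = 1.1),
    allowable_ST = 45.5,              # deg C comfort threshold
    probe_depth = 5,                  # mm, HPM read-out depth
    # published optimized response intervals per reliability level lambda
    reference_optima = list(
      lambda = c(0.8, 0.9, 1.0, 1.1),
      ST  = list(interval(41.81, 46.24), interval(41.63, 45.90),
                 interval(40.99, 45.50), interval(40.59, 44.98)),
      HPM = list(interval(37.59, 38.84), interval(37.44, 39.63),
                 interval(37.35, 38.60), interval(37.27, 38.51))
    ),
    # deterministic (midpoint) reference indicator values
    reference_general = c(HPM = 38.5, ST = 45.5),
    reference_ranges = list(HPM = interval(37.5, 43.5), ST = interval(39.5, 58.1))
  )
}
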