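#' Moxa stick heat source
#'
#' The burning tip of the moxa stick is modelled as a flat disk of diameter
#' `d` held parallel to the skin at distance `h`, radiating at a
#' time-varying temperature.  Burning is periodic: the tip climbs to its
#' maximum temperature `t1` and decays as ash accumulates, then recovers
#' after ash clearing; a simple harmonic captures the cycle,
#' \deqn{T_a(t) = \frac{t_1 + T_{floor}}{2} +
#'       \frac{t_1 - T_{floor}}{2}\cos(2\pi t / period).}
#' With the defaults (`t1 = 600`, `floor_temp = 200`, `period = 500`) this is
#' \eqn{T_a = 400 + 200\cos(2\pi t/500)} deg C.
#'
#' An optional "ash dip" modifier drops the source to `ash_dip_temp` for
#' `ash_dip_seconds` every `ash_dip_every` seconds (off by default; the
#' harmonic alone is the standard operating model).
#'
#' @param t1 Maximum burning temperature of the tip, deg C.
#' @param d Stick diameter, mm.
#' @param h Stick-to-skin distance, mm.
#' @param floor_temp Minimum tip temperature over the ash cycle, deg C.
#' @param period Burning/ash-clearing cycle length, s.
#' @param emissivity Effective emissivity of the tip--skin radiative
#'   exchange (dimensionless, in \[0, 1\]).  The default 0.35 lumps the
#'   insulating ash layer on the smoldering tip and smoke attenuation into
#'   a single exchange factor; it is calibrated so the centre operating
#'   point reproduces the magnitude of clinically observed moxibustion
#'   skin temperatures.
#' @param ash_dip If `TRUE`, superimpose the ash-clearing dip.
#' @param ash_dip_every,ash_dip_seconds,ash_dip_temp Dip schedule: every so
#'   many seconds the source temperature is clamped to `ash_dip_temp` for
#'   `ash_dip_seconds`.
#' @return A list of class `"moxa_source"`.
#' @examples
#' src <- moxa_source()
#' moxa_temperature(c(0, 125, 250), src)  # 600 400 200
#' @export
moxa_source <- function(t1 = 600, d = 15, h = 30,
                        floor_temp = 200, period = 500,
                        emissivity = 0.35,
                        ash_dip = FALSE, ash_dip_every = 60,
                        ash_dip_seconds = 3, ash_dip_temp = 50) {
  stopifnot(t1 > floor_temp, floor_temp >= 0, d > 0, h > 0,
            emissivity >= 0, emissivity <= 1, period > 0)
  structure(list(t1 = t1, d = d, h = h, floor_temp = floor_temp,
                 period = period, emissivity = emissivity,
                 reflectance = 1 - emissivity, refractive_index = 1,
                 sigma = 5.67e-8,
                 ash_dip = ash_dip, ash_dip_every = ash_dip_every,
                 ash_dip_seconds = ash_dip_seconds,
                 ash_dip_temp = ash_dip_temp),
            class = "moxa_source")
}

#' @export
print.moxa_source <- function(x, ...) {
  cat(sprintf(
    "moxa source: t1 %.0f degC, d %.1f mm, h %.1f mm, floor %.0f degC, period %.0f s%s\n",
    x$t1, x$d, x$h, x$floor_temp, x$period,
    if (isTRUE(x$ash_dip)) sprintf(", ash dip to %.0f degC every %.0f s",
                                   x$ash_dip_temp, x$ash_dip_every) else ""))
  invisible(x)
}

#' @rdname moxa_source
#' @param t Time(s) since ignition, seconds (vectorized).
#' @param source A [moxa_source()].
#' @return `moxa_temperature`: tip temperature(s) in deg C.
#' @export
moxa_temperature <- function(t, source = moxa_source()) {
  stopifnot(is.numeric(t), all(t >= 0))
  mean_T <- (source$t1 + source$floor_temp) / 2
  amp    <- (source$t1 - source$floor_temp) / 2
  Ta <- mean_T + amp * cos(2 * pi * t / source$period)
  if (isTRUE(source$ash_dip)) {
    phase <- t %% source$ash_dip_every
    Ta[phase < source$ash_dip_seconds] <- source$ash_dip_temp
  }
  Ta
}

#' View factor from a skin surface point to the moxa tip disk
#'
#' Closed-form view factor from a differential planar element, lying in the
#' skin plane at radial offset `r` from the moxibustion axis, to a coaxial
#' parallel disk of radius `R` at height `h`.  With the reduced variables
#' \eqn{\rho = R/h}, \eqn{\tau = r/h}:
#' \deqn{F = \frac{1}{2}\left[1 - \frac{1 + \tau^2 - \rho^2}
#'       {\sqrt{(1 + \tau^2 + \rho^2)^2 - 4\tau^2\rho^2}}\right]}
#' On the axis (\eqn{\tau = 0}) this reduces to the familiar
#' \eqn{R^2/(R^2 + h^2)}, and it vanishes as \eqn{h \to \infty}.
#'
#' @param r Radial offset(s) of the surface point, mm (vectorized).
#' @param R Disk radius, mm.
#' @param h Disk height above the surface plane, mm.
#' @return View factor(s) in \[0, 1\].
#' @examples
#' disk_view_factor(0, R = 7.5, h = 30)     # 7.5^2 / (7.5^2 + 30^2) = 0.0588
#' @export
disk_view_factor <- function(r, R, h) {
  stopifnot(R > 0, h > 0, all(r >= 0))
  tau2 <- (r / h)^2
  rho2 <- (R / h)^2
  disc <- (1 + tau2 + rho2)^2 - 4 * tau2 * rho2
  0.5 * (1 - (1 + tau2 - rho2) / sqrt(disc))
}

#' Net radiative flux absorbed by the skin surface
#'
#' Net absorbed flux density at radial offset `r`:
#' \deqn{q(r) = \varepsilon\,\sigma\,(T_a^4 - T_s^4)\,F(r; d/2, h)}
#' with temperatures converted to kelvin and \eqn{F} the disk view factor of
#' [disk_view_factor()].  Positive values heat the tissue; the flux is zero
#' at radiative equilibrium (`moxa_temp == surface_temp`) and vanishes as the
#' stick is withdrawn (`h -> Inf`).
#'
#' @param r Radial offset(s) on the skin surface, mm (vectorized).
#' @param surface_temp Local skin surface temperature(s), deg C (scalar or
#'   same length as `r`).
#' @param moxa_temp Current tip temperature, deg C.
#' @param source A [moxa_source()] (supplies `d`, `h`, emissivity).
#' @return Net absorbed flux in W m^-2, same length as `r`.
#' @export
radiative_surface_flux <- function(r, surface_temp, moxa_temp,
                                   source = moxa_source()) {
  TaK <- moxa_temp + 273.15
  TsK <- surface_temp + 273.15
  if (any(TaK < 0) || any(TsK < 0))
    stop("negative absolute temperature in radiative flux", call. = FALSE)
  Fv <- disk_view_factor(r, R = source$d / 2, h = source$h)
  source$emissivity * source$sigma * (TaK^4 - TsK^4) * Fv
}
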