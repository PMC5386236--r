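#' Site forcing: seasonal and diel temperature, soil moisture, warming offset
#'
#' Describes the abiotic drivers of a simulated campaign at a warm-temperate
#' evergreen broadleaf forest site.  The seasonal course of temperature is a
#' single sinusoid solved through two monthly means (January and August,
#' defaults 7.0 and 27.9 degC) with its peak at mid-August; a diel sinusoid
#' (peaking mid-afternoon) is superimposed, with a larger amplitude in air
#' than in the 5-cm soil.  Volumetric soil moisture is a base level plus
#' Poisson rain events with exponential drawdown, clipped to `[0, 0.6]`.
#' Soil warming adds a constant offset (default +2.5 degC) to the 5-cm soil
#' temperature of warmed-treatment chambers only.
#'
#' @param t_jan,t_aug Mean monthly temperature (degC) of the coldest and
#'   warmest months used to anchor the seasonal sinusoid.
#' @param peak_doy Day of year at which the seasonal sinusoid peaks.
#' @param diel_amp_air,diel_amp_soil Semi-amplitude (degC) of the diel cycle
#'   for chamber air and 5-cm soil temperature.
#' @param diel_peak_hour Local hour of the diel temperature maximum.
#' @param moisture_base Base volumetric soil moisture (m3 m-3).
#' @param rain_rate Mean number of rain events per day (Poisson).
#' @param rain_jump Range (min, max) of the moisture step added per event.
#' @param moisture_tau_d e-folding drawdown time of event moisture, days.
#' @param warming_offset Soil temperature increase at 5 cm depth in warmed
#'   plots (degC).
#'
#' @return An object of class `site_forcing`.
#' @examples
#' f <- site_forcing()
#' soil_temperature(f, as.POSIXct("2009-08-15 14:00", tz = "Etc/GMT-9"))
#' @export
site_forcing <- function(t_jan = 7.0, t_aug = 27.9, peak_doy = 227,
                         diel_amp_air = 4, diel_amp_soil = 1,
                         diel_peak_hour = 15,
                         moisture_base = 0.30, rain_rate = 0.25,
                         rain_jump = c(0.03, 0.12), moisture_tau_d = 4,
                         warming_offset = 2.5) {
  stopifnot(t_aug > t_jan, moisture_base >= 0, moisture_base <= 0.6,
            moisture_tau_d > 0, rain_rate >= 0)
  # Solve T(doy) = mean + amp * cos(2*pi*(doy - peak)/365) through the two
  # anchor months (mid-January and the peak itself).
  c_jan <- cos(2 * pi * (15 - peak_doy) / 365)
  amp <- (t_aug - t_jan) / (1 - c_jan)
  structure(
    list(
      t_jan = t_jan, t_aug = t_aug, peak_doy = peak_doy,
      seasonal_mean = t_aug - amp, seasonal_amp = amp,
      diel_amp_air = diel_amp_air, diel_amp_soil = diel_amp_soil,
      diel_peak_hour = diel_peak_hour,
      moisture_base = moisture_base, rain_rate = rain_rate,
      rain_jump = rain_jump, moisture_tau_d = moisture_tau_d,
      warming_offset = warming_offset
    ),
    class = "site_forcing"
  )
}

#' @export
print.site_forcing <- function(x, ...) {
  cat("<site_forcing>\n")
  cat(sprintf("  seasonal: %.2f +/- %.2f degC (peak doy %d)\n",
              x$seasonal_mean, x$seasonal_amp, x$peak_doy))
  cat(sprintf("  diel semi-amplitude: air %.1f, soil %.1f degC\n",
              x$diel_amp_air, x$diel_amp_soil))
  cat(sprintf("  moisture base %.2f m3 m-3, %.2f rain events/day\n",
              x$moisture_base, x$rain_rate))
  cat(sprintf("  warming offset at 5 cm: +%.1f degC\n", x$warming_offset))
  invisible(x)
}

## Fractional day of year and local hour from POSIXct.
cf_doy <- function(time) {
  lt <- as.POSIXlt(time, tz = CF_TZ)
  lt$yday + (lt$hour + lt$min / 60 + lt$sec / 3600) / 24
}

cf_hour <- function(time) {
  lt <- as.POSIXlt(time, tz = CF_TZ)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Deterministic temperature components of the forcing
#'
#' `seasonal_temperature()` evaluates the seasonal sinusoid alone;
#' `air_temperature()` and `soil_temperature()` add the diel cycle with the
#' air or soil amplitude.  `soil_temperature(warmed = TRUE)` adds the
#' warming offset, emulating the heat-lamp treatment.
#'
#' @param forcing A [site_forcing()].
#' @param time POSIXct vector.
#' @param warmed Logical (recycled): apply the warming offset?
#' @return Numeric vector of temperatures, degC.
#' @export
seasonal_temperature <- function(forcing, time) {
  forcing$seasonal_mean +
    forcing$seasonal_amp * cos(2 * pi * (cf_doy(time) - forcing$peak_doy) / 365)
}

#' @rdname seasonal_temperature
#' @export
air_temperature <- function(forcing, time) {
  seasonal_temperature(forcing, time) +
    forcing$diel_amp_air *
      cos(2 * pi * (cf_hour(time) - forcing$diel_peak_hour) / 24)
}

#' @rdname seasonal_temperature
#' @export
soil_temperature <- function(forcing, time, warmed = FALSE) {
  # Soil lags air by ~2 h at 5 cm; small phase shift on the diel term.
  seasonal_temperature(forcing, time) +
    forcing$diel_amp_soil *
      cos(2 * pi * (cf_hour(time) - forcing$diel_peak_hour - 2) / 24) +
    ifelse(rep_len(warmed, length(time)), forcing$warming_offset, 0)
}

## Soil moisture sample path on a time grid (POSIXct, sorted).  Uses the
## current RNG stream; callers wrap in withr::with_seed().
simulate_moisture <- function(forcing, times) {
  t0 <- as.numeric(min(times))
  t_d <- (as.numeric(times) - t0) / 86400            # days since start
  span <- max(t_d)
  n_events <- rpois(1, forcing$rain_rate * max(span, 1 / 24))
  w <- rep(forcing$moisture_base, length(times))
  if (n_events > 0) {
    ev_t <- runif(n_events, 0, span)
    ev_j <- runif(n_events, forcing$rain_jump[1], forcing$rain_jump[2])
    for (i in seq_len(n_events)) {
      dt <- t_d - ev_t[i]
      w <- w + ifelse(dt >= 0, ev_j[i] * exp(-dt / forcing$moisture_tau_d), 0)
    }
  }
  pmin(pmax(w, 0), 0.6)
}
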