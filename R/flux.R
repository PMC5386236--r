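#' Flux coefficient for a closed chamber
#'
#' For a chamber with effective volume-to-surface ratio `V/S` (m), soil CO2
#' efflux (umol m-2 s-1) is obtained from the concentration slope
#' (ppm s-1) as
#' `flux = 1000 * (V/S) / 8.314 * P_air / (T_air + 273.15) * slope`,
#' with `P_air` in kPa.  With the system's `V/S = 0.5` m the leading
#' coefficient is 60.14 (4 s.f.).
#'
#' @param vs_ratio Effective chamber volume / soil surface area, m.
#' @return The coefficient `1000 * vs_ratio / 8.314` (K kPa-1 units folded).
#' @examples
#' flux_coefficient(0.5)  # 60.14
#' @export
flux_coefficient <- function(vs_ratio = 0.5) {
  stopifnot(vs_ratio > 0)
  1000 * vs_ratio / GAS_CONSTANT
}

#' Compute per-closure soil CO2 effluxes
#'
#' Turns QC'd closures into a tidy flux table using the linear model (the
#' OLS slope of CO2 against closure time) or the average model (the mean
#' of per-interval concentration changes over retained consecutive record
#' pairs, using actual record spacing).  On a noise-free linear ramp the
#' two estimators coincide.
#'
#' The pressure used is the chamber-height ambient pressure
#' (`pressure_source = "chamber"`, the correct choice); `"cell"` (analyser
#' cell pressure, typically ~5 kPa higher) and `"standard"` (101.32 kPa)
#' are provided to quantify the overestimate/underestimate those common
#' shortcuts introduce.  Air temperature is averaged over the retained
#' records of each closure; closures with no air temperature fall back to
#' `t_air_fallback` (e.g. the site humidity-temperature probe) when given,
#' otherwise they are flagged unusable.
#'
#' @param qc A `closure_qc` object from [qc_closures()].
#' @param model `"linear"` or `"average"`.
#' @param pressure_source `"chamber"`, `"cell"`, or `"standard"`.
#' @param pressure_fallback Site-constant pressure (kPa) used when a
#'   closure has no pressure record; `NULL` (default) flags such closures.
#' @param t_air_fallback Optional fallback air temperature (degC), scalar
#'   or a function of closure start time.
#' @param interval_divisor For the average model: `"n-1"` (default; mean
#'   over the n-1 intervals) or `"n"` (divide the interval sum by n).
#' @return A tibble with one row per closure: `time`, `chamber`,
#'   `treatment`, `flux` (umol CO2 m-2 s-1), `model`, `p_air`, `t_air`,
#'   `t_air_source`, `r`, `n_used`, `usable`, `flags`.
#' @export
compute_fluxes <- function(qc, model = c("linear", "average"),
                           pressure_source = c("chamber", "cell", "standard"),
                           pressure_fallback = NULL,
                           t_air_fallback = NULL,
                           interval_divisor = c("n-1", "n")) {
  model <- match.arg(model)
  pressure_source <- match.arg(pressure_source)
  interval_divisor <- match.arg(interval_divisor)
  cl <- qc$closures

  slope <- switch(model,
    linear = cl$slope,
    average = average_slopes(qc$records, cl, interval_divisor)
  )

  p <- switch(pressure_source,
    chamber = cl$p_air,
    cell = cl$p_cell,
    standard = rep(101.32, nrow(cl))
  )
  flags <- cl$flags
  if (any(!is.finite(p))) {
    if (is.null(pressure_fallback))
      stop("closures without a pressure record; supply pressure_fallback",
           call. = FALSE)
    n_fb <- sum(!is.finite(p))
    message("using fallback pressure ", pressure_fallback, " kPa for ",
            n_fb, " closure(s)")
    flags[!is.finite(p)] <- paste_flag(flags[!is.finite(p)], "pressure_fallback")
    p[!is.finite(p)] <- pressure_fallback
  }

  t_air <- cl$t_air
  t_src <- rep("chamber", nrow(cl))
  if (any(!is.finite(t_air))) {
    miss <- !is.finite(t_air)
    if (!is.null(t_air_fallback)) {
      fb <- if (is.function(t_air_fallback)) t_air_fallback(cl$time[miss])
            else rep_len(t_air_fallback, sum(miss))
      t_air[miss] <- fb
      t_src[miss] <- "site_hmp"
    }
  }
  usable <- cl$usable & is.finite(t_air) & is.finite(slope)
  miss_t <- cl$usable & !is.finite(t_air)
  flags[miss_t] <- paste_flag(flags[miss_t], "no_air_temperature")

  tibble::tibble(
    time = cl$time,
    chamber = cl$chamber,
    treatment = cl$treatment,
    flux = flux_coefficient(cl$vs_ratio) * p / (t_air + 273.15) * slope,
    model = model,
    p_air = p,
    t_air = t_air,
    t_air_source = t_src,
    r = cl$r,
    n_used = cl$n_used,
    usable = usable,
    flags = flags
  )
}

paste_flag <- function(flags, new) {
  ifelse(flags == "", new, paste(flags, new, sep = ";"))
}

## Mean of per-interval dC/dt over retained consecutive record pairs,
## per closure (ordered as in cl).
average_slopes <- function(records, cl, interval_divisor = "n-1") {
  r <- records[records$qc_keep, , drop = FALSE]
  gi <- match(r$closure, cl$closure)
  ord <- order(gi, r$offset_s)
  gi <- gi[ord]
  t <- r$offset_s[ord]
  y <- r$co2_ppm[ord]
  n <- length(gi)
  if (n == 0) return(rep(NA_real_, nrow(cl)))
  same <- gi[-1] == gi[-n]
  dt <- (t[-1] - t[-n])[same]
  dy <- (y[-1] - y[-n])[same]
  g2 <- gi[-1][same]
  G <- nrow(cl)
  s <- group_sum(dy / dt, g2, G)
  k <- group_sum(rep(1, length(g2)), g2, G)
  div <- if (interval_divisor == "n") k + 1 else k
  ifelse(k > 0, s / div, NA_real_)
}

#' Flux from a single QC'd segment
#'
#' Convenience single-closure versions of the two estimators.
#' `flux_linear()` uses the OLS slope of the retained records;
#' `flux_average()` uses the mean per-interval concentration change.  Both
#' then apply the chamber flux equation with the given pressure and the
#' mean retained air temperature.
#'
#' @param segment One closure's records (`offset_s`, `co2_ppm`,
#'   `t_air_c`, `p_air_kpa`; optionally `qc_keep`).
#' @param vs_ratio Chamber V/S, m.
#' @param interval_divisor See [compute_fluxes()].
#' @return One-row tibble with `flux`, `slope`, `p_air`, `t_air`, `r`,
#'   `n_used`.
#' @examples
#' seg <- tibble::tibble(offset_s = c(0, 10, 20), co2_ppm = c(400, 401, 402),
#'                       t_air_c = 25, p_air_kpa = 101.32)
#' flux_average(seg)
#' @export
flux_linear <- function(segment, vs_ratio = 0.5) {
  keep <- segment[["qc_keep"]] %||% rep(TRUE, nrow(segment))
  fit <- ols_by_group(segment$offset_s, segment$co2_ppm,
                      rep(1L, nrow(segment)), keep, 1L)
  segment_flux(segment, keep, fit$slope, fit$r, vs_ratio)
}

#' @rdname flux_linear
#' @export
flux_average <- function(segment, vs_ratio = 0.5,
                         interval_divisor = c("n-1", "n")) {
  interval_divisor <- match.arg(interval_divisor)
  keep <- segment[["qc_keep"]] %||% rep(TRUE, nrow(segment))
  if (sum(keep) < 2) stop("need at least 2 retained records", call. = FALSE)
  t <- segment$offset_s[keep]
  y <- segment$co2_ppm[keep]
  o <- order(t)
  slopes <- diff(y[o]) / diff(t[o])
  slope <- sum(slopes) /
    (if (interval_divisor == "n") length(slopes) + 1 else length(slopes))
  fit <- ols_by_group(segment$offset_s, segment$co2_ppm,
                      rep(1L, nrow(segment)), keep, 1L)
  segment_flux(segment, keep, slope, fit$r, vs_ratio)
}

segment_flux <- function(segment, keep, slope, r, vs_ratio) {
  t_air <- mean(segment$t_air_c[keep], na.rm = TRUE)
  p_air <- mean(segment$p_air_kpa[keep], na.rm = TRUE)
  tibble::tibble(
    flux = flux_coefficient(vs_ratio) * p_air / (t_air + 273.15) * slope,
    slope = slope, p_air = p_air, t_air = t_air, r = r,
    n_used = sum(keep)
  )
}

#' Full chamber flux with water-vapour dilution correction
#'
#' The complete non-steady-state chamber equation: with chamber pressure
#' `P0` (Pa), effective volume `V` (m3), soil area `S` (m2), air
#' temperature `T` (degC), CO2 mole fraction series `C` (umol mol-1) and
#' water vapour mole fraction series `W` (mmol mol-1),
#'
#' `flux = P0 * V / (R * S * (T + 273.15)) * (dC/dt + Cbar / (1000 - Wbar) * dW/dt)`
#'
#' where `dC/dt` and `dW/dt` are OLS slopes against time and `Cbar`,
#' `Wbar` are means over the closure.  With `dW/dt = 0` this reduces
#' exactly to the simplified (linear-model) equation.  Most field
#' analysers cannot measure `W`; in this system the dilution term
#' contributes under 1% of the flux and is dropped in routine processing.
#'
#' @param time_s Record times, s.
#' @param co2_ppm CO2 mole fraction series, umol mol-1.
#' @param w_mmol Water vapour mole fraction series, mmol mol-1 (must be
#'   `< 1000`).
#' @param t_air_c Air temperature, degC (scalar or per-record).
#' @param p0_pa Chamber air pressure, Pa.
#' @param v_m3,s_m2 Chamber volume and soil surface area; alternatively
#'   give `vs_ratio`.
#' @param vs_ratio V/S, m, used when `v_m3`/`s_m2` are `NULL`.
#' @return One-row tibble with `flux` (umol m-2 s-1), `flux_simplified`
#'   (dilution term dropped), `dilution_fraction` (relative contribution
#'   of the dilution term), `dcdt`, `dwdt`.
#' @export
flux_full <- function(time_s, co2_ppm, w_mmol, t_air_c, p0_pa,
                      v_m3 = NULL, s_m2 = NULL, vs_ratio = 0.5) {
  if (any(w_mmol >= 1000))
    stop("water vapour mole fraction must be < 1000 mmol mol-1",
         call. = FALSE)
  stopifnot(length(time_s) >= 2, length(co2_ppm) == length(time_s),
            length(w_mmol) == length(time_s))
  vs <- if (!is.null(v_m3) && !is.null(s_m2)) v_m3 / s_m2 else vs_ratio
  gi <- rep(1L, length(time_s))
  w_all <- rep(TRUE, length(time_s))
  dcdt <- ols_by_group(time_s, co2_ppm, gi, w_all, 1L)$slope
  dwdt <- ols_by_group(time_s, w_mmol, gi, w_all, 1L)$slope
  cbar <- mean(co2_ppm)
  wbar <- mean(w_mmol)
  t_k <- mean(t_air_c) + 273.15
  pref <- p0_pa * vs / (GAS_CONSTANT * t_k)
  flux <- pref * (dcdt + cbar / (1000 - wbar) * dwdt)
  flux_s <- pref * dcdt
  tibble::tibble(
    flux = flux, flux_simplified = flux_s,
    dilution_fraction = ifelse(flux != 0, (flux - flux_s) / flux, 0),
    dcdt = dcdt, dwdt = dwdt
  )
}
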