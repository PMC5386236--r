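#' Pre-treatment chamber calibration coefficients
#'
#' Before a warming treatment starts, the trenched and warmed-trenched
#' chamber groups differ only through spatial heterogeneity.  Over a
#' pre-treatment window the calibration coefficient of a treatment is
#'
#' `Qc(treatment) = mean hourly flux of all trenched chambers / mean
#' hourly flux of that treatment's chambers`,
#'
#' both means taken over the hours in which both groups have usable data.
#' Multiplying a group's fluxes by its `Qc` aligns the group means,
#' removing the initial heterogeneity from subsequent treatment contrasts.
#'
#' @param fluxes Flux table from [compute_fluxes()] (uses usable closures
#'   only).
#' @param window Length-2 vector (start, end) of the pre-treatment
#'   calibration window; closures with `start <= time < end` are used.
#' @param treatments Treatments to calibrate (default both trenched
#'   groups).
#' @param reference_treatments Chamber groups whose pooled mean defines
#'   the numerator (default: all trenched chambers, i.e. both groups).
#' @return A tibble of class `qc_calibration` with columns `treatment`,
#'   `qc`, `mean_reference`, `mean_treatment`, `n_hours`; the window is
#'   attached as attribute `"window"`.
#' @examples
#' # see vignette("chamberflux") for a full campaign example
#' @export
calibrate_qc <- function(fluxes, window,
                         treatments = c("trenched", "warmed_trenched"),
                         reference_treatments = c("trenched",
                                                  "warmed_trenched")) {
  window <- cf_time(window)
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be (start, end) with end > start", call. = FALSE)
  f <- dplyr::filter(fluxes, .data$usable,
                     .data$time >= window[1], .data$time < window[2])
  if (nrow(f) == 0) stop("no usable fluxes in the calibration window",
                         call. = FALSE)
  absent <- setdiff(treatments, unique(f$treatment))
  if (length(absent) > 0)
    stop("treatment(s) absent from the window: ",
         paste(absent, collapse = ", "), call. = FALSE)

  hourly <- f %>%
    dplyr::mutate(hour = floor_hour(.data$time)) %>%
    dplyr::group_by(.data$hour, .data$treatment) %>%
    dplyr::summarise(flux = mean(.data$flux), .groups = "drop")

  out <- purrr::map_dfr(treatments, function(tr) {
    grp <- tidyr::pivot_wider(
      dplyr::filter(hourly, .data$treatment %in%
                      union(tr, reference_treatments)),
      names_from = "treatment", values_from = "flux")
    ## hours where the target group and every reference group are present
    need <- union(tr, intersect(reference_treatments, names(grp)))
    ok <- stats::complete.cases(grp[, need, drop = FALSE])
    grp <- grp[ok, , drop = FALSE]
    ## reference mean pools all reference chambers: weight group means
    ## equally (equal chamber counts per group in this design)
    ref <- rowMeans(grp[, intersect(reference_treatments, names(grp)),
                        drop = FALSE])
    tibble::tibble(
      treatment = tr,
      qc = mean(ref) / mean(grp[[tr]]),
      mean_reference = mean(ref),
      mean_treatment = mean(grp[[tr]]),
      n_hours = nrow(grp)
    )
  })
  structure(tibble::as_tibble(out), window = window,
            class = c("qc_calibration", class(out)))
}

floor_hour <- function(time) {
  .POSIXct(floor(as.numeric(time) / 3600) * 3600, tz = CF_TZ)
}

#' Warming effect on heterotrophic respiration
#'
#' Estimates the warming effect `Fe` (percent increase in heterotrophic
#' efflux per degC of soil warming) from calibrated treatment means:
#'
#' `Fe = (Qcw * Rhw - Qch * Rh) / (Qch * Rh * (Tsw - Tsh)) * 100`
#'
#' where `Rh`/`Rhw` are the mean hourly effluxes of the trenched and
#' warmed-trenched groups over the analysis period (paired hours only),
#' `Qch`/`Qcw` their pre-treatment calibration coefficients, and
#' `Tsw - Tsh` the mean 5-cm soil temperature difference between the
#' groups.  By default the period means enter the formula once
#' (`per_hour = FALSE`); alternatively Fe is computed hour by hour and
#' averaged.
#'
#' @param fluxes Flux table from [compute_fluxes()].
#' @param env Environment table with per-chamber `t_soil_c` (used for the
#'   temperature difference).
#' @param calibration A `qc_calibration` from [calibrate_qc()].
#' @param meta Chamber metadata ([chamber_layout()]).
#' @param period Length-2 vector (start, end) of the analysis period.
#' @param per_hour Compute Fe per paired hour and average, instead of
#'   from period means.
#' @return An object of class `warming_effect`: list with `fe` (% per
#'   degC), `dt` (degC), `rh_cal`, `rhw_cal` (calibrated means,
#'   umol m-2 s-1), `n_hours`, `period`, `method`.
#' @export
warming_effect <- function(fluxes, env, calibration, meta = chamber_layout(),
                           period, per_hour = FALSE) {
  period <- cf_time(period)
  qch <- calibration$qc[calibration$treatment == "trenched"]
  qcw <- calibration$qc[calibration$treatment == "warmed_trenched"]
  if (length(qch) != 1 || length(qcw) != 1)
    stop("calibration must contain trenched and warmed_trenched Qc",
         call. = FALSE)

  hourly <- fluxes %>%
    dplyr::filter(.data$usable, .data$time >= period[1],
                  .data$time < period[2],
                  .data$treatment %in% c("trenched", "warmed_trenched")) %>%
    dplyr::mutate(hour = floor_hour(.data$time)) %>%
    dplyr::group_by(.data$hour, .data$treatment) %>%
    dplyr::summarise(flux = mean(.data$flux), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "treatment", values_from = "flux") %>%
    dplyr::filter(stats::complete.cases(.))
  if (nrow(hourly) == 0)
    stop("no paired hours with both trenched groups in the period",
         call. = FALSE)

  temps <- env %>%
    dplyr::filter(.data$timestamp >= period[1],
                  .data$timestamp < period[2]) %>%
    dplyr::left_join(meta, by = "chamber") %>%
    dplyr::filter(.data$treatment %in% c("trenched", "warmed_trenched")) %>%
    dplyr::group_by(.data$treatment) %>%
    dplyr::summarise(t_soil = mean(.data$t_soil_c, na.rm = TRUE))
  tsh <- temps$t_soil[temps$treatment == "trenched"]
  tsw <- temps$t_soil[temps$treatment == "warmed_trenched"]
  if (length(tsh) != 1 || length(tsw) != 1 || !is.finite(tsw - tsh))
    stop("soil temperatures for both trenched groups are required",
         call. = FALSE)
  dt <- tsw - tsh
  if (abs(dt) < 0.1)
    stop("soil temperature difference ~0 over the period; ",
         "per-degree warming effect is undefined", call. = FALSE)

  rh_cal <- qch * mean(hourly$trenched)
  rhw_cal <- qcw * mean(hourly$warmed_trenched)
  fe <- if (per_hour) {
    mean((qcw * hourly$warmed_trenched - qch * hourly$trenched) /
           (qch * hourly$trenched) / dt * 100)
  } else {
    (rhw_cal - rh_cal) / (rh_cal * dt) * 100
  }
  structure(
    list(fe = fe, dt = dt, rh_cal = rh_cal, rhw_cal = rhw_cal,
         qch = qch, qcw = qcw, n_hours = nrow(hourly), period = period,
         method = if (per_hour) "per_hour" else "period_mean"),
    class = "warming_effect"
  )
}

#' @export
print.warming_effect <- function(x, ...) {
  cat("<warming_effect>\n")
  cat(sprintf("  Fe = %.2f %% per degC  (deltaT = %.2f degC, %s)\n",
              x$fe, x$dt, x$method))
  cat(sprintf("  calibrated means: Rh %.3f, Rhw %.3f umol m-2 s-1 over %d paired hours\n",
              x$rh_cal, x$rhw_cal, x$n_hours))
  invisible(x)
}

#' Fit an exponential (Q10) temperature response
#'
#' Fits `ln(flux) = a + b * T_soil` by ordinary least squares on positive
#' fluxes and reports `Q10 = exp(10 b)` with the reference flux
#' `exp(a + b * t_ref)`.  Non-positive fluxes are excluded (their count is
#' reported); the fit refuses temperature spans below `min_span` or fewer
#' than `min_n` points, where the exponent is not identifiable.
#'
#' @param data Data frame of an hourly flux series with its matching 5-cm
#'   soil temperature.
#' @param flux,t_soil Column names (tidy-select style, unquoted) of the
#'   flux (umol m-2 s-1) and soil temperature (degC).
#' @param t_ref Reference temperature, degC.
#' @param min_span Minimum temperature range, degC.
#' @param min_n Minimum number of positive-flux observations.
#' @return An object of class `q10_fit`: list with `q10`, `r_ref`,
#'   `t_ref`, `fit` (the underlying `lm`), `n`, `n_excluded`, `t_span`,
#'   `se_log_q10`.  Supports [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] and `predict()`.
#' @examples
#' t <- seq(5, 25, 0.5)
#' d <- data.frame(t_soil = t, flux = 2 * 2.5^((t - 10) / 10))
#' fit_q10(d)$q10
#' @export
fit_q10 <- function(data, flux = "flux", t_soil = "t_soil", t_ref = 10,
                    min_span = 5, min_n = 30) {
  fl <- data[[rlang::as_name(rlang::enquo(flux))]] %||% data[["flux"]]
  ts <- data[[rlang::as_name(rlang::enquo(t_soil))]] %||% data[["t_soil"]]
  ok <- is.finite(fl) & is.finite(ts)
  pos <- ok & fl > 0
  n_excl <- sum(ok) - sum(pos)
  d <- data.frame(lf = log(fl[pos]), t = ts[pos])
  span <- if (nrow(d) > 0) diff(range(d$t)) else 0
  if (nrow(d) < min_n)
    stop("need at least ", min_n, " positive-flux observations (got ",
         nrow(d), ")", call. = FALSE)
  if (span < min_span)
    stop("temperature span ", signif(span, 3), " degC below minimum ",
         min_span, "; Q10 not identifiable", call. = FALSE)
  fit <- lm(lf ~ t, data = d)
  b <- unname(coef(fit)[2])
  a <- unname(coef(fit)[1])
  structure(
    list(q10 = exp(10 * b), r_ref = exp(a + b * t_ref), t_ref = t_ref,
         fit = fit, n = nrow(d), n_excluded = n_excl, t_span = span,
         se_log_q10 = 10 * summary(fit)$coefficients[2, 2],
         r_squared = summary(fit)$r.squared),
    class = "q10_fit"
  )
}

#' @export
print.q10_fit <- function(x, ...) {
  cat("<q10_fit>\n")
  cat(sprintf("  Q10 = %.3f,  flux at %.0f degC = %.3f umol m-2 s-1\n",
              x$q10, x$t_ref, x$r_ref))
  cat(sprintf("  n = %d (excluded %d non-positive), T span %.1f degC, R2 = %.3f\n",
              x$n, x$n_excluded, x$t_span, x$r_squared))
  invisible(x)
}

#' @param object A `q10_fit`.
#' @param temperature Soil temperatures (degC) at which to predict.
#' @param ... Unused.
#' @rdname fit_q10
#' @export
predict.q10_fit <- function(object, temperature, ...) {
  object$r_ref * object$q10 ^ ((temperature - object$t_ref) / 10)
}

#' Cross-chamber spatial variability (coefficient of variation)
#'
#' For each hour with at least two reporting chambers in a treatment, the
#' CV is `100 * sd / mean` of the chamber fluxes (sample sd); the result
#' is the mean CV over hours, per treatment.  Hours whose mean flux is
#' near zero are skipped (their count is reported).  Chambers can be
#' excluded to probe the influence of efflux hot spots.
#'
#' @param fluxes Flux table from [compute_fluxes()].
#' @param period Optional (start, end) restriction.
#' @param exclude Chamber ids to exclude.
#' @param min_mean Hours with `|mean| <` this (umol m-2 s-1) are skipped.
#' @return Tibble with `treatment`, `cv_pct`, `n_hours`, `n_skipped`.
#' @export
chamber_cv <- function(fluxes, period = NULL, exclude = NULL,
                       min_mean = 0.05) {
  f <- dplyr::filter(fluxes, .data$usable)
  if (!is.null(period)) {
    period <- cf_time(period)
    f <- dplyr::filter(f, .data$time >= period[1], .data$time < period[2])
  }
  if (!is.null(exclude))
    f <- dplyr::filter(f, !.data$chamber %in% exclude)
  f %>%
    dplyr::mutate(hour = floor_hour(.data$time)) %>%
    dplyr::group_by(.data$treatment, .data$hour) %>%
    dplyr::summarise(n_ch = dplyr::n(), mu = mean(.data$flux),
                     sdv = sd(.data$flux), .groups = "drop") %>%
    dplyr::filter(.data$n_ch >= 2) %>%
    dplyr::group_by(.data$treatment) %>%
    dplyr::summarise(
      cv_pct = mean(100 * .data$sdv[abs(.data$mu) >= min_mean] /
                      .data$mu[abs(.data$mu) >= min_mean]),
      n_hours = sum(abs(.data$mu) >= min_mean),
      n_skipped = sum(abs(.data$mu) < min_mean),
      .groups = "drop"
    )
}

#' Aggregate an hourly flux series to daily carbon sums
#'
#' Converts an hourly efflux series (one value per hour, e.g. one chamber
#' or a treatment mean) into daily carbon emission: a flux of 1 umol CO2
#' m-2 s-1 sustained for one hour emits `12.011 * 3600 * 1e-6 = 0.04324`
#' g C m-2.  Hours without a usable value are optionally filled from a
#' fitted Q10 response evaluated at the measured soil temperature;
#' without gap-filling the daily sum scales the mean of the observed
#' hours to 24 h (days with no observations give `NA`).
#'
#' @param hourly Data frame with columns `hour` (POSIXct) and `flux`;
#'   when gap-filling, also `t_soil` for the missing hours (supplied via
#'   `temperature`).
#' @param gap_fill Optional `q10_fit` used to model missing hours.
#' @param temperature Optional data frame `hour`, `t_soil` providing soil
#'   temperature for every hour of the period (required with `gap_fill`).
#' @return Tibble of class `daily_sums`: `date`, `n_hours_obs`,
#'   `n_filled`, `flux_mean` (umol m-2 s-1), `g_c_m2`.
#' @seealso [annual_sums()]
#' @export
aggregate_fluxes <- function(hourly, gap_fill = NULL, temperature = NULL) {
  stopifnot(all(c("hour", "flux") %in% names(hourly)))
  h <- dplyr::distinct(hourly, .data$hour, .keep_all = TRUE)[, c("hour", "flux")]
  if (!is.null(gap_fill)) {
    if (is.null(temperature))
      stop("gap-filling requires a temperature series", call. = FALSE)
    stopifnot(inherits(gap_fill, "q10_fit"),
              all(c("hour", "t_soil") %in% names(temperature)))
    all_h <- dplyr::distinct(temperature, .data$hour, .keep_all = TRUE)
    h <- dplyr::full_join(all_h[, c("hour", "t_soil")], h, by = "hour") %>%
      dplyr::mutate(
        filled = !is.finite(.data$flux),
        flux = ifelse(.data$filled,
                      predict(gap_fill, .data$t_soil), .data$flux)
      )
  } else {
    h$filled <- FALSE
  }
  out <- h %>%
    dplyr::mutate(date = as.Date(.data$hour, tz = CF_TZ)) %>%
    dplyr::group_by(.data$date) %>%
    dplyr::summarise(
      n_hours_obs = sum(is.finite(.data$flux) & !.data$filled),
      n_filled = sum(.data$filled & is.finite(.data$flux)),
      flux_mean = mean(.data$flux[is.finite(.data$flux)]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(g_c_m2 = .data$flux_mean * 24 * GC_PER_UMOL_HOUR)
  structure(out, class = c("daily_sums", class(out)))
}

#' Annual carbon sums from daily sums
#'
#' Sums daily emissions within calendar years; `t_c_ha = g_c_m2 / 100`.
#' The annual total is exactly the sum of its daily sums; days with no
#' value propagate `NA` and are counted.
#'
#' @param daily Output of [aggregate_fluxes()].
#' @return Tibble with `year`, `n_days`, `n_missing_days`,
#'   `fill_fraction`, `g_c_m2`, `t_c_ha`.
#' @export
annual_sums <- function(daily) {
  daily %>%
    dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(
      n_days = dplyr::n(),
      n_missing_days = sum(!is.finite(.data$g_c_m2)),
      fill_fraction = sum(.data$n_filled) /
        pmax(1, sum(.data$n_filled) + sum(.data$n_hours_obs)),
      g_c_m2 = sum(.data$g_c_m2),
      .groups = "drop"
    ) %>%
    dplyr::mutate(t_c_ha = .data$g_c_m2 / 100)
}

#' Hourly treatment-mean flux series
#'
#' Averages usable closure fluxes across the chambers of each treatment,
#' per hour, and attaches the hourly mean measured 5-cm soil temperature
#' — the input shape for [fit_q10()] and [aggregate_fluxes()].
#'
#' @param fluxes Flux table from [compute_fluxes()].
#' @param env Optional environment table supplying `t_soil_c` per chamber;
#'   when `NULL`, soil temperature is not attached.
#' @param meta Chamber metadata.
#' @return Tibble `hour`, `treatment`, `flux`, `n_chambers` and (with
#'   `env`) `t_soil`.
#' @export
treatment_hourly <- function(fluxes, env = NULL, meta = chamber_layout()) {
  h <- fluxes %>%
    dplyr::filter(.data$usable) %>%
    dplyr::mutate(hour = floor_hour(.data$time)) %>%
    dplyr::group_by(.data$hour, .data$treatment) %>%
    dplyr::summarise(flux = mean(.data$flux), n_chambers = dplyr::n(),
                     .groups = "drop")
  if (!is.null(env)) {
    te <- env %>%
      dplyr::left_join(meta, by = "chamber") %>%
      dplyr::mutate(hour = floor_hour(.data$timestamp)) %>%
      dplyr::group_by(.data$hour, .data$treatment) %>%
      dplyr::summarise(t_soil = mean(.data$t_soil_c, na.rm = TRUE),
                       .groups = "drop")
    h <- dplyr::left_join(h, te, by = c("hour", "treatment"))
  }
  h
}

#' Daily coverage and missing-data accounting
#'
#' `daily_coverage()` classifies each calendar day of a flux table as
#' missing when fewer than `min_fraction` of the expected closures are
#' usable.  `missing_fraction()` turns missing/total day counts (or a
#' coverage table) into the summary percentage, reported to one decimal.
#'
#' @param fluxes Flux table from [compute_fluxes()].
#' @param expected_per_day Expected usable closures per day (chambers x
#'   cycles).
#' @param min_fraction Day is missing when usable closures fall below
#'   this fraction of expected.
#' @return `daily_coverage()`: tibble `date`, `n_usable`, `missing`.
#' @examples
#' missing_fraction(105, 2202)  # 4.8%
#' @export
daily_coverage <- function(fluxes, expected_per_day = 15 * 24,
                           min_fraction = 0.5) {
  rng <- range(as.Date(fluxes$time, tz = CF_TZ))
  tibble::tibble(date = seq(rng[1], rng[2], by = "day")) %>%
    dplyr::left_join(
      fluxes %>%
        dplyr::mutate(date = as.Date(.data$time, tz = CF_TZ)) %>%
        dplyr::group_by(.data$date) %>%
        dplyr::summarise(n_usable = sum(.data$usable), .groups = "drop"),
      by = "date") %>%
    dplyr::mutate(
      n_usable = dplyr::coalesce(.data$n_usable, 0L),
      missing = .data$n_usable < min_fraction * expected_per_day
    )
}

#' @param missing Number of missing days, or a coverage table from
#'   [daily_coverage()].
#' @param total Total measurement days (ignored when `missing` is a
#'   coverage table).
#' @rdname daily_coverage
#' @return `missing_fraction()`: tibble `missing_days`, `total_days`,
#'   `missing_pct` (one decimal).
#' @export
missing_fraction <- function(missing, total = NULL) {
  if (is.data.frame(missing)) {
    total <- nrow(missing)
    missing <- sum(missing$missing)
  }
  stopifnot(is.numeric(missing), is.numeric(total), total >= missing)
  tibble::tibble(
    missing_days = as.integer(missing),
    total_days = as.integer(total),
    missing_pct = round(100 * missing / total, 1)
  )
}
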