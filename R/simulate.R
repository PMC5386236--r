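#' Simulate a full measurement campaign with known ground truth
#'
#' Generates raw 10-s efflux records and half-hourly environment records for
#' a multichannel automated chamber campaign, together with a
#' [truth bundle][truth_bundle] holding the generating flux series, model
#' parameters, chamber offsets, and the positions of every injected fault
#' and outlier spike.  Within each cycle the chambers close sequentially
#' (chamber `c` from `(c-1)*closure_s` seconds past the hour); each closure
#' yields `closure_s / record_s` records whose noise-free concentration ramp
#' has slope
#' `flux_true * (T_air + 273.15) / (1000 * (V/S) / 8.314 * P_air)` ppm s-1,
#' i.e. the exact inverse of the linear flux estimator, so the pipeline
#' recovers the truth exactly in the noise-free case.  The first
#' `dead_band_records` records of each closure are rendered as a smooth
#' transition from ambient air onto the ramp (the dead band).
#'
#' Air temperature, 5-cm soil temperature and air pressure are held constant
#' within a single 240-s closure (their real within-closure drift is
#' negligible) and vary between closures with the forcing.  Soil warming
#' (temperature offset and flux response) is applied to warmed-trenched
#' chambers only, from `warming_start` onwards; before that the warmed
#' group behaves as ordinary trenched plots, providing the pre-treatment
#' calibration window.
#'
#' @param start,end Campaign start (inclusive) and end (exclusive); `Date`,
#'   POSIXct or string, interpreted in Japan standard time (UTC+9).
#' @param forcing A [site_forcing()].
#' @param flux_model A [true_flux_model()].
#' @param instrument An [instrument_model()].
#' @param meta Chamber metadata from [chamber_layout()]; defaults to the
#'   instrument's chamber count split evenly over the three treatments.
#' @param warming_start When the warming treatment switches on; defaults to
#'   `start` (warming active for the whole campaign).
#' @param seed Integer seed; identical seed and configuration give
#'   identical output.
#'
#' @return A list of class `chamber_campaign` with elements `raw`
#'   (record-level tibble in the raw dialect), `env` (half-hourly
#'   environment tibble), `truth` (a `truth_bundle`), and `meta`.
#' @examples
#' camp <- simulate_campaign("2009-07-01", "2009-07-02",
#'   instrument = instrument_model(n_chambers = 3), seed = 1)
#' dplyr::count(camp$raw, chamber)
#' @export
simulate_campaign <- function(start, end,
                              forcing = site_forcing(),
                              flux_model = true_flux_model(),
                              instrument = instrument_model(),
                              meta = NULL,
                              warming_start = NULL,
                              seed = 1) {
  start <- cf_time(start)
  end <- cf_time(end)
  if (as.numeric(end) - as.numeric(start) < 86400)
    stop("campaign period must be at least one day", call. = FALSE)
  if (is.null(warming_start)) warming_start <- start
  warming_start <- cf_time(warming_start)
  if (is.null(meta)) meta <- chamber_layout(instrument$n_chambers)
  if (!all(seq_len(instrument$n_chambers) %in% meta$chamber))
    stop("meta must cover chambers 1..", instrument$n_chambers, call. = FALSE)
  meta <- dplyr::filter(meta, .data$chamber <= instrument$n_chambers)

  withr::with_seed(seed, {
    offsets <- draw_chamber_offsets(flux_model, meta)

    ## --- closure grid -------------------------------------------------
    hour_sec <- seq(as.numeric(start), as.numeric(end) - 1,
                    by = instrument$cycle_s)
    n_h <- length(hour_sec)
    p_site <- 101.32 + rnorm(n_h, 0, 0.3)       # synoptic pressure, kPa

    cl <- tidyr::expand_grid(
      hour_sec = hour_sec,
      chamber = seq_len(instrument$n_chambers)
    ) %>%
      dplyr::left_join(meta, by = "chamber") %>%
      dplyr::mutate(
        start_sec = .data$hour_sec +
          (.data$chamber - 1) * instrument$closure_s,
        time = .POSIXct(.data$start_sec, tz = CF_TZ),
        p_air = rep(p_site, each = instrument$n_chambers),
        warmed = .data$treatment == "warmed_trenched" &
          .data$start_sec >= as.numeric(warming_start)
      )

    tf <- true_flux_tbl(cl, forcing, flux_model, offsets)
    cl <- dplyr::bind_cols(cl, tf) %>%
      dplyr::mutate(
        slope_true = .data$flux_true * (.data$t_air + 273.15) /
          (flux_coefficient(.data$vs_ratio) * .data$p_air),
        c0 = instrument$ambient_co2 + rnorm(dplyr::n(), 0, 1)
      )

    ## --- expand to 10-s records --------------------------------------
    nrec <- instrument$records_per_closure
    offs <- (seq_len(nrec) - 1) * instrument$record_s
    idx <- rep(seq_len(nrow(cl)), each = nrec)
    ot <- rep(offs, nrow(cl))
    lag <- instrument$dead_band_records * instrument$record_s
    s <- cl$slope_true[idx]
    c_clean <- cl$c0[idx] +
      if (lag > 0) {
        ifelse(ot <= lag, s * ot^2 / (2 * lag), s * (ot - lag / 2))
      } else {
        s * ot
      }
    n_rec <- length(ot)
    co2 <- c_clean + rnorm(n_rec, 0, instrument$co2_noise_sd)

    spikes <- tibble::tibble(timestamp = .POSIXct(numeric(0), tz = CF_TZ),
                             chamber = integer(0))
    if (instrument$spike_rate > 0) {
      hit <- which(runif(n_rec) < instrument$spike_rate)
      if (length(hit) > 0) {
        mag <- sample(c(-1, 1), length(hit), replace = TRUE) *
          instrument$spike_sd * runif(length(hit), 0.8, 1.3)
        co2[hit] <- co2[hit] + mag
        spikes <- tibble::tibble(
          timestamp = .POSIXct(cl$start_sec[idx[hit]] + ot[hit], tz = CF_TZ),
          chamber = cl$chamber[idx[hit]]
        )
      }
    }

    raw <- tibble::tibble(
      timestamp = .POSIXct(cl$start_sec[idx] + ot, tz = CF_TZ),
      chamber = cl$chamber[idx],
      co2_ppm = co2,
      flow_lpm = pmax(0, instrument$flow_lpm + rnorm(n_rec, 0, 0.05)),
      p_air_kpa = cl$p_air[idx],
      p_cell_kpa = cl$p_air[idx] + instrument$p_cell_offset_kpa,
      t_air_c = cl$t_air[idx],
      t_soil_c = cl$t_soil[idx]
    )

    fault_log <- NULL
    if (!is.null(instrument$faults)) {
      raw <- inject_fault(raw, instrument$faults, instrument)
      fault_log <- attr(raw, "fault_log")
    }

    ## --- environment records -----------------------------------------
    env_sec <- seq(as.numeric(start), as.numeric(end) - 1, by = 1800)
    env_time <- .POSIXct(env_sec, tz = CF_TZ)
    vwc_site <- simulate_moisture(forcing, env_time)
    ch_vwc_off <- rnorm(nrow(meta), 0, 0.02)
    t_amb <- air_temperature(forcing, env_time) + rnorm(length(env_sec), 0, 0.2)
    rh <- pmin(100, pmax(30,
      75 - 15 * cos(2 * pi * (cf_hour(env_time) - 15) / 24) +
        rnorm(length(env_sec), 0, 3)))
    env <- tidyr::expand_grid(i = seq_along(env_sec), chamber = meta$chamber) %>%
      dplyr::left_join(meta, by = "chamber") %>%
      dplyr::mutate(
        timestamp = env_time[.data$i],
        warmed = .data$treatment == "warmed_trenched" &
          env_sec[.data$i] >= as.numeric(warming_start),
        t_soil_c = soil_temperature(forcing, .data$timestamp,
                                    warmed = .data$warmed) +
          rnorm(dplyr::n(), 0, 0.05),
        vwc = pmin(0.6, pmax(0, vwc_site[.data$i] +
                               ch_vwc_off[match(.data$chamber, meta$chamber)])),
        t_air_amb_c = t_amb[.data$i],
        rh = rh[.data$i]
      ) %>%
      dplyr::select("timestamp", "chamber", "t_soil_c", "vwc",
                    "t_air_amb_c", "rh")

    truth <- structure(
      list(
        flux = dplyr::select(cl, "time", "chamber", "treatment",
                             "flux_true", "slope_true", "t_soil", "t_air",
                             "warmed"),
        q10 = flux_model$q10, t_ref = flux_model$t_ref,
        fe = flux_model$fe,
        warming_offset = forcing$warming_offset,
        warming_start = warming_start,
        chamber_offsets = offsets,
        faults = fault_log %||% validate_faults(
          tibble::tibble(type = character(0), chamber = integer(0),
                         start = .POSIXct(numeric(0), tz = CF_TZ),
                         end = .POSIXct(numeric(0), tz = CF_TZ),
                         param = numeric(0))),
        spikes = spikes,
        dead_band = list(records = instrument$dead_band_records,
                         lag_s = lag),
        seed = seed
      ),
      class = "truth_bundle"
    )

    structure(
      list(raw = raw, env = env, truth = truth, meta = meta,
           instrument = instrument, forcing = forcing,
           flux_model = flux_model, period = c(start, end)),
      class = "chamber_campaign"
    )
  })
}

#' @export
print.chamber_campaign <- function(x, ...) {
  cat("<chamber_campaign>\n")
  cat(sprintf("  %s to %s, %d chambers\n",
              format(x$period[1]), format(x$period[2]), nrow(x$meta)))
  cat(sprintf("  %s raw records, %s environment records\n",
              format(nrow(x$raw), big.mark = ","),
              format(nrow(x$env), big.mark = ",")))
  cat(sprintf("  truth: Q10 %.2f, Fe %.1f %%/degC, %d fault(s), %d spike(s)\n",
              x$truth$q10, x$truth$fe, nrow(x$truth$faults),
              nrow(x$truth$spikes)))
  invisible(x)
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("<truth_bundle>\n")
  cat(sprintf("  %s true closure fluxes; Q10 %.2f, Fe %.1f %%/degC, warming +%.1f degC\n",
              format(nrow(x$flux), big.mark = ","), x$q10, x$fe,
              x$warming_offset))
  cat(sprintf("  %d fault(s), %d spike(s), dead band %d records\n",
              nrow(x$faults), nrow(x$spikes), x$dead_band$records))
  invisible(x)
}

## Mean-one lognormal spatial offsets, with optional hot spot.
draw_chamber_offsets <- function(flux_model, meta) {
  n <- nrow(meta)
  off <- rlnorm(n, -flux_model$spatial_sd^2 / 2, flux_model$spatial_sd)
  tib <- tibble::tibble(chamber = meta$chamber, offset = off)
  if (!is.na(flux_model$hot_spot_chamber) &&
      flux_model$hot_spot_chamber %in% tib$chamber) {
    tib$offset[tib$chamber == flux_model$hot_spot_chamber] <-
      tib$offset[tib$chamber == flux_model$hot_spot_chamber] *
      flux_model$hot_spot_factor
  }
  tib
}

## True flux, soil and air temperature for a closure table with columns
## time, chamber, treatment, warmed.  Returns tibble(t_air, t_soil, flux_true).
true_flux_tbl <- function(cl, forcing, flux_model, offsets) {
  t_air <- air_temperature(forcing, cl$time)
  t_soil_un <- soil_temperature(forcing, cl$time, warmed = FALSE)
  t_soil <- t_soil_un + ifelse(cl$warmed, forcing$warming_offset, 0)
  base <- ifelse(cl$treatment == "control",
                 flux_model$base_control, flux_model$base_trenched)
  off <- offsets$offset[match(cl$chamber, offsets$chamber)]
  flux <- base * off *
    flux_model$q10 ^ ((t_soil_un - flux_model$t_ref) / 10) *
    ifelse(cl$warmed, 1 + flux_model$fe / 100 * forcing$warming_offset, 1)
  tibble::tibble(t_air = t_air, t_soil = t_soil, flux_true = flux)
}

#' Inject instrument faults into raw records
#'
#' Applies the fault table to generated raw records.  `pump_stop` holds the
#' concentration at its closure-start value for the first half of the
#' closure, then lets it decay slowly (the stagnant analyser cell), and
#' drops the flow column to near zero — the classic signature of a stopped
#' sampling pump or stuck valve.  `leak` turns the linear ramp into a
#' saturating curve with rate `param` s-1 (`param = 0` leaves records
#' unchanged).  `fan` inflates record-to-record scatter by factor `param`
#' (poorly mixed chamber air).
#'
#' Closure membership is derived from the instrument schedule (chamber `c`
#' closes at `(c-1)*closure_s` seconds past each cycle).
#'
#' @param raw Raw record tibble (see [simulate_campaign()]).
#' @param faults Fault table from [fault_spec()].
#' @param instrument The [instrument_model()] describing the schedule.
#' @return `raw` with faults applied; the realised fault log (windows
#'   clipped to the data, defaults filled) is attached as attribute
#'   `"fault_log"`.
#' @export
inject_fault <- function(raw, faults, instrument = instrument_model()) {
  faults <- validate_faults(faults)
  sec <- as.numeric(raw$timestamp)
  cyc <- floor(sec / instrument$cycle_s)
  in_cycle <- sec - cyc * instrument$cycle_s
  ot <- in_cycle - (raw$chamber - 1) * instrument$closure_s
  closure_key <- paste(raw$chamber, cyc)

  rng <- range(sec)
  for (i in seq_len(nrow(faults))) {
    f <- faults[i, ]
    if (as.numeric(f$end) < rng[1] || as.numeric(f$start) > rng[2])
      stop("fault window ", format(f$start), " - ", format(f$end),
           " lies outside the generated period", call. = FALSE)
    rows <- which(raw$chamber == f$chamber &
                    sec >= as.numeric(f$start) & sec < as.numeric(f$end))
    if (length(rows) == 0) next
    if (f$type == "pump_stop") {
      plateau <- instrument$closure_s / 2
      tau <- if (is.na(f$param)) 800 else f$param
      for (key in unique(closure_key[rows])) {
        r <- rows[closure_key[rows] == key]
        c0 <- raw$co2_ppm[r[which.min(ot[r])]]
        dec <- pmax(0, ot[r] - plateau)
        raw$co2_ppm[r] <- c0 * exp(-dec / tau) + rnorm(length(r), 0, 0.3)
        raw$flow_lpm[r] <- pmax(0, rnorm(length(r), 0.05, 0.02))
        faults$param[i] <- tau
      }
    } else if (f$type == "leak") {
      lambda <- if (is.na(f$param)) 0.01 else f$param
      faults$param[i] <- lambda
      if (lambda > 0) {
        for (key in unique(closure_key[rows])) {
          r <- rows[closure_key[rows] == key]
          c0 <- raw$co2_ppm[r[which.min(ot[r])]]
          otr <- ot[r]
          shrink <- ifelse(otr > 0, (1 - exp(-lambda * otr)) / (lambda * otr), 1)
          raw$co2_ppm[r] <- c0 + (raw$co2_ppm[r] - c0) * shrink
        }
      }
    } else if (f$type == "fan") {
      fac <- if (is.na(f$param)) 8 else f$param
      faults$param[i] <- fac
      raw$co2_ppm[rows] <- raw$co2_ppm[rows] +
        rnorm(length(rows), 0, fac * max(instrument$co2_noise_sd, 0.1))
    }
  }
  attr(raw, "fault_log") <- faults
  raw
}

cf_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date")) return(as.POSIXct(format(x), tz = CF_TZ))
  as.POSIXct(x, tz = CF_TZ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
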