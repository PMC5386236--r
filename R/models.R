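#' True efflux model for synthetic campaigns
#'
#' Defines the ground-truth soil CO2 efflux generating process: an
#' exponential (Q10) temperature response around a reference temperature,
#' treatment-specific baselines (control vs root-trenched), multiplicative
#' per-chamber spatial offsets (lognormal, optionally with one "hot spot"
#' chamber), and a warming response expressed as a percentage increase per
#' degC of soil warming (Fe).  The warmed-trenched true flux is the trenched
#' response evaluated at the *unwarmed* soil temperature multiplied by
#' `1 + fe/100 * warming_offset`, so Fe encapsulates the entire warming
#' response and is exactly the quantity the warming-effect estimator
#' recovers.
#'
#' Baselines default to 1.65 (control) and 1.25 (trenched)
#' umol CO2 m-2 s-1 at 10 degC, which under the default forcing put the
#' simulated annual sums near observed warm-temperate forest values
#' (roughly 16 and 12 tC ha-1 yr-1 for total and heterotrophic efflux).
#'
#' @param q10 Multiplicative change in efflux per 10 degC (dimensionless, > 0).
#' @param t_ref Reference temperature, degC.
#' @param base_control,base_trenched Reference efflux at `t_ref` for control
#'   and trenched treatments, umol CO2 m-2 s-1.
#' @param fe Warming effect, percent increase in heterotrophic efflux per
#'   degC of soil warming.
#' @param spatial_sd Standard deviation (log scale) of the lognormal
#'   per-chamber multiplicative offsets; offsets are mean-one.
#' @param hot_spot_chamber Optional chamber id given an anomalously large
#'   offset (an efflux "hot spot"); `NA` for none.
#' @param hot_spot_factor Multiplier applied to the hot-spot chamber.
#' @param moisture_effect Optional multiplicative moisture modifier; `NULL`
#'   (default, off) or a function `f(vwc)` returning a positive multiplier.
#'
#' @return An object of class `true_flux_model`.
#' @export
true_flux_model <- function(q10 = 2.5, t_ref = 10,
                            base_control = 1.65, base_trenched = 1.25,
                            fe = 9.4, spatial_sd = 0.25,
                            hot_spot_chamber = NA_integer_,
                            hot_spot_factor = 3,
                            moisture_effect = NULL) {
  stopifnot(q10 > 0, base_control > 0, base_trenched > 0, spatial_sd >= 0,
            hot_spot_factor > 0,
            is.null(moisture_effect) || is.function(moisture_effect))
  structure(
    list(q10 = q10, t_ref = t_ref,
         base_control = base_control, base_trenched = base_trenched,
         fe = fe, spatial_sd = spatial_sd,
         hot_spot_chamber = hot_spot_chamber,
         hot_spot_factor = hot_spot_factor,
         moisture_effect = moisture_effect),
    class = "true_flux_model"
  )
}

#' @export
print.true_flux_model <- function(x, ...) {
  cat("<true_flux_model>\n")
  cat(sprintf("  Q10 %.2f at T_ref %.1f degC; baselines control %.2f, trenched %.2f umol m-2 s-1\n",
              x$q10, x$t_ref, x$base_control, x$base_trenched))
  cat(sprintf("  warming effect Fe %.1f %% per degC; spatial sd %.2f (log)\n",
              x$fe, x$spatial_sd))
  if (!is.na(x$hot_spot_chamber))
    cat(sprintf("  hot spot: chamber %d x %.1f\n",
                x$hot_spot_chamber, x$hot_spot_factor))
  invisible(x)
}

#' Instrument model: schedule, noise and fault injection
#'
#' Describes the multichannel automated chamber system being emulated: 15
#' chambers closed sequentially for 240 s each within a one-hour cycle,
#' 10-s averaged records (24 per closure), a dead band of a few records
#' after lid closure while chamber air reaches the analyser, Gaussian
#' analyser noise on the CO2 mole fraction, a pump holding the analyser
#' cell a few kPa above ambient, and optional instrument faults.
#'
#' @param n_chambers Number of chambers sampled sequentially per cycle.
#' @param closure_s Closure (sampling) length per chamber, seconds.
#' @param record_s Record averaging interval, seconds.
#' @param cycle_s Full measurement cycle, seconds.
#' @param dead_band_records Number of initial records per closure rendered as
#'   a transition between ambient air and the concentration ramp (the dead
#'   band, typically 2-3 records / 20-30 s).
#' @param co2_noise_sd Gaussian noise sd on each 10-s CO2 record, ppm.
#' @param ambient_co2 Ambient CO2 mole fraction at lid closure, ppm.
#' @param p_cell_offset_kpa Analyser cell pressure minus chamber-height
#'   ambient pressure, kPa.
#' @param flow_lpm Nominal pump flow, l min-1.
#' @param spike_rate Per-record probability of an isolated outlier spike.
#' @param spike_sd Spike magnitude sd, ppm.
#' @param faults Optional fault table from [fault_spec()].
#'
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(n_chambers = 15, closure_s = 240, record_s = 10,
                             cycle_s = 3600, dead_band_records = 3,
                             co2_noise_sd = 0.5, ambient_co2 = 400,
                             p_cell_offset_kpa = 5, flow_lpm = 5,
                             spike_rate = 0, spike_sd = 10,
                             faults = NULL) {
  if (n_chambers * closure_s > cycle_s)
    stop("infeasible schedule: ", n_chambers, " closures of ", closure_s,
         " s exceed the ", cycle_s, " s cycle", call. = FALSE)
  if (closure_s %% record_s != 0)
    stop("closure_s must be a multiple of record_s", call. = FALSE)
  stopifnot(dead_band_records >= 0, co2_noise_sd >= 0, spike_rate >= 0,
            spike_rate <= 1)
  if (!is.null(faults)) faults <- validate_faults(faults)
  structure(
    list(n_chambers = n_chambers, closure_s = closure_s, record_s = record_s,
         cycle_s = cycle_s, records_per_closure = closure_s %/% record_s,
         dead_band_records = dead_band_records,
         co2_noise_sd = co2_noise_sd, ambient_co2 = ambient_co2,
         p_cell_offset_kpa = p_cell_offset_kpa, flow_lpm = flow_lpm,
         spike_rate = spike_rate, spike_sd = spike_sd, faults = faults),
    class = "instrument_model"
  )
}

#' @export
print.instrument_model <- function(x, ...) {
  cat("<instrument_model>\n")
  cat(sprintf("  %d chambers x %d s closures, %d-s records (%d/closure), %d-s cycle\n",
              x$n_chambers, x$closure_s, x$record_s, x$records_per_closure,
              x$cycle_s))
  cat(sprintf("  dead band %d records; CO2 noise sd %.2f ppm; cell pressure +%.1f kPa\n",
              x$dead_band_records, x$co2_noise_sd, x$p_cell_offset_kpa))
  if (!is.null(x$faults))
    cat(sprintf("  %d fault(s) configured\n", nrow(x$faults)))
  invisible(x)
}

#' Closure schedule and chamber duty cycle
#'
#' Returns one row per chamber with its closure start offset within the
#' cycle and the closed/open minutes per cycle.  With the default schedule
#' each chamber is closed 4 min and open 56 min per hour (93% open).
#'
#' @param instrument An [instrument_model()].
#' @return A tibble with columns `chamber`, `start_offset_s`, `closed_min`,
#'   `open_min`, `open_fraction`.
#' @examples
#' closure_schedule(instrument_model())
#' @export
closure_schedule <- function(instrument = instrument_model()) {
  tibble::tibble(
    chamber = seq_len(instrument$n_chambers),
    start_offset_s = (seq_len(instrument$n_chambers) - 1) * instrument$closure_s,
    closed_min = instrument$closure_s / 60,
    open_min = (instrument$cycle_s - instrument$closure_s) / 60,
    open_fraction = (instrument$cycle_s - instrument$closure_s) /
      instrument$cycle_s
  )
}

#' Chamber metadata: treatment assignment and geometry
#'
#' Chambers are divided into consecutive groups assigned to the treatments
#' in order (default: 1-5 control, 6-10 trenched, 11-15 warmed-trenched),
#' each with the same effective volume-to-surface ratio V/S.
#'
#' @param n_chambers Number of chambers.
#' @param treatments Treatment labels, assigned in consecutive blocks.
#' @param vs_ratio Effective chamber volume / soil surface area, m.
#' @return A tibble with columns `chamber`, `treatment`, `vs_ratio`.
#' @export
chamber_layout <- function(n_chambers = 15,
                           treatments = c("control", "trenched",
                                          "warmed_trenched"),
                           vs_ratio = 0.5) {
  stopifnot(n_chambers >= 1, vs_ratio > 0)
  k <- length(treatments)
  tibble::tibble(
    chamber = seq_len(n_chambers),
    treatment = treatments[pmin(k, ceiling(seq_len(n_chambers) / max(1, ceiling(n_chambers / k))))],
    vs_ratio = vs_ratio
  )
}

#' Specify instrument faults to inject
#'
#' @param type One of `"pump_stop"` (air flow through the analyser stops:
#'   concentration plateaus then slowly decays, flow drops to ~0),
#'   `"leak"` (chamber lid leak: the concentration ramp saturates with rate
#'   `param`, s-1; `param = 0` is a no-op), `"fan"` (mixing fan stops:
#'   record-to-record scatter inflated by factor `param`).
#' @param chamber Affected chamber id.
#' @param start,end POSIXct fault window.
#' @param param Fault parameter (see `type`); `NA` uses the type default.
#' @return A tibble usable as the `faults` argument of [instrument_model()]
#'   or with [inject_fault()].  Multiple calls can be row-bound.
#' @export
fault_spec <- function(type, chamber, start, end, param = NA_real_) {
  validate_faults(tibble::tibble(
    type = type, chamber = as.integer(chamber),
    start = start, end = end, param = as.numeric(param)
  ))
}

FAULT_TYPES <- c("pump_stop", "leak", "fan")

validate_faults <- function(faults) {
  faults <- tibble::as_tibble(faults)
  need <- c("type", "chamber", "start", "end")
  if (!all(need %in% names(faults)))
    stop("fault spec needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(faults$type), FAULT_TYPES)
  if (length(bad) > 0)
    stop("unknown fault type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!"param" %in% names(faults)) faults$param <- NA_real_
  if (any(as.numeric(faults$end) <= as.numeric(faults$start)))
    stop("fault windows must have end > start", call. = FALSE)
  faults
}
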