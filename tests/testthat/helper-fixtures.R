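## Shared fixtures, generated in code.

suppressPackageStartupMessages(library(dplyr))

cf_tz <- "Etc/GMT-9"

ptime <- function(x) as.POSIXct(x, tz = cf_tz)

## One closure segment on an exact line, optionally with noise.
make_ramp <- function(n = 24, dt = 10, c0 = 400, slope = 0.1,
                      noise = 0, t_air = 25, p_air = 101.32,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  off <- (seq_len(n) - 1) * dt
  tibble::tibble(
    offset_s = off,
    co2_ppm = c0 + slope * off + rnorm(n, 0, noise),
    t_air_c = t_air,
    p_air_kpa = p_air
  )
}

## Small noise-free campaign used by several round-trip tests.
quiet_campaign <- function(days = 1, n_chambers = 3, seed = 5, ...) {
  simulate_campaign(
    "2009-07-01", sprintf("2009-07-%02d", 1 + days),
    instrument = instrument_model(n_chambers = n_chambers,
                                  co2_noise_sd = 0, ...),
    seed = seed
  )
}
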