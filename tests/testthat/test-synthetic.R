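test_that("seasonal temperature passes through the anchor monthly values", {
  f <- site_forcing()
  # anchor days of year 15 (mid-January) and 227 (the mid-August peak)
  expect_equal(seasonal_temperature(f, ptime("2009-01-16 00:00")), 7.0,
               tolerance = 1e-6)
  expect_equal(seasonal_temperature(f, ptime("2009-08-16 00:00")), 27.9,
               tolerance = 1e-6)
  # diel cycle peaks mid-afternoon
  d <- ptime(sprintf("2009-05-01 %02d:00", 0:23))
  expect_equal(which.max(air_temperature(f, d)), 16)  # 15:00 is element 16
})

test_that("warming offset is applied only to warmed chambers, at the configured level", {
  camp <- simulate_campaign("2009-03-01", "2009-03-04", seed = 7)
  env <- dplyr::left_join(camp$env, camp$meta, by = "chamber")
  m <- tapply(env$t_soil_c, env$treatment, mean)
  expect_equal(unname(m["warmed_trenched"] - m["trenched"]), 2.5,
               tolerance = 0.05)
  expect_equal(unname(m["control"] - m["trenched"]), 0, tolerance = 0.05)
  expect_true(all(env$vwc >= 0 & env$vwc <= 0.6))
})

test_that("identical seed and configuration give identical output", {
  a <- quiet_campaign(seed = 42)
  b <- quiet_campaign(seed = 42)
  expect_identical(a$raw, b$raw)
  expect_identical(a$env, b$env)
  expect_identical(a$truth$flux, b$truth$flux)
  fa <- file.path(tempdir(), "a.csv"); fb <- file.path(tempdir(), "b.csv")
  write_raw(a$raw, fa); write_raw(b$raw, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  c <- quiet_campaign(seed = 43)
  expect_false(identical(a$raw$co2_ppm, c$raw$co2_ppm))
})

test_that("schedule arithmetic: each chamber closed 4 min, open 56 min per hour", {
  sch <- closure_schedule(instrument_model())
  expect_equal(nrow(sch), 15)
  expect_true(all(sch$closed_min == 4))
  expect_true(all(sch$open_min == 56))
  expect_equal(unique(sch$open_fraction), 56 / 60)
  # every chamber emits exactly closure_s/record_s records per cycle
  camp <- quiet_campaign(days = 1, n_chambers = 15)
  cnt <- dplyr::count(camp$raw, chamber)
  expect_true(all(cnt$n == 24 * 24))
})

test_that("infeasible schedules and degenerate periods are rejected", {
  expect_error(instrument_model(n_chambers = 16), "infeasible")
  expect_error(instrument_model(n_chambers = 10, closure_s = 245),
               "multiple")
  expect_error(simulate_campaign("2009-01-01", "2009-01-01"), "one day")
  expect_error(simulate_campaign("2009-01-02", "2009-01-01"), "one day")
})

test_that("dead-band records deviate below the ramp and are recoverable", {
  inst <- instrument_model(n_chambers = 1, co2_noise_sd = 0,
                           dead_band_records = 3)
  camp <- simulate_campaign("2009-07-01", "2009-07-02",
                            instrument = inst, seed = 1)
  one <- dplyr::filter(camp$raw,
                       camp$raw$timestamp < ptime("2009-07-01 01:00"))
  tr <- camp$truth$flux[1, ]
  # retained part is an exact line with the true slope
  late <- one[one$timestamp >= one$timestamp[1] + 30, ]
  fit <- lm(co2_ppm ~ I(as.numeric(timestamp - timestamp[1])), data = late)
  expect_equal(unname(coef(fit)[2]), tr$slope_true, tolerance = 1e-10)
  # dead-band records deviate from that line's backward extension
  t0 <- as.numeric(late$timestamp[1])
  early <- one[as.numeric(one$timestamp) < t0, ]
  pred <- coef(fit)[1] + coef(fit)[2] * (as.numeric(early$timestamp) - t0)
  expect_true(all(abs(early$co2_ppm - pred) > 1e-6))
})

test_that("spike injection is logged in the truth bundle", {
  inst <- instrument_model(n_chambers = 2, spike_rate = 0.01)
  camp <- simulate_campaign("2009-07-01", "2009-07-02",
                            instrument = inst, seed = 3)
  expect_gt(nrow(camp$truth$spikes), 0)
  expect_true(all(camp$truth$spikes$chamber %in% 1:2))
  # spikes stand out from a noise-free replay at the same seed
  quietc <- simulate_campaign("2009-07-01", "2009-07-02",
                              instrument = instrument_model(n_chambers = 2),
                              seed = 3)
  expect_equal(nrow(quietc$truth$spikes), 0)
})

test_that("pump-stop fault: plateau then decay, flow drops, logged in truth", {
  f <- fault_spec("pump_stop", 2, ptime("2009-07-01 05:00"),
                  ptime("2009-07-01 06:00"))
  inst <- instrument_model(n_chambers = 3, faults = f)
  camp <- simulate_campaign("2009-07-01", "2009-07-02",
                            instrument = inst, seed = 6)
  expect_equal(nrow(camp$truth$faults), 1)
  aff <- dplyr::filter(camp$raw, camp$raw$chamber == 2,
                       camp$raw$timestamp >= ptime("2009-07-01 05:00"),
                       camp$raw$timestamp < ptime("2009-07-01 06:00"))
  expect_true(all(aff$flow_lpm < 0.5))
  # concentration ends below where it started (decay), having plateaued
  expect_lt(tail(aff$co2_ppm, 1), aff$co2_ppm[1])
  expect_lt(abs(aff$co2_ppm[6] - aff$co2_ppm[1]), 2)
})

test_that("leak fault with zero attenuation is the identity; unknown types rejected", {
  base <- quiet_campaign(seed = 9)
  f0 <- fault_spec("leak", 1, ptime("2009-07-01 00:00"),
                   ptime("2009-07-01 12:00"), param = 0)
  out <- inject_fault(base$raw, f0, instrument_model(n_chambers = 3,
                                                     co2_noise_sd = 0))
  expect_equal(out$co2_ppm, base$raw$co2_ppm)
  fl <- fault_spec("leak", 1, ptime("2009-07-01 00:00"),
                   ptime("2009-07-01 12:00"), param = 0.02)
  out2 <- inject_fault(base$raw, fl, instrument_model(n_chambers = 3,
                                                      co2_noise_sd = 0))
  ch1 <- base$raw$chamber == 1 &
    base$raw$timestamp < ptime("2009-07-01 12:00")
  # saturation attenuates the rise but keeps it monotone
  expect_true(all(out2$co2_ppm[ch1] <= base$raw$co2_ppm[ch1] + 1e-9))
  expect_error(fault_spec("volcano", 1, ptime("2009-07-01 00:00"),
                          ptime("2009-07-01 01:00")), "unknown fault")
  expect_error(
    inject_fault(base$raw,
                 fault_spec("leak", 1, ptime("2012-01-01 00:00"),
                            ptime("2012-01-02 00:00"))),
    "outside the generated period")
})

test_that("hot-spot chamber receives the configured multiplier", {
  fm <- true_flux_model(hot_spot_chamber = 5L, hot_spot_factor = 3)
  camp <- simulate_campaign("2009-07-01", "2009-07-02", flux_model = fm,
                            instrument = instrument_model(co2_noise_sd = 0),
                            seed = 12)
  off <- camp$truth$chamber_offsets
  others <- off$offset[off$chamber != 5]
  expect_gt(off$offset[off$chamber == 5], max(others))
})
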