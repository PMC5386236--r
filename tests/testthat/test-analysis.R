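## Build a toy flux table directly: hourly closures for given chambers.
toy_fluxes <- function(values, treatments, hours = 24,
                       start = "2009-01-01") {
  n_ch <- length(values)
  tidyr::expand_grid(h = seq_len(hours) - 1, ch = seq_len(n_ch)) %>%
    dplyr::mutate(
      time = ptime(start) + h * 3600 + (ch - 1) * 240,
      chamber = ch,
      treatment = treatments[ch],
      flux = values[ch],
      usable = TRUE
    )
}

test_that("calibration coefficients follow the group-mean ratio", {
  # identical chambers -> Qc = 1 for both groups
  fx <- toy_fluxes(rep(2, 4), rep(c("trenched", "warmed_trenched"), each = 2))
  cal <- calibrate_qc(fx, window = c("2009-01-01", "2009-01-02"))
  expect_equal(cal$qc, c(1, 1))
  # trenched-group mean 2.0, warmed-group mean 1.6 -> all-mean 1.8,
  # Qcw = 1.8/1.6 = 1.125, Qch = 0.9; with reference = warmed pair removed:
  fx2 <- toy_fluxes(c(2, 2, 1.6, 1.6),
                    rep(c("trenched", "warmed_trenched"), each = 2))
  cal2 <- calibrate_qc(fx2, window = c("2009-01-01", "2009-01-02"))
  expect_equal(cal2$qc[cal2$treatment == "warmed_trenched"], 1.8 / 1.6)
  expect_equal(cal2$qc[cal2$treatment == "trenched"], 1.8 / 2.0)
  # reference restricted to trenched-only reproduces the 2.0 / 1.6 = 1.25 case
  cal3 <- calibrate_qc(fx2, window = c("2009-01-01", "2009-01-02"),
                       treatments = "warmed_trenched",
                       reference_treatments = "trenched")
  expect_equal(cal3$qc, 1.25)
  expect_error(calibrate_qc(fx2, window = c("2010-01-01", "2010-01-02")),
               "no usable fluxes")
  expect_error(calibrate_qc(fx2[fx2$treatment == "trenched", ],
                            window = c("2009-01-01", "2009-01-02")),
               "absent")
})

test_that("warming effect arithmetic matches the defining equation", {
  fx <- toy_fluxes(c(2.0, 2.5), c("trenched", "warmed_trenched"))
  env <- tidyr::expand_grid(
    timestamp = ptime("2009-01-01") + seq(0, 23 * 3600, 1800),
    chamber = 1:2
  ) %>%
    dplyr::mutate(t_soil_c = ifelse(chamber == 2, 12.5, 10),
                  vwc = 0.3, t_air_amb_c = 10, rh = 70)
  cal <- tibble::tibble(treatment = c("trenched", "warmed_trenched"),
                        qc = c(1, 1))
  meta <- tibble::tibble(chamber = 1:2,
                         treatment = c("trenched", "warmed_trenched"),
                         vs_ratio = 0.5)
  we <- warming_effect(fx, env, cal, meta,
                       period = c("2009-01-01", "2009-01-02"))
  # (2.5 - 2.0) / (2.0 * 2.5) * 100 = 10 % per degC
  expect_equal(we$fe, 10)
  expect_equal(we$dt, 2.5)
  # equal calibrated means -> Fe = 0
  fx0 <- toy_fluxes(c(2.0, 2.0), c("trenched", "warmed_trenched"))
  expect_equal(warming_effect(fx0, env, cal, meta,
                              period = c("2009-01-01", "2009-01-02"))$fe, 0)
  # deltaT ~ 0 is undefined per degree
  env0 <- dplyr::mutate(env, t_soil_c = 10)
  expect_error(warming_effect(fx, env0, cal, meta,
                              period = c("2009-01-01", "2009-01-02")),
               "undefined")
  # per-hour formulation agrees for constant series
  weh <- warming_effect(fx, env, cal, meta,
                        period = c("2009-01-01", "2009-01-02"),
                        per_hour = TRUE)
  expect_equal(weh$fe, 10)
})

test_that("Q10 fitting is exact on noise-free exponentials and guards degeneracy", {
  t <- seq(5, 25, 0.25)
  d <- data.frame(t_soil = t, flux = 2 * 2.5 ^ ((t - 10) / 10))
  fit <- fit_q10(d)
  expect_equal(fit$q10, 2.5, tolerance = 1e-10)
  expect_equal(fit$r_ref, 2, tolerance = 1e-10)
  expect_equal(predict(fit, 20), 5, tolerance = 1e-9)
  # constant temperature is unidentifiable
  expect_error(fit_q10(data.frame(t_soil = rep(10, 50), flux = rep(2, 50))),
               "not identifiable")
  expect_error(fit_q10(d[1:10, ]), "at least")
  # non-positive fluxes are excluded and counted
  d2 <- d
  d2$flux[1:5] <- -1
  fit2 <- fit_q10(d2)
  expect_equal(fit2$n_excluded, 5)
  expect_equal(fit2$q10, 2.5, tolerance = 1e-6)
  # tidy/glance surface the estimates
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "q10"], 2.5, tolerance = 1e-10)
  expect_equal(glance(fit)$nobs, nrow(d))
})

test_that("chamber CV follows the sample-sd definition and drops with hot spots excluded", {
  fx <- toy_fluxes(c(1, 3), c("control", "control"))
  cv <- chamber_cv(fx)
  expect_equal(cv$cv_pct, 100 * sd(c(1, 3)) / 2, tolerance = 1e-10)
  expect_equal(round(cv$cv_pct, 1), 70.7)
  # identical chambers: CV = 0
  cv0 <- chamber_cv(toy_fluxes(c(2, 2, 2), rep("control", 3)))
  expect_equal(cv0$cv_pct, 0)
  # a hot-spot chamber inflates CV; excluding it drops the CV
  fxh <- toy_fluxes(c(1, 1.2, 0.9, 1.1, 5), rep("warmed_trenched", 5))
  cv_all <- chamber_cv(fxh)
  cv_excl <- chamber_cv(fxh, exclude = 5)
  expect_gt(cv_all$cv_pct, cv_excl$cv_pct)
  # near-zero hours are skipped and counted
  fxz <- toy_fluxes(c(0.01, -0.01), c("control", "control"))
  cvz <- chamber_cv(fxz)
  expect_equal(cvz$n_skipped, 24)
})

test_that("unit conversion: 1 umol m-2 s-1 for a year is 378.8 g C m-2 = 3.788 t C ha-1", {
  hours <- seq(ptime("2009-01-01"), by = 3600, length.out = 24 * 365)
  daily <- aggregate_fluxes(tibble::tibble(hour = hours, flux = 1))
  expect_equal(nrow(daily), 365)
  ann <- annual_sums(daily)
  expect_equal(ann$g_c_m2, 12.011e-6 * 31536000, tolerance = 1e-10)
  expect_equal(round(ann$g_c_m2, 1), 378.8)
  expect_equal(round(ann$t_c_ha, 3), 3.788)
  # zero-flux year sums to zero; conservation: annual = sum of dailies
  dz <- aggregate_fluxes(tibble::tibble(hour = hours, flux = 0))
  expect_equal(annual_sums(dz)$g_c_m2, 0)
  expect_equal(ann$g_c_m2, sum(daily$g_c_m2))
})

test_that("Q10 gap-filling keeps annual sums within 2% at 5% missingness", {
  forcing <- site_forcing()
  hours <- seq(ptime("2009-01-01"), by = 3600, length.out = 24 * 365)
  ts <- soil_temperature(forcing, hours)
  set.seed(17)
  flux <- 1.25 * 2.5 ^ ((ts - 10) / 10) * rlnorm(length(ts), 0, 0.1)
  full <- tibble::tibble(hour = hours, flux = flux, t_soil = ts)
  ann_full <- annual_sums(aggregate_fluxes(full))
  drop <- sample(length(hours), round(0.05 * length(hours)))
  gappy <- full[-drop, ]
  fit <- fit_q10(gappy)
  ann_fill <- annual_sums(aggregate_fluxes(
    gappy, gap_fill = fit,
    temperature = tibble::tibble(hour = hours, t_soil = ts)))
  expect_equal(ann_fill$g_c_m2, ann_full$g_c_m2, tolerance = 0.02)
  expect_equal(ann_fill$fill_fraction, 0.05, tolerance = 0.01)
  expect_error(aggregate_fluxes(gappy, gap_fill = fit), "temperature")
})

test_that("missing-day accounting reports percentages to one decimal", {
  out <- missing_fraction(105, 2202)
  expect_equal(out$missing_pct, 4.8)
  expect_equal(missing_fraction(0, 100)$missing_pct, 0.0)
  expect_equal(missing_fraction(100, 100)$missing_pct, 100.0)
  # coverage classification path
  fx <- toy_fluxes(c(2, 2), c("control", "control"), hours = 48)
  fx$usable[fx$time >= ptime("2009-01-02")] <- FALSE
  cov <- daily_coverage(fx, expected_per_day = 48, min_fraction = 0.5)
  expect_equal(sum(cov$missing), 1)
  expect_equal(missing_fraction(cov)$missing_pct, 50.0)
})

test_that("calibration aligns groups with multiplicative offsets and no treatment effect", {
  # synthetic truth: constant per-chamber offsets, warming off
  set.seed(9)
  offs <- rlnorm(4, 0, 0.3)
  base <- 2 * rlnorm(24, 0, 0.05)                  # shared hourly signal
  fx <- purrr::map_dfr(1:4, function(ch) {
    tibble::tibble(
      time = ptime("2009-01-01") + (0:23) * 3600 + ch * 240,
      chamber = ch,
      treatment = c("trenched", "trenched",
                    "warmed_trenched", "warmed_trenched")[ch],
      flux = offs[ch] * base,
      usable = TRUE
    )
  })
  cal <- calibrate_qc(fx, window = c("2009-01-01", "2009-01-02"))
  h <- fx %>%
    dplyr::left_join(cal[, c("treatment", "qc")], by = "treatment") %>%
    dplyr::group_by(treatment) %>%
    dplyr::summarise(m = mean(flux * qc))
  expect_equal(h$m[1], h$m[2], tolerance = 1e-10)
})
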