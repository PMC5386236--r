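test_that("dead-band stripping removes exactly k leading records", {
  seg <- make_ramp()
  s3 <- strip_dead_band(seg, 3)
  expect_equal(sum(s3$qc_keep), 21)
  expect_equal(which(!s3$qc_keep), 1:3)
  expect_equal(s3$offset_s, seg$offset_s)           # offsets preserved
  s0 <- strip_dead_band(seg, 0)
  expect_true(all(s0$qc_keep))
  s24 <- strip_dead_band(seg, 24)
  expect_false(attr(s24, "usable"))
  expect_error(strip_dead_band(seg, -1))
})

test_that("a single displaced record is exactly identified and the slope restored", {
  seg <- make_ramp(slope = 0.1)
  seg$co2_ppm[13] <- seg$co2_ppm[13] + 10
  res <- reject_outliers(seg, passes = 3, m = 3)
  expect_equal(res$rejected$index, 13)
  expect_match(res$rejected$reason, "^outlier_pass")
  # oracle: OLS excluding the known-injected point
  oracle <- lm(co2_ppm ~ offset_s, data = seg[-13, ])
  expect_equal(res$fit$slope, unname(coef(oracle)[2]), tolerance = 1e-12)
  expect_equal(res$fit$slope, 0.1, tolerance = 1e-12)
})

test_that("an exact line yields zero removals and no division by zero", {
  seg <- make_ramp()
  res <- reject_outliers(seg)
  expect_equal(nrow(res$rejected), 0)
  expect_equal(res$fit$resid_sd, 0)
  expect_equal(res$fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(res$fit$r, 1)
})

test_that("rejection fraction of pure Gaussian noise matches the 3-sigma tail", {
  # expected 2*(1 - Phi(3)) ~ 0.27% per pass at large n
  set.seed(101)
  n <- 20000
  seg <- tibble::tibble(offset_s = seq_len(n),
                        co2_ppm = 400 + 0.1 * seq_len(n) + rnorm(n))
  res <- reject_outliers(seg, passes = 2, m = 3)   # one removal pass
  frac <- nrow(res$rejected) / n
  expect_gt(frac, 0.0012)
  expect_lt(frac, 0.0045)
})

test_that("outlier rejection is idempotent and residual sd non-increasing", {
  set.seed(7)
  sds <- purrr::map_dbl(1:20, function(i) {
    seg <- make_ramp(noise = 0.5)
    idx <- sample(24, 2)
    seg$co2_ppm[idx] <- seg$co2_ppm[idx] + 6
    res <- reject_outliers(seg, passes = 10)   # enough passes to converge
    sd1 <- {
      f1 <- lm(co2_ppm ~ offset_s, data = seg)
      sd(stats::resid(f1))
    }
    # converged result removes nothing further
    seg2 <- seg[res$retained, ]
    res2 <- reject_outliers(seg2, passes = 10, min_points = 3)
    expect_equal(nrow(res2$rejected), 0)
    res$fit$resid_sd - sd1                         # final sd vs initial sd
  })
  expect_true(all(sds <= 1e-8))
})

test_that("per-segment fits agree with lm on noisy segments", {
  set.seed(21)
  for (i in 1:5) {
    seg <- make_ramp(noise = 1, slope = runif(1, 0, 0.3))
    res <- reject_outliers(seg, passes = 1)        # single fit, no removal
    f <- lm(co2_ppm ~ offset_s, data = seg)
    expect_equal(res$fit$slope, unname(coef(f)[2]), tolerance = 1e-10)
    expect_equal(res$fit$intercept, unname(coef(f)[1]), tolerance = 1e-10)
    expect_equal(res$fit$r, cor(seg$offset_s, seg$co2_ppm),
                 tolerance = 1e-10)
    expect_equal(res$fit$resid_sd, sd(stats::resid(f)), tolerance = 1e-10)
  }
})

test_that("usability threshold separates clean ramps from marginal fits", {
  clean <- reject_outliers(make_ramp())
  expect_true(usability(clean))
  # deterministic alternating residuals tuned so r falls just below 0.95
  seg <- make_ramp()
  seg$co2_ppm <- seg$co2_ppm + 2.51 * (-1)^(seq_len(24))
  r_oracle <- cor(seg$offset_s, seg$co2_ppm)
  expect_lt(r_oracle, 0.95)
  expect_gt(r_oracle, 0.90)
  res <- reject_outliers(seg)
  expect_equal(nrow(res$rejected), 0)              # pattern survives 3x sd
  expect_equal(res$fit$r, r_oracle, tolerance = 1e-10)
  u <- usability(res)
  expect_false(as.logical(u))
  expect_match(attr(u, "flags"), "low_r")
  # too few points is unusable regardless of fit
  short <- reject_outliers(make_ramp(n = 6), min_points = 10)
  expect_false(as.logical(usability(short, min_points = 10)))
})

test_that("near-zero fluxes are kept as usable-zero rather than discarded", {
  set.seed(5)
  seg <- make_ramp(slope = 0, noise = 0.3)
  res <- reject_outliers(seg)
  u <- usability(res, zero_noise_max = 1)
  expect_true(as.logical(u))
  expect_match(attr(u, "flags"), "usable_zero")
  expect_false(as.logical(usability(res, zero_noise_max = NULL)))
  # a perfectly flat noise-free trace is usable-zero too (r undefined)
  flat <- make_ramp(slope = 0, noise = 0)
  uf <- usability(reject_outliers(flat))
  expect_true(as.logical(uf))
})

test_that("vectorised closure QC matches the per-segment path", {
  camp <- simulate_campaign("2009-07-01", "2009-07-02",
                            instrument = instrument_model(n_chambers = 3),
                            seed = 31)
  seg <- segment_closures(camp$raw, camp$meta)
  qc <- qc_closures(seg, dead_band = 3, passes = 3, m = 3)
  ids <- unique(seg$closure)[c(1, 10, 40)]
  for (id in ids) {
    one <- seg[seg$closure == id, ]
    one <- strip_dead_band(one[order(one$offset_s), ], 3)
    res <- reject_outliers(one, passes = 3, m = 3)
    row <- qc$closures[qc$closures$closure == id, ]
    expect_equal(row$slope, res$fit$slope, tolerance = 1e-12)
    expect_equal(row$r, res$fit$r, tolerance = 1e-12)
    expect_equal(row$n_used, res$fit$n)
  }
  # retained + rejected = all records of each closure
  tab <- table(qc$records$qc_keep | !is.na(qc$records$qc_reason))
  expect_equal(unname(tab["TRUE"]), nrow(qc$records))
})
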