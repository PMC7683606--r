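# The synthetic cohort generator: distributions, envelope, channel
# decomposition, LH/hormone dynamics, determinism.

test_that("truncated-normal draws match numerically integrated moments", {
  withr::local_seed(42)
  x <- rtnorm(1e5, -5.82, 1.82, -8, -2)
  mom <- surgewave:::tnorm_moments_numint(-5.82, 1.82, -8, -2)
  expect_lt(abs(mean(x) - mom$mean) / abs(mom$mean), 0.02)
  expect_lt(abs(sd(x) - mom$sd) / mom$sd, 0.02)
  expect_true(all(x >= -8 & x <= -2))
})

test_that("cycle truths honor ranges, ordering and the hierarchical moments", {
  cfg <- cohort_config(seed = 42)
  withr::local_seed(42)
  # individuals of 2-3 cycles, 10,000 cycles total
  infl <- peak <- trough <- numeric(0)
  n <- 0L
  while (n < 10000L) {
    ind <- draw_individual(cfg, "X")
    for (k in seq_len(sample(2:3, 1))) {
      tr <- draw_cycle_truth(cfg, ind)
      ev <- tr$events$dbt
      infl <- c(infl, ev[["inflection"]])
      peak <- c(peak, ev[["peak"]])
      trough <- c(trough, ev[["trough"]])
      n <- n + 1L
    }
  }
  expect_true(all(infl >= -8 & infl <= -2))
  expect_true(all(infl < peak & peak < trough))
  expect_true(all(peak <= 2 + 1e-12))
  # marginal of the inflection day is exactly the configured trunc-normal
  mom <- surgewave:::tnorm_moments_numint(-5.82, 1.82, -8, -2)
  expect_lt(abs(mean(infl) - mom$mean) / abs(mom$mean), 0.02)
  expect_lt(abs(sd(infl) - mom$sd) / mom$sd, 0.02)
})

test_that("perimenopausal truths have a flat envelope and no onset", {
  cfg <- cohort_config(group = "perimenopausal", seed = 3)
  withr::local_seed(3)
  tr <- draw_cycle_truth(cfg)
  expect_true(tr$flat_envelope)
  expect_true(is.na(tr$lh_onset_day))
  expect_null(tr$events)
  expect_equal(tr$midcycle_day, floor(tr$cycle_length / 2))
  expect_equal(ur_envelope_value(tr, cfg, seq(-10, 10, by = 0.5)),
               rep(1, 41))
})

test_that("envelope interpolates linearly through its anchors", {
  cfg <- cohort_config()
  tr <- canonical_truth()
  ev <- tr$events$dbt
  expect_equal(ur_envelope_value(tr, cfg, ev[["peak"]]), 2.0)
  expect_equal(ur_envelope_value(tr, cfg, ev[["trough"]]), 0.5)
  expect_equal(ur_envelope_value(tr, cfg, ev[["inflection"]]), 1.0)
  mid <- (ev[["inflection"]] + ev[["peak"]]) / 2
  expect_equal(ur_envelope_value(tr, cfg, mid), 1.5)
  # flat at 1 beyond the recovery anchor; positive everywhere
  expect_equal(ur_envelope_value(tr, cfg, ev[["trough"]] + 5), 1.0)
  grid <- seq(0.5 - tr$lh_onset_day, tr$cycle_length - tr$lh_onset_day, by = 0.01)
  expect_true(all(ur_envelope_value(tr, cfg, grid) > 0))
})

test_that("noise-free DBT decomposes into its stated components", {
  cfg <- noise_free_config()
  cfg$channels$dbt$ur_periods_h <- 3   # single 3 h sinusoid
  cfg$channels$dbt$ur_amps <- 0.3
  tr <- canonical_truth()
  chs <- synthesize_channels(tr, cfg, channels = "dbt", seed = 5)
  t_min <- chs$channels$dbt$t_min
  tod <- (t_min / 60) %% 24; tau <- t_min / 1440; th <- t_min / 60
  base_circ <- 34.5 + cos(2 * pi * (tod - 4) / 24) +
    0.3 * pmin(pmax(tau - 16, 0), 1)     # luteal ramp from onset midday + 0.5
  resid <- chs$channels$dbt$value - base_circ
  env <- ur_envelope_value(tr, cfg, tau - 15.5)
  # residual / envelope is an exact unit-frequency sinusoid: R^2 = 1
  s <- resid / (env * 0.3)
  fit <- lm(s ~ sin(2 * pi * th / 3) + cos(2 * pi * th / 3))
  expect_lt(mean(abs(residuals(fit))), 1e-9)
  expect_equal(sqrt(sum(coef(fit)[2:3]^2)), 1, tolerance = 1e-9)
  # each day's ultradian amplitude tracks the envelope's daily maximum;
  # in particular the peak day carries twice the baseline amplitude
  day <- floor(tau) + 1
  amp_d <- tapply(resid, day, function(v) (max(v) - min(v)) / 2)
  env_d <- tapply(env, day, max)
  expect_equal(as.numeric(amp_d / (0.3 * env_d)), rep(1, 28), tolerance = 0.02)
})

test_that("flat envelope gives constant-amplitude ultradian DBT", {
  cfg <- noise_free_config(group = "perimenopausal")
  withr::local_seed(8)
  tr <- draw_cycle_truth(cfg)
  chs <- synthesize_channels(tr, cfg, channels = "dbt", seed = 5)
  t_min <- chs$channels$dbt$t_min
  tod <- (t_min / 60) %% 24
  resid <- chs$channels$dbt$value - (34.5 + cos(2 * pi * (tod - 4) / 24))
  day <- floor(t_min / 1440) + 1
  amps <- tapply(resid, day, function(v) (max(v) - min(v)) / 2)
  expect_lt(diff(range(amps)) / mean(amps), 0.01)
})

test_that("HR ultradian component is not envelope-modulated", {
  cfg <- noise_free_config()
  tr <- canonical_truth()
  chs <- synthesize_channels(tr, cfg, channels = "hr", seed = 5)
  v <- chs$channels$hr$value; t_min <- chs$channels$hr$t_min
  tau <- t_min / 1440
  resid <- v - 58 - 2 * pmin(pmax(tau - 16, 0), 1)
  night <- findInterval(t_min, chs$nights$onset_min)
  amps <- tapply(resid, night, function(x) (max(x) - min(x)) / 2)
  expect_lt(diff(range(amps)) / mean(amps), 0.05)
})

test_that("HR/RMSSD exist only inside the sleep windows; timestamps increase", {
  ds <- tiny_cohort(n = 2, seed = 21)
  for (rec in ds$records) {
    for (ch in c("hr", "rmssd")) {
      t <- rec$channels[[ch]]$t_min
      expect_true(all(diff(t) > 0))
      expect_true(all(surgewave:::in_sleep_window(t, rec$nights)))
    }
    expect_true(all(diff(rec$channels$dbt$t_min) > 0))
  }
})

test_that("sleep window longer than a day is rejected", {
  expect_error(cohort_config(sleep = list(onset_h = 8, offset_h = 8, jitter_min = 0)),
               "sleep window")
})

test_that("LH is positive exactly on the surge days; perimenopausal LH is tonic", {
  cfg <- noise_free_config()
  tr <- canonical_truth(); tr$surge_length <- 2L
  hl <- synthesize_hormones_and_lh(tr, cfg, seed = 1, noise = FALSE)
  pos <- hl$lh$day[hl$lh$positive == 1]
  expect_identical(pos, c(16L, 17L))

  cfgp <- noise_free_config(group = "perimenopausal")
  withr::local_seed(4)
  trp <- draw_cycle_truth(cfgp)
  hlp <- synthesize_hormones_and_lh(trp, cfgp, seed = 1, noise = FALSE)
  expect_true(all(hlp$lh$positive == 1))
  expect_identical(nrow(hlp$lh), trp$cycle_length)
})

test_that("noiseless E2 peaks exactly at onset minus its offset; censoring at LOD", {
  cfg <- noise_free_config()
  tr <- canonical_truth(); tr$e2_peak_offset <- 3
  hl <- synthesize_hormones_and_lh(tr, cfg, seed = 1, noise = FALSE)
  expect_identical(hl$hormones$day[which.max(hl$hormones$e2)],
                   tr$lh_onset_day - 3L)
  # alpha-Pg reaches ~5x baseline six days after onset
  apg <- hl$hormones$apg
  expect_equal(apg[tr$lh_onset_day + 6] / apg[5], 5, tolerance = 1e-9)
  # a tiny baseline forces censoring at the LOD
  cfg$hormones$apg$base <- 0.01
  hl2 <- synthesize_hormones_and_lh(tr, cfg, seed = 1, noise = FALSE)
  expect_true(any(hl2$hormones$apg_censored))
  expect_true(all(hl2$hormones$apg >= cfg$hormones$apg$lod))
})

test_that("generation is deterministic and groups into 2-3 cycle individuals", {
  cfg <- cohort_config(n_cycles = 45, seed = 42)
  ds1 <- generate_cohort(cfg)
  ds2 <- generate_cohort(cfg)
  expect_identical(ds1, ds2)
  expect_length(ds1$truths, 45)
  sizes <- table(vapply(ds1$records, `[[`, "", "participant"))
  expect_true(all(sizes %in% 2:3))
  expect_gte(length(sizes), 15)
  # one ground truth per record, ids aligned
  expect_identical(vapply(ds1$records, `[[`, "", "cycle_id"),
                   vapply(ds1$truths, `[[`, "", "cycle_id"))
})

test_that("nightly DBT deviation is positive after the surge (criterion d)", {
  ds <- tiny_cohort(n = 3, seed = 33)
  for (i in seq_along(ds$records)) {
    dev <- nightly_temperature_deviation(ds$records[[i]])
    onset <- ds$truths[[i]]$lh_onset_day
    post <- dev$deviation[dev$night >= onset + 2]
    expect_true(all(post > 0))
  }
})
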