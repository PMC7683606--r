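# Feature detection: smoothing, extrema, inflection/peak/trough rules,
# alignment and the anticipation summary.

mk_wp <- function(power, day, tau, dt_min = 1, channel = "dbt") {
  structure(list(power = power, day = day, tau = tau, dt_min = dt_min,
                 channel = channel, band_h = c(2, 5), trimmed = TRUE),
            class = "wavelet_power")
}

test_that("z-scoring and smoothing behave as documented", {
  set.seed(3)
  n <- 2000
  wp <- mk_wp(runif(n, 1, 3), day = rep(1:10, each = 200), tau = (1:n) / 200)
  out <- zscore_and_smooth(wp, detection_config(smooth_window = 201))
  expect_equal(mean(out$zscored), 0, tolerance = 1e-9)
  expect_equal(sd(out$zscored), 1, tolerance = 1e-9)
  # smoothing a linear ramp leaves the interior unchanged
  ramp <- mk_wp(seq(0, 1, length.out = n), rep(1:10, each = 200), (1:n) / 200)
  sm <- zscore_and_smooth(ramp, detection_config(smooth_window = 201))
  inner <- 101:(n - 101)
  expect_equal(sm$processed[inner], sm$zscored[inner], tolerance = 1e-9)
  # a single spike on a constant background spreads over exactly one window
  spike <- c(rep(0, 500), 100, rep(0, 499))
  wsp <- mk_wp(spike, rep(1:5, each = 200), (1:1000) / 200)
  ssp <- zscore_and_smooth(wsp, detection_config(smooth_window = 101))
  nz <- which(abs(ssp$processed - min(ssp$processed)) > 1e-9)
  expect_identical(length(nz), 101L)
  expect_equal(nz, 451:551)
  # zero variance errors with the cycle named
  flat <- mk_wp(rep(1, 300), rep(1:3, each = 100), (1:300) / 100)
  expect_error(zscore_and_smooth(flat, cycle_id = "P9_c1"), "P9_c1")
})

test_that("extrema match the neighbour rule on canonical cases", {
  ex <- find_extrema(c(0, 1, 0))
  expect_identical(ex$peaks, 2L)
  expect_identical(ex$troughs, integer(0))
  mono <- find_extrema(as.numeric(1:50))
  expect_identical(mono$peaks, integer(0))
  expect_identical(mono$crossings, integer(0))
  # plateau resolves to its leftmost sample
  plat <- find_extrema(c(0, 2, 2, 2, 0, -1, -1, 3))
  expect_identical(plat$peaks, 2L)
  expect_identical(plat$troughs, 6L)
})

test_that("extrema and crossings agree with an exhaustive scan on random series", {
  set.seed(11)
  for (rep in 1:5) {
    x <- cumsum(rnorm(200))
    ex <- find_extrema(x)
    pk <- tr <- integer(0)
    for (i in 2:199) {
      if (x[i] > x[i - 1] && x[i] > x[i + 1]) pk <- c(pk, i)
      if (x[i] < x[i - 1] && x[i] < x[i + 1]) tr <- c(tr, i)
    }
    expect_identical(ex$peaks, pk)
    expect_identical(ex$troughs, tr)
    # every interior extremum is a derivative sign change and vice versa
    expect_identical(sort(ex$crossings), sort(c(pk, tr)))
  }
})

test_that("the first crossing inside the exclusion window is skipped", {
  # smoothed-power stand-in: minima at day 4 and day 7, samples daily x 20
  tau <- seq(0.5, 12, by = 0.05)
  day <- floor(tau) + 1
  x <- cos(2 * pi * (tau - 4) / 6)   # minima at tau 1, 7; maximum at 4
  wp <- mk_wp(x, day, tau)
  wp$processed <- x
  fs <- detect_anticipation_features(wp, align_day = 9,
                                     config = detection_config(smooth_window = 3))
  # crossings exist near tau 1 (day 2, excluded) and tau 4 (day 5, excluded);
  # the first retained one is the minimum at tau 7 (day 8)
  expect_equal(fs$inflection + 8.5, 7, tolerance = 0.1)
})

test_that("noise-free canonical cycle is recovered within half a day", {
  cfg <- noise_free_config()
  tr <- canonical_truth()
  rec <- record_from_truth(tr, cfg)
  # DBT is sampled continuously through the waking day, so recovery is
  # bounded by the smoothing window (+/- 0.5 d); the sleeping channels
  # are sampled one night per day, adding up to one night of
  # quantization on top of that bound.
  tol <- c(dbt = 0.5, rmssd = 1.0)
  for (ch in c("dbt", "rmssd")) {
    res <- analyze_cycle(rec, ch)
    truth <- tr$events[[ch]]
    expect_lt(abs(res$features$inflection - truth[["inflection"]]), tol[[ch]])
    expect_lt(abs(res$features$peak - truth[["peak"]]), tol[[ch]])
    expect_lt(abs(res$features$trough - truth[["trough"]]), tol[[ch]])
  }
})

test_that("alignment aggregates single and duplicated cycles correctly", {
  wp <- mk_wp(rep(1:14, each = 10) / 14, day = rep(1:14, each = 10),
              tau = (1:140) / 10)
  wp$processed <- wp$power
  al1 <- align_and_aggregate(list(wp), align_days = 7)
  expect_equal(unname(al1$mean[al1$days %in% -6:7]),
               unname(al1$per_cycle[1, al1$days %in% -6:7]))
  expect_true(all(al1$sd == 0 | is.na(al1$sd)))
  al2 <- align_and_aggregate(list(wp, wp), align_days = c(7, 7))
  expect_true(all(al2$sd[al2$n == 2] == 0))
  expect_true(al2$partial[1])   # day -7 missing for a 14-day series
})

test_that("anticipation fractions are monotone and handle degenerate input", {
  f <- data.frame(cycle_id = paste0("c", 1:6), participant = rep(c("a", "b", "c"), 2),
                  channel = "dbt", inflection = rep(-5, 6), peak = rep(-2, 6))
  s <- anticipation_summary(f)
  cum <- s$cumulative$dbt_inflection
  expect_true(all(diff(cum) >= 0))
  expect_true(all(cum[s$days < -5] == 0) && all(cum[s$days >= -5] == 1))
  expect_equal(unname(s$range_ratio["dbt_inflection"]), 0)
  # missing features never count as detected
  f2 <- f; f2$inflection[1] <- NA
  s2 <- anticipation_summary(f2)
  expect_equal(max(s2$cumulative$dbt_inflection), 5 / 6)
})

test_that("co-detection uses the later of the two channels' feature days", {
  f <- rbind(
    data.frame(cycle_id = c("c1", "c2"), participant = "p", channel = "dbt",
               inflection = c(-6, -3), peak = c(-3, -1)),
    data.frame(cycle_id = c("c1", "c2"), participant = "p", channel = "rmssd",
               inflection = c(-4, -5), peak = c(-2, -2)))
  s <- anticipation_summary(f)
  expect_equal(s$values$both_inflection, c(-4, -3))
  expect_equal(s$values$both_peak, c(-2, -1))
})
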