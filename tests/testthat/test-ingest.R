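# Dataset IO, cleaning rules, waking/sleeping concatenation, nightly
# temperature deviation.

test_that("write -> read round-trips every series and ground truth", {
  ds <- tiny_cohort(n = 3, seed = 5)
  path <- withr::local_tempdir()
  write_dataset(ds, file.path(path, "ds"))
  recs <- read_dataset(file.path(path, "ds"))
  expect_length(recs, 3)
  ids <- vapply(ds$records, `[[`, "", "cycle_id")
  for (i in seq_along(recs)) {
    orig <- ds$records[[match(recs[[i]]$cycle_id, ids)]]
    expect_identical(recs[[i]]$participant, orig$participant)
    expect_identical(recs[[i]]$cycle_length, orig$cycle_length)
    for (ch in names(orig$channels)) {
      expect_equal(recs[[i]]$channels[[ch]]$t_min, as.numeric(orig$channels[[ch]]$t_min))
      expect_equal(recs[[i]]$channels[[ch]]$value, orig$channels[[ch]]$value,
                   tolerance = 1e-10)
    }
    expect_equal(recs[[i]]$lh, orig$lh, ignore_attr = TRUE)
    expect_equal(recs[[i]]$hormones$e2, orig$hormones$e2, tolerance = 1e-10)
  }
  truths <- attr(recs, "truths")
  tr <- truths[[match(ds$records[[1]]$cycle_id, vapply(recs, `[[`, "", "cycle_id"))]]
  orig_tr <- ds$truths[[1]]
  expect_equal(tr$lh_onset_day, orig_tr$lh_onset_day)
  expect_equal(unname(tr$events$dbt), unname(orig_tr$events$dbt), tolerance = 1e-10)
})

test_that("writing the same cohort twice is byte-identical", {
  ds <- tiny_cohort(n = 2, seed = 9)
  path <- withr::local_tempdir()
  write_dataset(ds, file.path(path, "a"))
  write_dataset(ds, file.path(path, "b"))
  fa <- list.files(file.path(path, "a"), recursive = TRUE)
  for (f in fa)
    expect_identical(readBin(file.path(path, "a", f), "raw", 1e7),
                     readBin(file.path(path, "b", f), "raw", 1e7))
})

test_that("a cycle missing lh.csv raises an error naming it", {
  ds <- tiny_cohort(n = 2, seed = 9)
  path <- withr::local_tempdir()
  write_dataset(ds, file.path(path, "ds"))
  cyc <- list.dirs(file.path(path, "ds"), recursive = FALSE)[1]
  file.remove(file.path(cyc, "lh.csv"))
  expect_error(read_dataset(file.path(path, "ds")), basename(cyc), fixed = TRUE)
})

test_that("shuffled channel rows parse to the same record as sorted input", {
  ds <- tiny_cohort(n = 1, seed = 13)
  path <- withr::local_tempdir()
  write_dataset(ds, file.path(path, "ds"))
  cyc <- list.dirs(file.path(path, "ds"), recursive = FALSE)[1]
  f <- file.path(cyc, "channels.csv")
  tab <- data.table::fread(f)
  before <- read_dataset(file.path(path, "ds"), with_truth = FALSE)[[1]]
  set.seed(1)
  data.table::fwrite(tab[sample(nrow(tab)), ], f)
  after <- read_dataset(file.path(path, "ds"), with_truth = FALSE)[[1]]
  expect_equal(after$channels, before$channels, tolerance = 1e-12)
})

test_that("cleaning flags and replaces a single extreme outlier", {
  set.seed(2)
  x <- sin(seq(0, 20, length.out = 500)) + rnorm(500, 0, 0.05)
  i <- 300
  x[i] <- mean(x) + 10 * sd(x)
  cl <- clean_series(x, dt_min = 1)
  expect_identical(which(cl$flags), as.integer(i))
  expect_equal(cl$values[i], median(cl$values[(i - 60):(i - 1)]))
  expect_identical(cl$n_replaced, 1L)
})

test_that("a clean sinusoid passes through cleaning untouched", {
  x <- sin(seq(0, 10, length.out = 400))
  cl <- clean_series(x, dt_min = 1)
  expect_identical(cl$values, x)
  expect_identical(cl$n_replaced, 0L)
  # constant series: SD 0 is defined as no flags, not an error
  cl0 <- clean_series(rep(3, 50), dt_min = 1)
  expect_identical(cl0$n_replaced, 0L)
})

test_that("seeded spikes are flagged exactly as a brute-force two-rule scan", {
  set.seed(7)
  n <- 2000
  x <- rnorm(n)
  spikes <- sort(sample(100:(n - 100), 20))
  x[spikes] <- x[spikes] + sample(c(-1, 1), 20, TRUE) * 9
  cl <- clean_series(x, dt_min = 1, config = cleaning_config(derivative_threshold = 1e5))
  # oracle: apply the two flagging rules independently, point by point
  mu <- mean(x); sig <- sd(x)
  oracle <- abs(x - mu) > 4 * sig
  for (i in 2:n) if (abs(x[i] - x[i - 1]) > 1e5) oracle[i] <- TRUE
  expect_identical(cl$flags, oracle)
  expect_identical(which(cl$flags), spikes)
  # a derivative-rule-only glitch (pair of huge jumps) is caught by pass 2
  y <- sin(seq(0, 5, length.out = 300))
  y[150] <- y[150] + 2e5
  cl2 <- clean_series(y, dt_min = 1)
  expect_true(cl2$flags[150])
})

test_that("waking DBT concatenation has 960 samples per day with day indices 1..n", {
  cfg <- noise_free_config()
  rec <- record_from_truth(canonical_truth(), cfg)
  s <- segment_and_concatenate(rec, "dbt")
  expect_s3_class(s, "concat_series")
  counts <- table(s$day)
  # first day: night 1's sleep starts 23:30, so day 1 keeps 1410 - 450 of
  # its own morning... all interior days keep 16 h = 960 one-minute bins
  interior <- counts[as.character(2:27)]
  expect_true(all(interior == 960))
  expect_identical(sort(unique(s$day)), 1:28)
  expect_identical(length(s$values), length(s$day))
  # a 03:00 sample (inside a recorded sleep window) is never kept; the
  # first morning and last evening have no recorded night, so only
  # interior days are checked
  tod <- (s$t_min / 60) %% 24
  interior_sel <- s$day %in% 2:27
  expect_false(any(tod[interior_sel] >= 23.6 | tod[interior_sel] < 7.4))
})

test_that("sleeping-channel concatenation keeps only in-window samples per night", {
  rec <- record_from_truth(canonical_truth())
  s <- segment_and_concatenate(rec, "rmssd")
  expect_identical(sort(unique(s$day)), rec$nights$night)
  expect_true(all(table(s$day) == 96))
  expect_error(segment_and_concatenate(rec, "nope"), "unknown channel")
})

test_that("an empty night is recorded missing; short gaps are interpolated", {
  rec <- record_from_truth(canonical_truth())
  ch <- rec$channels$rmssd
  night5 <- rec$nights[rec$nights$night == 5, ]
  drop <- ch$t_min >= night5$onset_min & ch$t_min < night5$offset_min
  rec$channels$rmssd <- list(t_min = ch$t_min[!drop], value = ch$value[!drop])
  s <- segment_and_concatenate(rec, "rmssd")
  expect_identical(s$missing_days, 5L)
  expect_false(5 %in% s$day)

  # a 30-min hole inside a kept day is filled linearly and flagged
  rec2 <- record_from_truth(canonical_truth())
  dch <- rec2$channels$dbt
  hole <- dch$t_min >= 10 * 1440 + 600 & dch$t_min < 10 * 1440 + 630
  rec2$channels$dbt <- list(t_min = dch$t_min[!hole], value = dch$value[!hole])
  s2 <- segment_and_concatenate(rec2, "dbt")
  expect_identical(sum(s2$interpolated), 30L)
  full <- segment_and_concatenate(record_from_truth(canonical_truth()), "dbt")
  expect_identical(length(s2$values), length(full$values))
  # concatenation preserves kept-sample count: kept + interpolated = total
  expect_identical(sum(!s2$interpolated), length(dch$t_min[!hole]) -
                     sum(surgewave:::in_sleep_window(dch$t_min[!hole], rec2$nights)))
})

test_that("temperature deviation is zero for constant input and exact for a step", {
  rec <- record_from_truth(canonical_truth())
  n <- length(rec$channels$dbt$t_min)
  # constant temperature
  dev0 <- nightly_temperature_deviation(rec, values = rep(36, n))
  expect_true(all(dev0$deviation == 0))
  # +x on night 21's window only
  x <- 0.7
  v <- rep(36, n)
  t <- rec$channels$dbt$t_min
  win21 <- t >= 20 * 1440 + 22 * 60 & t < 21 * 1440 + 8 * 60
  v[win21] <- 36 + x
  dev <- nightly_temperature_deviation(rec, values = v)
  expect_equal(dev$deviation[dev$night == 21], x)
  # fewer than 21 nights -> empty result, not an error
  short <- canonical_truth(); short$cycle_length <- 15L; short$lh_onset_day <- 8L
  expect_identical(nrow(nightly_temperature_deviation(record_from_truth(short))), 0L)
})

test_that("cleaning is deterministic: same input, same flags and output", {
  set.seed(31)
  x <- rnorm(1000)
  x[c(100, 500)] <- 20
  a <- clean_series(x, 1); b <- clean_series(x, 1)
  expect_identical(a, b)
})
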