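# Surge-anticipation features: z-score, daily moving-average smoothing,
# extrema / derivative zero-crossing detection, cohort alignment and
# the cumulative anticipation summary.

#' Centered moving mean with shrinking edges
#'
#' @param x numeric vector.
#' @param w window length in samples; at the edges the window shrinks to
#'   the available samples.
#' @export
moving_mean <- function(x, w) {
  n <- length(x)
  w <- min(as.integer(w), n)
  h1 <- floor((w - 1) / 2); h2 <- (w - 1) - h1
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h1); hi <- pmin(n, i + h2)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Z-score and smooth a band-power series
#'
#' Z-scores over the full (trimmed) cycle, then applies a centered moving
#' mean spanning one nominal day of samples (960 for 1-min waking DBT,
#' 96 for 5-min sleeping channels). Z-scoring is affine so it cannot move
#' extrema or zero-crossings; it only standardizes units across cycles.
#'
#' @param wp a `wavelet_power` object (trimmed).
#' @param config a [detection_config()].
#' @param cycle_id used in error messages.
#' @return The `wavelet_power` object with `$processed` (smoothed
#'   z-scores) and `$smooth_window` added.
#' @export
zscore_and_smooth <- function(wp, config = detection_config(), cycle_id = "?") {
  stopifnot(inherits(wp, "wavelet_power"))
  p <- wp$power
  s <- sd(p)
  if (!is.finite(s) || s == 0)
    stop("zero-variance band power in cycle ", cycle_id, call. = FALSE)
  z <- (p - mean(p)) / s
  w <- config$smooth_window
  if (is.null(w)) w <- nominal_day_samples(wp$channel, wp$dt_min)
  wp$processed <- moving_mean(z, w)
  wp$zscored <- z
  wp$smooth_window <- w
  wp
}

#' Local extrema and derivative zero-crossings
#'
#' Peaks are points strictly greater than both neighbours (plateaus
#' resolve to their leftmost sample); troughs are peaks of the negated
#' series; crossings are sign changes of the first difference (the sample
#' shared by the two differences, plateau runs again resolving leftmost).
#'
#' @param x numeric series, length >= 3.
#' @return List of integer indices: `peaks`, `troughs`, `crossings`.
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) stop("series too short for extrema detection", call. = FALSE)
  r <- rle(x)
  v <- r$values
  k <- length(v)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  peaks <- troughs <- integer(0)
  if (k >= 3) {
    mid <- 2:(k - 1)
    peaks <- starts[mid][v[mid] > v[mid - 1] & v[mid] > v[mid + 1]]
    troughs <- starts[mid][v[mid] < v[mid - 1] & v[mid] < v[mid + 1]]
  }
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  crossings <- integer(0)
  if (length(nz) > 1) {
    flip <- which(s[nz[-length(nz)]] * s[nz[-1]] < 0)
    crossings <- nz[flip] + 1L   # sample shared by the two differences
  }
  list(peaks = peaks, troughs = troughs, crossings = crossings)
}

#' Detect the surge-anticipation features of one cycle
#'
#' The first inflection is the earliest derivative zero-crossing of the
#' smoothed band power whose day label exceeds the early-cycle exclusion
#' (default: first five days, when an LH surge is very unlikely); the
#' subsequent peak is the earliest strict local maximum after that
#' inflection; the post-surge trough is the earliest local minimum after
#' onset. Sample indices are converted to fractional days relative to
#' LH onset (midday of the onset day; midcycle for perimenopausal
#' cycles). Absent features are reported as `NA`, never fabricated.
#'
#' @param wp output of [zscore_and_smooth()].
#' @param align_day LH onset day (or midcycle day).
#' @param config a [detection_config()].
#' @return A `feature_set`: channel, fractional `inflection`, `peak`,
#'   `trough` days relative to onset, their sample indices, and the
#'   alignment day used.
#' @export
detect_anticipation_features <- function(wp, align_day, config = detection_config()) {
  stopifnot(inherits(wp, "wavelet_power"), !is.null(wp$processed))
  ex <- find_extrema(wp$processed)
  t_align <- align_day - 0.5
  rel <- wp$tau - t_align

  ok <- ex$crossings[wp$day[ex$crossings] > config$exclude_days]
  i_inf <- if (length(ok)) ok[1] else NA_integer_
  i_pk <- if (!is.na(i_inf)) {
    cand <- ex$peaks[ex$peaks > i_inf]
    if (length(cand)) cand[1] else NA_integer_
  } else NA_integer_
  cand_tr <- ex$troughs[rel[ex$troughs] > 0]
  i_tr <- if (length(cand_tr)) cand_tr[1] else NA_integer_

  structure(list(channel = wp$channel,
                 inflection = if (is.na(i_inf)) NA_real_ else rel[i_inf],
                 peak = if (is.na(i_pk)) NA_real_ else rel[i_pk],
                 trough = if (is.na(i_tr)) NA_real_ else rel[i_tr],
                 idx = c(inflection = i_inf, peak = i_pk, trough = i_tr),
                 align_day = align_day),
            class = "feature_set")
}

#' Align processed power curves and aggregate across cycles
#'
#' Per cycle and relative day (default -7..+7 around LH onset, midcycle
#' for perimenopausal cycles), the daily mean of the processed
#' (z-scored, smoothed) band power; then the cohort mean, SD and n per
#' day. Cycles lacking part of the window get `NA` for the missing days
#' and are flagged partial.
#'
#' @param wps list of processed `wavelet_power` objects.
#' @param align_days integer vector of alignment days (one per cycle).
#' @param days relative-day window.
#' @return List: `days`, `per_cycle` (cycles x days matrix), `mean`,
#'   `sd`, `n`, `partial` flags.
#' @export
align_and_aggregate <- function(wps, align_days, days = -7:7) {
  stopifnot(length(wps) == length(align_days), length(wps) >= 1)
  m <- matrix(NA_real_, nrow = length(wps), ncol = length(days),
              dimnames = list(NULL, days))
  for (i in seq_along(wps)) {
    wp <- wps[[i]]
    rel_day <- wp$day - align_days[i]
    for (j in seq_along(days)) {
      sel <- rel_day == days[j]
      if (any(sel)) m[i, j] <- mean(wp$processed[sel])
    }
  }
  list(days = days, per_cycle = m,
       mean = colMeans(m, na.rm = TRUE),
       sd = apply(m, 2, sd, na.rm = TRUE),
       n = colSums(!is.na(m)),
       partial = rowSums(is.na(m)) > 0)
}

#' Cohort anticipation summary
#'
#' Cumulative fraction of cycles whose detected first inflection
#' (respectively subsequent peak) lies on or before each relative day,
#' per channel and combined ("co-detected": the later of the two
#' channels' feature days, i.e. the day by which *both* channels have
#' shown the feature), plus the intra- vs inter-individual range ratio.
#' Cycles with a missing feature never count as detected.
#'
#' @param features data.frame with columns `cycle_id`, `participant`,
#'   `channel`, `inflection`, `peak` (days relative to onset).
#' @param days integer grid of relative days.
#' @return List: `days`, `cumulative` (named list of non-decreasing
#'   fraction vectors: `<channel>_inflection`, `<channel>_peak`,
#'   `both_inflection`, `both_peak`), `range_ratio` (intra/inter, per
#'   feature), `n_cycles`.
#' @export
anticipation_summary <- function(features, days = -10:5) {
  stopifnot(all(c("cycle_id", "participant", "channel",
                  "inflection", "peak") %in% names(features)))
  chans <- unique(features$channel)
  n_cyc <- length(unique(features$cycle_id))
  cum <- list()
  vals <- list()
  for (ch in chans) {
    f <- features[features$channel == ch, ]
    for (ft in c("inflection", "peak")) {
      v <- f[[ft]][match(unique(features$cycle_id), f$cycle_id)]
      vals[[paste(ch, ft, sep = "_")]] <- v
      cum[[paste(ch, ft, sep = "_")]] <-
        vapply(days, function(d) sum(v <= d, na.rm = TRUE) / n_cyc, numeric(1))
    }
  }
  if (length(chans) >= 2) {
    for (ft in c("inflection", "peak")) {
      per_ch <- do.call(cbind, vals[paste(chans, ft, sep = "_")])
      both <- apply(per_ch, 1, function(r) if (anyNA(r)) NA_real_ else max(r))
      vals[[paste0("both_", ft)]] <- both
      cum[[paste0("both_", ft)]] <-
        vapply(days, function(d) sum(both <= d, na.rm = TRUE) / n_cyc, numeric(1))
    }
  }
  # intra- vs inter-individual range (per channel feature, averaged)
  ids <- unique(features$cycle_id)
  part_of <- features$participant[match(ids, features$cycle_id)]
  range_ratio <- sapply(names(vals), function(nm) {
    v <- vals[[nm]]
    if (all(is.na(v))) return(NA_real_)
    inter <- diff(range(v, na.rm = TRUE))
    intra <- tapply(v, part_of, function(x) {
      x <- x[!is.na(x)]
      if (length(x) >= 2) diff(range(x)) else NA_real_
    })
    if (inter == 0) 0 else mean(intra, na.rm = TRUE) / inter
  })
  list(days = days, cumulative = cum, values = vals,
       range_ratio = range_ratio, n_cycles = n_cyc)
}
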