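# Waking/sleeping excerption and day-by-day concatenation, plus the
# nightly temperature deviation.

# Which samples fall inside any nightly sleep window (windows sorted,
# non-overlapping). Returns the night index per sample (NA = awake).
sleep_night_of <- function(t_min, nights) {
  ord <- order(nights$onset_min)
  on <- nights$onset_min[ord]; off <- nights$offset_min[ord]
  idx <- findInterval(t_min, on)
  ins <- idx >= 1 & t_min < off[pmax(idx, 1)]
  out <- rep(NA_integer_, length(t_min))
  out[ins] <- nights$night[ord][idx[ins]]
  out
}

in_sleep_window <- function(t_min, nights) !is.na(sleep_night_of(t_min, nights))

#' Excerpt and concatenate a channel into one continuous signal
#'
#' DBT keeps only waking samples (outside the nightly sleep windows) and
#' is segmented by calendar day; HR/RMSSD keep only sleeping samples,
#' segmented by night. Segments are concatenated in order into one
#' signal representing all days (or nights) of the cycle. Gaps shorter
#' than `max_gap_min` inside a kept segment are filled by linear
#' interpolation (flagged); days or nights with no samples at all are
#' recorded as missing.
#'
#' @param record a `cycle_record`.
#' @param channel `"dbt"`, `"hr"` or `"rmssd"`.
#' @param values optional replacement values (e.g. the cleaned series
#'   from [clean_series()]); defaults to the stored raw values.
#' @param max_gap_min interpolate gaps up to this length (default 60).
#' @return A `concat_series`: `values`, `t_min`, `tau` (continuous cycle
#'   time, days), `day` (day or night index per sample), `dt_min`,
#'   `interpolated` flags, `missing_days`, `n_days`, `channel`.
#' @export
segment_and_concatenate <- function(record, channel, values = NULL,
                                    max_gap_min = 60) {
  stopifnot(inherits(record, "cycle_record"))
  if (!channel %in% names(record$channels))
    stop("unknown channel: ", channel, call. = FALSE)
  ch <- record$channels[[channel]]
  v <- if (is.null(values)) ch$value else values
  if (length(v) != length(ch$t_min))
    stop("values length does not match the channel series", call. = FALSE)
  t_min <- ch$t_min
  dt <- if (length(t_min) > 1) min(diff(sort(t_min))) else 1
  sleeping <- channel %in% c("hr", "rmssd")

  if (sleeping) {
    day_of <- sleep_night_of(t_min, record$nights)
    keep <- !is.na(day_of)
    all_days <- record$nights$night
  } else {
    keep <- !in_sleep_window(t_min, record$nights)
    day_of <- floor(t_min / 1440) + 1L
    all_days <- seq_len(record$cycle_length)
  }

  t_k <- t_min[keep]; v_k <- v[keep]; d_k <- day_of[keep]
  ord <- order(t_k)
  t_k <- t_k[ord]; v_k <- v_k[ord]; d_k <- d_k[ord]

  # fill short gaps inside each day's kept segment
  out_t <- vector("list", length(all_days))
  out_v <- vector("list", length(all_days))
  out_i <- vector("list", length(all_days))
  missing_days <- integer(0)
  for (j in seq_along(all_days)) {
    dd <- all_days[j]
    sel <- which(d_k == dd)
    if (!length(sel)) { missing_days <- c(missing_days, dd); next }
    tt <- t_k[sel]; vv <- v_k[sel]
    gaps <- which(diff(tt) > dt * 1.5)
    ti <- tt; vi <- vv; flag <- rep(FALSE, length(tt))
    for (g in rev(gaps)) {
      glen <- tt[g + 1] - tt[g]
      if (glen <= max_gap_min) {
        newt <- seq(tt[g] + dt, tt[g + 1] - dt / 2, by = dt)
        newv <- approx(c(tt[g], tt[g + 1]), c(vv[g], vv[g + 1]), xout = newt)$y
        ins_at <- match(tt[g], ti)
        ti <- append(ti, newt, after = ins_at)
        vi <- append(vi, newv, after = ins_at)
        flag <- append(flag, rep(TRUE, length(newt)), after = ins_at)
      }
    }
    out_t[[j]] <- ti; out_v[[j]] <- vi; out_i[[j]] <- flag
  }
  tm <- unlist(out_t)
  structure(list(values = unlist(out_v), t_min = tm, tau = tm / 1440,
                 day = rep(all_days[!all_days %in% missing_days],
                           lengths(out_t)[lengths(out_t) > 0]),
                 dt_min = dt, interpolated = unlist(out_i),
                 missing_days = missing_days,
                 n_days = length(all_days) - length(missing_days),
                 channel = channel),
            class = "concat_series")
}

#' Nightly temperature deviation
#'
#' The nightly temperature is the mean DBT between 22:00 of day `n` and
#' 08:00 of day `n + 1` (fixed clock times). For each night `n >= 21`,
#' the deviation is that night's value minus the mean of the previous 20
#' nightly values — referencing nights against nights, so the circadian
#' day/night difference of distal temperature cancels and the metric sits
#' near zero until the luteal rise. A sustained positive deviation after
#' the LH surge marks the luteal phase and is inclusion criterion (d).
#'
#' @param record a `cycle_record` with a `dbt` channel.
#' @param values optional cleaned DBT values.
#' @return data.frame with `night` and `deviation` (empty if fewer than
#'   21 nights of data).
#' @export
nightly_temperature_deviation <- function(record, values = NULL) {
  stopifnot(inherits(record, "cycle_record"))
  ch <- record$channels$dbt
  if (is.null(ch)) stop("record has no dbt channel", call. = FALSE)
  v <- if (is.null(values)) ch$value else values
  t_min <- ch$t_min
  n_nights <- record$cycle_length - 1L
  if (n_nights < 21)
    return(data.frame(night = integer(0), deviation = numeric(0)))
  nightly <- vapply(seq_len(n_nights), function(n) {
    win <- t_min >= (n - 1) * 1440 + 22 * 60 & t_min < n * 1440 + 8 * 60
    if (!any(win)) return(NA_real_)
    mean(v[win])
  }, numeric(1))
  dev <- vapply(21:n_nights, function(n)
    nightly[n] - mean(nightly[(n - 20):(n - 1)], na.rm = TRUE), numeric(1))
  data.frame(night = 21:n_nights, deviation = dev)
}
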