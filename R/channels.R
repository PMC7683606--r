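# Synthetic wearable channels for one cycle: 1-min distal body
# temperature around the clock, and 5-min sleeping-only heart rate and
# RMSSD. Time is carried as minutes since midnight of cycle day 1
# (`t_min`); `tau = t_min / 1440` is continuous cycle time in days.

# AR(1) noise with *marginal* (stationary) SD sd_marg; burn-in discarded.
ar1_noise <- function(n, phi, sd_marg) {
  if (sd_marg <= 0) return(numeric(n))
  burn <- 300
  e <- rnorm(n + burn, 0, sd_marg * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))[(burn + 1):(n + burn)]
}

linear_ramp <- function(x, x0, width) pmin(pmax((x - x0) / width, 0), 1)

# Nightly sleep windows. Night n starts on the evening of cycle day n;
# the last evening of the cycle has no recorded night (its sleep would
# belong to the next cycle).
make_sleep_windows <- function(cycle_length, sleep, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_nights <- cycle_length - 1
  j_on <- if (sleep$jitter_min > 0) runif(n_nights, -sleep$jitter_min, sleep$jitter_min) else numeric(n_nights)
  j_off <- if (sleep$jitter_min > 0) runif(n_nights, -sleep$jitter_min, sleep$jitter_min) else numeric(n_nights)
  data.frame(night = seq_len(n_nights),
             onset_min = (seq_len(n_nights) - 1) * 1440 + sleep$onset_h * 60 + j_on,
             offset_min = seq_len(n_nights) * 1440 + sleep$offset_h * 60 + j_off)
}

# Deterministic waveform of a channel at minutes t_min (no noise).
channel_waveform <- function(truth, config, channel, t_min, phases = NULL) {
  p <- config$channels[[channel]]
  tau <- t_min / 1440
  tod <- (t_min / 60) %% 24
  th <- t_min / 60
  x <- rep(p$base, length(t_min))
  if (p$circadian_amp > 0)
    x <- x + p$circadian_amp * cos(2 * pi * (tod - p$circadian_peak_h) / 24)
  env <- if (p$envelope_modulated)
    ur_envelope_value(truth, config, tau - (truth_align_day(truth) - 0.5),
                      channel = if (channel == "hr") "dbt" else channel)
  else rep(1, length(t_min))
  for (i in seq_along(p$ur_periods_h)) {
    phase <- if (is.null(phases)) 0 else phases[i]
    x <- x + env * p$ur_amps[i] * sin(2 * pi * th / p$ur_periods_h[i] + phase)
  }
  if (truth$group == "premenopausal" && p$luteal_shift != 0) {
    t0 <- truth$lh_onset_day - 0.5 + 0.5   # ramp starts at onset midday + 0.5 d
    x <- x + p$luteal_shift * linear_ramp(tau, t0, config$luteal_ramp_days)
  }
  x
}

# Alignment day: LH onset for premenopausal cycles, midcycle otherwise.
truth_align_day <- function(truth) {
  if (truth$group == "premenopausal") truth$lh_onset_day else truth$midcycle_day
}

#' Synthesize the wearable channels of one cycle
#'
#' DBT is generated every minute around the clock as base level +
#' circadian cosine + envelope-modulated ultradian sinusoids + AR(1)
#' noise + a ramped luteal rise; RMSSD and HR exist only inside the
#' nightly sleep windows (5-min bins), RMSSD envelope-modulated with a
#' luteal decrease, HR deliberately *not* envelope-modulated (the null
#' channel). Perimenopausal cycles have a flat envelope and no luteal
#' shifts.
#'
#' @param truth a `cycle_truth`.
#' @param config a [cohort_config()].
#' @param channels subset of `c("dbt", "hr", "rmssd")` to generate.
#' @param seed integer seed; each channel derives an independent
#'   sub-stream so that generating a subset leaves the others' draws
#'   unchanged.
#' @return List with `channels` (per channel: `t_min`, `value`) and
#'   `nights` (night, onset_min, offset_min).
#' @export
synthesize_channels <- function(truth, config, channels = c("dbt", "hr", "rmssd"),
                                seed = 1L) {
  stopifnot(inherits(truth, "cycle_truth"), inherits(config, "cohort_config"))
  channels <- match.arg(channels, c("dbt", "hr", "rmssd"), several.ok = TRUE)
  len <- truth$cycle_length
  nights <- make_sleep_windows(len, config$sleep, seed = seed)
  out <- list()
  ch_seed <- c(dbt = 2L, hr = 3L, rmssd = 4L)
  for (ch in channels) {
    p <- config$channels[[ch]]
    set.seed(seed + ch_seed[[ch]])
    if (p$sleeping_only) {
      t_min <- unlist(lapply(seq_len(nrow(nights)), function(i)
        seq(ceiling(nights$onset_min[i] / p$dt_min) * p$dt_min,
            (ceiling(nights$offset_min[i] / p$dt_min) - 1) * p$dt_min,
            by = p$dt_min)))
    } else {
      t_min <- seq(0, len * 1440 - p$dt_min, by = p$dt_min)
    }
    phases <- runif(length(p$ur_periods_h), 0, 2 * pi)
    v <- channel_waveform(truth, config, ch, t_min, phases = phases) +
      ar1_noise(length(t_min), p$ar_phi, p$ar_sd)
    out[[ch]] <- list(t_min = as.numeric(t_min), value = v)
  }
  list(channels = out, nights = nights)
}
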