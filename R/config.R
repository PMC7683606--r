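# Cohort, cleaning and detection configuration objects. All numeric
# defaults are either the cohort statistics reported for the study
# population (cycle length, LH onset/surge timing, event-day distributions,
# assay CVs and LODs) or the generator's own signal calibration, chosen so
# that the latent envelope events are recoverable by the detection chain
# (see the methods vignette for the calibration reasoning).

tnorm_spec <- function(mean, sd, lower, upper) {
  if (sd <= 0) stop("distribution sd must be > 0", call. = FALSE)
  if (!(lower < upper)) stop("distribution range must be increasing", call. = FALSE)
  if (mean < lower || mean > upper) stop("distribution range must contain the mean", call. = FALSE)
  list(mean = mean, sd = sd, lower = lower, upper = upper)
}

#' Synthetic cohort configuration
#'
#' Builds the full parameter set for [generate_cohort()]: cycle and LH
#' surge timing distributions, the per-channel ultradian amplitude
#' envelope event-day distributions, channel signal models (circadian,
#' ultradian sinusoids, AR(1) noise, luteal shifts), the sleep window,
#' and urinary hormone dynamics with assay noise and detection limits.
#'
#' Event days are expressed relative to the day of LH surge onset
#' (negative = before onset). Perimenopausal cycles carry a flat envelope
#' (no latent events) and tonically positive LH.
#'
#' @param n_cycles number of cycles to generate.
#' @param group `"premenopausal"` or `"perimenopausal"`.
#' @param seed integer RNG seed; a fixed seed makes the generated dataset
#'   bit-identical across runs.
#' @param ... named overrides of any default listed below (nested lists
#'   are replaced wholesale).
#'
#' @section Defaults:
#' * `cycle_length`: trunc-normal, premenopausal mean 27.78 d, SD 4.16,
#'   range 25-36; perimenopausal mean 28.7, SD 8.87, range 22-50.
#' * `lh_onset`: trunc-normal mean 15.75 d, SD 3.4, range 10-29 (day 1 =
#'   first day of menses); the lower bound is raised per cycle to keep the
#'   latent inflection after cycle day 7 so it survives the first-5-day
#'   exclusion.
#' * `surge_length_pmf`: P(1..5 days) = .40/.18/.16/.16/.10, matching the
#'   persistence anchors (42% still positive at onset+2, 26% at onset+3).
#' * `envelope`: per-channel inflection/peak-gap/trough distributions
#'   (DBT: -5.82 +/- 1.82 in [-8,-2], gap 3.24 +/- 0.51 in [0.5,8], trough
#'   +2.06 +/- 1.02 in [0,5]; RMSSD SDs 1.53/0.43/1.27, trough +2.11);
#'   peak clamped at +2, trough at least peak+0.5; amplitude anchors
#'   1.3 (cycle start), 1.0 (inflection), 2.0 (peak), 0.5 (trough),
#'   recovery to 1.0 three days after the trough.
#' * `channels`: DBT 1-min sampling, base 34.5 C, circadian amplitude
#'   1.0 C peaking 04:00, ultradian sinusoids with periods 3.0 h and
#'   2.4 h at 0.30 C each (envelope-modulated), AR(1) phi 0.9 with
#'   marginal SD 0.001 C, +0.3 C luteal rise ramped over one day from
#'   onset; RMSSD 5-min sleeping-only, base 45 ms, period 24/7 h at 8 ms,
#'   SD 0.02 ms, -8 ms luteal; HR 5-min sleeping-only, base 58 bpm,
#'   period 24/9 h at 1.5 bpm *not* envelope-modulated (null channel),
#'   SD 0.5 bpm, +2 bpm luteal.
#' * `sleep`: 23:30-07:30, nightly jitter 0 min (jitter breaks the
#'   day-periodicity the daily smoothing relies on; config-exposed).
#' * `hormones`: E2 base 1.5, x3 Gaussian bump (width 1.5 d) peaking
#'   0-4 d before onset (offset 1.67 +/- 1.38); alpha/beta-pregnanediol
#'   bases 0.5/15, x5 linear rise over 6 d from onset; CVs 8/12/13%;
#'   LODs 0.2/0.2/10 ng/mL (below-LOD values reported at the LOD and
#'   flagged censored); perimenopausal: flat E2, x2.5 rise from midcycle.
#' * `individuals`: 2-3 cycles each (P(3) = 0.25); within-individual
#'   event-day SD 25% of the between-individual SD; ages trunc-normal
#'   32 +/- 4 in 21-38 (premenopausal) or 55 +/- 5 in 48-60
#'   (perimenopausal).
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cycles = 45,
                          group = c("premenopausal", "perimenopausal"),
                          seed = 1, ...) {
  group <- match.arg(group)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  cfg <- list(
    n_cycles = as.integer(n_cycles),
    group = group,
    seed = as.integer(seed),
    cycle_length = if (group == "premenopausal")
      tnorm_spec(27.78, 4.16, 25, 36) else tnorm_spec(28.7, 8.87, 22, 50),
    lh_onset = tnorm_spec(15.75, 3.4, 10, 29),
    min_inflection_day = 7.5,   # lower-bounds onset at (this - inflection)
    surge_length_pmf = c(`1` = 0.40, `2` = 0.18, `3` = 0.16, `4` = 0.16, `5` = 0.10),
    envelope = list(
      dbt = list(inflection = tnorm_spec(-5.82, 1.82, -8, -2),
                 peak_gap   = tnorm_spec(3.24, 0.51, 0.5, 8),
                 trough     = tnorm_spec(2.06, 1.02, 0, 5)),
      rmssd = list(inflection = tnorm_spec(-5.82, 1.53, -8, -2),
                   peak_gap   = tnorm_spec(3.24, 0.43, 0.5, 8),
                   trough     = tnorm_spec(2.11, 1.27, 0, 5)),
      peak_clamp = 2, trough_min_gap = 0.5,
      amplitude = c(start = 1.3, baseline = 1, peak = 2, trough = 0.5, recovered = 1),
      recovery_days = 3
    ),
    within_sd_frac = 0.25,
    channels = list(
      dbt = list(dt_min = 1, base = 34.5, circadian_amp = 1.0, circadian_peak_h = 4,
                 ur_periods_h = c(3.0, 2.4), ur_amps = c(0.30, 0.30),
                 ar_phi = 0.9, ar_sd = 0.001, luteal_shift = 0.3,
                 envelope_modulated = TRUE, sleeping_only = FALSE),
      rmssd = list(dt_min = 5, base = 45, circadian_amp = 0, circadian_peak_h = 4,
                   ur_periods_h = 24 / 7, ur_amps = 8,
                   ar_phi = 0.9, ar_sd = 0.02, luteal_shift = -8,
                   envelope_modulated = TRUE, sleeping_only = TRUE),
      hr = list(dt_min = 5, base = 58, circadian_amp = 0, circadian_peak_h = 4,
                ur_periods_h = 24 / 9, ur_amps = 1.5,
                ar_phi = 0.9, ar_sd = 0.5, luteal_shift = 2,
                envelope_modulated = FALSE, sleeping_only = TRUE)
    ),
    luteal_ramp_days = 1,
    sleep = list(onset_h = 23.5, offset_h = 7.5, jitter_min = 0),
    hormones = list(
      e2  = list(base = 1.5, peak_mult = 3, width_d = 1.5, cv = 0.08, lod = 0.2),
      apg = list(base = 0.5, rise_mult = 5, rise_days = 6, cv = 0.12, lod = 0.2),
      bpg = list(base = 15,  rise_mult = 5, rise_days = 6, cv = 0.13, lod = 10),
      e2_offset = tnorm_spec(1.67, 1.38, 0, 4),
      peri_rise_mult = 2.5
    ),
    individuals = list(p_three = 0.25,
                       age = if (group == "premenopausal")
                         tnorm_spec(32, 4, 21, 38) else tnorm_spec(55, 5, 48, 60)),
    start_date = as.Date("2024-01-01")
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown cohort_config fields: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cfg[names(over)] <- over
  }
  validate_cohort_config(structure(cfg, class = "cohort_config"))
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!cfg$group %in% c("premenopausal", "perimenopausal"))
    stop("invalid group label", call. = FALSE)
  pmf <- cfg$surge_length_pmf
  if (abs(sum(pmf) - 1) > 1e-8 || any(pmf < 0))
    stop("surge_length_pmf must be a pmf over 1..5", call. = FALSE)
  for (ch in names(cfg$channels)) {
    p <- cfg$channels[[ch]]
    if (p$ar_sd < 0 || p$ar_phi < 0 || p$ar_phi >= 1)
      stop("invalid AR(1) parameters for channel ", ch, call. = FALSE)
    if (p$dt_min <= 0) stop("non-positive dt for channel ", ch, call. = FALSE)
  }
  sl <- cfg$sleep
  dur <- (sl$offset_h + 24 - sl$onset_h) %% 24
  if (dur <= 0 || dur >= 24) stop("sleep window must be shorter than 24 h", call. = FALSE)
  cfg
}

#' Cleaning rules for raw channel series
#'
#' Two-pass artifact rule: points outside `sd_threshold` standard
#' deviations of the whole series, and points whose absolute first
#' difference exceeds `derivative_threshold` (an intentionally extreme
#' default that only catches near-instantaneous glitches), are replaced by
#' the median of the previous hour of already-cleaned samples.
#'
#' @param sd_threshold z-score cutoff (default 4).
#' @param derivative_threshold absolute first-difference cutoff in value
#'   units per sample (default 1e5).
#' @param replace_window_min width of the prior window used for the
#'   replacement median, in minutes (default 60).
#' @export
cleaning_config <- function(sd_threshold = 4, derivative_threshold = 1e5,
                            replace_window_min = 60) {
  if (sd_threshold <= 0 || derivative_threshold <= 0 || replace_window_min <= 0)
    stop("cleaning thresholds must be positive", call. = FALSE)
  structure(list(sd_threshold = sd_threshold,
                 derivative_threshold = derivative_threshold,
                 replace_window_min = replace_window_min),
            class = "cleaning_config")
}

#' Feature-detection settings
#'
#' @param exclude_days candidate inflections on cycle days up to this
#'   value are ignored (the LH surge is very unlikely this early);
#'   default 5.
#' @param align_days relative-day window used for cohort alignment
#'   (default -7..+7 around LH onset, or around midcycle for
#'   perimenopausal cycles).
#' @param smooth_window moving-average window in samples; `NULL` uses one
#'   nominal day of samples for the channel (960 for 1-min waking DBT,
#'   96 for 5-min sleeping channels).
#' @export
detection_config <- function(exclude_days = 5, align_days = -7:7,
                             smooth_window = NULL) {
  if (exclude_days < 0) stop("exclude_days must be >= 0", call. = FALSE)
  if (!is.null(smooth_window) && smooth_window < 3)
    stop("smoothing window must span at least 3 samples", call. = FALSE)
  structure(list(exclude_days = exclude_days, align_days = align_days,
                 smooth_window = smooth_window),
            class = "detection_config")
}

# Nominal samples per analyzed day for a channel: waking minutes for DBT,
# sleeping minutes for HR/RMSSD.
nominal_day_samples <- function(channel, dt_min, sleep_dur_h = 8) {
  wake_h <- if (channel == "dbt") 24 - sleep_dur_h else sleep_dur_h
  round(wake_h * 60 / dt_min)
}

#' Write / read a cohort configuration as YAML
#'
#' The YAML file round-trips: reading it back yields a configuration
#' that generates the identical dataset.
#'
#' @param config a [cohort_config()].
#' @param path YAML file path.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- unclass(config)
  cfg$start_date <- format(cfg$start_date)
  # yaml drops the names of atomic vectors; keep keyed values as maps
  cfg$surge_length_pmf <- as.list(cfg$surge_length_pmf)
  cfg$envelope$amplitude <- as.list(cfg$envelope$amplitude)
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$start_date <- as.Date(cfg$start_date)
  cfg$surge_length_pmf <- unlist(cfg$surge_length_pmf)
  cfg$envelope$amplitude <- unlist(cfg$envelope$amplitude)
  for (ch in names(cfg$channels)) {
    cfg$channels[[ch]]$ur_periods_h <- unlist(cfg$channels[[ch]]$ur_periods_h)
    cfg$channels[[ch]]$ur_amps <- unlist(cfg$channels[[ch]]$ur_amps)
  }
  cfg$n_cycles <- as.integer(cfg$n_cycles)
  cfg$seed <- as.integer(cfg$seed)
  validate_cohort_config(structure(cfg, class = "cohort_config"))
}
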