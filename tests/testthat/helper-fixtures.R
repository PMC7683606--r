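# Shared fixture builders. Everything is generated in code at test time;
# no stored data.

# Config with all stochastic components switched off (deterministic
# channels and hormone profiles).
noise_free_config <- function(...) {
  cfg <- cohort_config(...)
  for (ch in names(cfg$channels)) cfg$channels[[ch]]$ar_sd <- 0
  for (h in c("e2", "apg", "bpg")) cfg$hormones[[h]]$cv <- 0
  cfg
}

# A canonical premenopausal cycle with fixed latent geometry close to the
# cohort means: 28 d, onset day 16, events (-5.82, -2.58, +2.06)/(+2.11).
canonical_truth <- function(cfg = cohort_config()) {
  structure(list(
    participant = "P001", age = 32, group = "premenopausal",
    cycle_length = 28L, lh_onset_day = 16L, surge_length = 2L,
    midcycle_day = 14L, flat_envelope = FALSE,
    events = list(dbt = c(inflection = -5.82, peak = -2.58, trough = 2.06),
                  rmssd = c(inflection = -5.82, peak = -2.58, trough = 2.11)),
    e2_peak_offset = 2, cycle_id = "P001_c1"), class = "cycle_truth")
}

# Build a full cycle_record from a truth (default: noise-free).
record_from_truth <- function(truth, cfg = noise_free_config(), seed = 99,
                              channels = c("dbt", "hr", "rmssd")) {
  chs <- synthesize_channels(truth, cfg, channels = channels, seed = seed)
  hl <- synthesize_hormones_and_lh(truth, cfg, seed = seed,
                                   noise = any(vapply(cfg$hormones[c("e2", "apg", "bpg")],
                                                      function(h) h$cv > 0, TRUE)))
  structure(list(cycle_id = truth$cycle_id %||% "T_c1",
                 participant = truth$participant, age = truth$age,
                 group = truth$group, start_date = as.Date("2024-01-01"),
                 cycle_length = truth$cycle_length,
                 channels = chs$channels, nights = chs$nights,
                 lh = hl$lh, hormones = hl$hormones),
            class = "cycle_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small premenopausal cohort shortcut.
tiny_cohort <- function(n = 4, seed = 11, ...) {
  generate_cohort(cohort_config(n_cycles = n, seed = seed, ...))
}
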