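# Daily LH strip results and urinary hormone metabolites.
#
# Premenopausal: the latent LH level is supra-threshold (25 mIU/mL strip
# cutoff) exactly on the surge days [onset, onset + surge_length - 1];
# strips are read daily from cycle day 10. E2 shows a Gaussian bump
# peaking a few days before onset; the pregnanediol metabolites rise
# about five-fold over the six days after onset. Perimenopausal: strips
# are positive on every sampled day (tonic LH), E2 stays at baseline
# (no significant pre-midcycle rise) and the metabolites rise modestly
# after midcycle. Multiplicative lognormal noise with the assay CVs;
# values below the limit of detection are reported at the LOD and
# flagged censored.

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, -s2 / 2, sqrt(s2)))
}

censor_lod <- function(x, lod) {
  cens <- x < lod
  x[cens] <- lod
  list(value = x, censored = cens)
}

#' Synthesize daily LH strip results and urinary hormones
#'
#' @param truth a `cycle_truth`.
#' @param config a [cohort_config()].
#' @param seed integer seed (independent sub-stream).
#' @param noise set `FALSE` to disable assay noise (deterministic
#'   profiles, used by the noiseless contracts).
#' @return List with `lh` (data.frame: day, positive) and `hormones`
#'   (data.frame: day, e2, apg, bpg and per-analyte censoring flags).
#' @export
synthesize_hormones_and_lh <- function(truth, config, seed = 1L, noise = TRUE) {
  stopifnot(inherits(truth, "cycle_truth"))
  set.seed(seed + 5L)
  len <- truth$cycle_length
  days <- seq_len(len)
  hcfg <- config$hormones

  if (truth$group == "premenopausal") {
    onset <- truth$lh_onset_day
    lh_days <- 10:len
    lh_pos <- as.integer(lh_days >= onset & lh_days <= onset + truth$surge_length - 1)
    e2_center <- onset - truth$e2_peak_offset
    e2_mult <- 1 + (hcfg$e2$peak_mult - 1) *
      exp(-0.5 * ((days - e2_center) / hcfg$e2$width_d)^2)
    rise <- function(p) 1 + (p$rise_mult - 1) * pmin(pmax((days - onset) / p$rise_days, 0), 1)
    apg_mult <- rise(hcfg$apg); bpg_mult <- rise(hcfg$bpg)
  } else {
    lh_days <- days
    lh_pos <- rep(1L, len)
    mid <- truth$midcycle_day
    e2_mult <- rep(1, len)
    peri_rise <- 1 + (hcfg$peri_rise_mult - 1) * pmin(pmax((days - mid) / 6, 0), 1)
    apg_mult <- peri_rise; bpg_mult <- peri_rise
  }

  mk <- function(p, mult) {
    raw <- p$base * mult * (if (noise) lognormal_noise(len, p$cv) else 1)
    censor_lod(raw, p$lod)
  }
  e2 <- mk(hcfg$e2, e2_mult); apg <- mk(hcfg$apg, apg_mult); bpg <- mk(hcfg$bpg, bpg_mult)

  list(lh = data.frame(day = lh_days, positive = lh_pos),
       hormones = data.frame(day = days,
                             e2 = e2$value, apg = apg$value, bpg = bpg$value,
                             e2_censored = e2$censored,
                             apg_censored = apg$censored,
                             bpg_censored = bpg$censored))
}
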