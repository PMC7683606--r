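# The latent ultradian amplitude envelope: the multiplier applied to a
# channel's ultradian component across the cycle. Piecewise linear through
# five anchors (cycle start 1.3, inflection 1.0, peak 2.0, trough 0.5,
# recovered 1.0 three days after the trough), constant outside. The
# decline from 1.3 at cycle start to 1.0 at the inflection makes the
# inflection the first derivative zero-crossing of band power after the
# early-cycle exclusion, i.e. it is what the detection chain is built to
# recover.

#' Ultradian envelope multiplier
#'
#' @param truth a `cycle_truth` from [draw_cycle_truth()].
#' @param config a [cohort_config()] (supplies the amplitude anchors).
#' @param day_rel days relative to LH surge onset (vectorized); onset
#'   itself sits at midday of the onset day.
#' @param channel `"dbt"` or `"rmssd"` (HR is never envelope-modulated).
#' @return Positive amplitude multipliers; identically 1 for
#'   flat-envelope (perimenopausal) cycles.
#' @export
ur_envelope_value <- function(truth, config, day_rel, channel = "dbt") {
  stopifnot(inherits(truth, "cycle_truth"))
  if (isTRUE(truth$flat_envelope) || is.null(truth$events))
    return(rep(1, length(day_rel)))
  ev <- truth$events[[channel]]
  if (is.null(ev)) return(rep(1, length(day_rel)))
  amp <- config$envelope$amplitude
  rel_start <- 0.5 - truth$lh_onset_day   # cycle start (tau = 0) in rel days
  xs <- c(rel_start, ev["inflection"], ev["peak"], ev["trough"],
          ev["trough"] + config$envelope$recovery_days)
  ys <- unname(amp[c("start", "baseline", "peak", "trough", "recovered")])
  approx(xs, ys, xout = day_rel, rule = 2)$y
}
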