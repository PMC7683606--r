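# Ground-truth draws for the synthetic cohort.
#
# Hierarchical structure: each event-day variable has an individual-level
# and a cycle-level standard-normal component, combined as
#   u = pnorm(a * z_individual + b * z_cycle),   a^2 + b^2 = 1,
# and mapped through the truncated-normal quantile function. The marginal
# of every event day is therefore *exactly* the configured truncated
# normal, while cycles of one individual cluster (within-individual SD =
# `within_sd_frac` of the between-individual SD, so b/a = within_sd_frac).
# The DBT and RMSSD envelopes share the same (z_individual, z_cycle) pair
# per event, i.e. they are comonotone across channels: both channels
# reflect one underlying hormonal event, which is what makes the
# "co-detected by both channels" anticipation fractions line up with the
# single-channel ones.

hier_coefs <- function(frac) {
  a <- 1 / sqrt(1 + frac^2)
  c(a = a, b = a * frac)
}

draw_z <- function() rnorm(1)

# One uniform quantile from individual + cycle z-scores.
hier_u <- function(z_ind, z_cyc, frac) {
  k <- hier_coefs(frac)
  pnorm(k[["a"]] * z_ind + k[["b"]] * z_cyc)
}

#' Individual-level latent state for the cohort generator
#'
#' Draws the per-individual random effects (one standard-normal score per
#' event-day variable) plus age. Consumed by [draw_cycle_truth()].
#'
#' @param config a [cohort_config()].
#' @param participant participant identifier.
#' @export
draw_individual <- function(config, participant = "P01") {
  age_spec <- config$individuals$age
  list(participant = participant,
       age = round(rtnorm(1, age_spec$mean, age_spec$sd, age_spec$lower, age_spec$upper)),
       z = list(cycle_length = draw_z(), lh_onset = draw_z(),
                inflection = draw_z(), peak_gap = draw_z(),
                trough = draw_z(), e2_offset = draw_z()))
}

#' Draw one cycle's ground truth
#'
#' Returns the latent quantities of a synthetic cycle: cycle length, LH
#' onset day and surge length (premenopausal), the per-channel envelope
#' event days relative to onset (first inflection, subsequent peak,
#' post-surge trough, satisfying inflection < peak < trough), and the E2
#' peak offset. Perimenopausal cycles carry no onset and a flat envelope;
#' the cycle midpoint is recorded for downstream alignment.
#'
#' @param config a [cohort_config()].
#' @param individual output of [draw_individual()]; `NULL` draws a fresh
#'   individual (its cycles then do not cluster with any other cycle).
#' @return An object of class `cycle_truth`.
#' @export
draw_cycle_truth <- function(config, individual = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(individual)) individual <- draw_individual(config)
  frac <- config$within_sd_frac
  z <- individual$z
  qd <- function(spec, z_ind, lower = spec$lower, upper = spec$upper) {
    qtnorm(hier_u(z_ind, draw_z(), frac), spec$mean, spec$sd, lower, upper)
  }

  len <- as.integer(round(qd(config$cycle_length, z$cycle_length)))

  if (config$group == "perimenopausal") {
    return(structure(list(
      participant = individual$participant, age = individual$age,
      group = "perimenopausal", cycle_length = len,
      lh_onset_day = NA_integer_, surge_length = NA_integer_,
      midcycle_day = as.integer(len %/% 2), flat_envelope = TRUE,
      events = NULL, e2_peak_offset = NA_real_), class = "cycle_truth"))
  }

  env <- config$envelope
  # shared quantile per event -> comonotone DBT/RMSSD event days
  u_inf <- hier_u(z$inflection, draw_z(), frac)
  u_gap <- hier_u(z$peak_gap, draw_z(), frac)
  u_tro <- hier_u(z$trough, draw_z(), frac)
  events <- lapply(env[c("dbt", "rmssd")], function(e) {
    inf <- qtnorm(u_inf, e$inflection$mean, e$inflection$sd,
                  e$inflection$lower, e$inflection$upper)
    gap <- qtnorm(u_gap, e$peak_gap$mean, e$peak_gap$sd,
                  e$peak_gap$lower, e$peak_gap$upper)
    pk <- min(inf + gap, env$peak_clamp)
    tro <- max(qtnorm(u_tro, e$trough$mean, e$trough$sd,
                      e$trough$lower, e$trough$upper),
               pk + env$trough_min_gap)
    c(inflection = inf, peak = pk, trough = tro)
  })

  # onset: lower bound keeps the earliest latent inflection on the
  # analyzable side of the first-5-day exclusion
  inf_min <- min(events$dbt["inflection"], events$rmssd["inflection"])
  on_spec <- config$lh_onset
  # lower bound: inflection must fall after the first-5-day exclusion, and
  # the 20-night deviation reference must reach back before the luteal
  # rise on every night of the cycle (criterion d)
  on_lo <- max(on_spec$lower, config$min_inflection_day - inf_min, len - 22)
  on_hi <- min(on_spec$upper, len - 7)
  if (on_lo >= on_hi) on_lo <- on_hi - 1e-9
  onset <- round(qd(on_spec, z$lh_onset, lower = on_lo, upper = on_hi))
  onset <- min(max(onset, ceiling(on_lo)), len - 7)

  surge <- sample(as.integer(names(config$surge_length_pmf)), 1,
                  prob = config$surge_length_pmf)
  e2_off <- round(qd(config$hormones$e2_offset, z$e2_offset))

  structure(list(
    participant = individual$participant, age = individual$age,
    group = "premenopausal", cycle_length = len,
    lh_onset_day = as.integer(onset), surge_length = surge,
    midcycle_day = as.integer(len %/% 2), flat_envelope = FALSE,
    events = events, e2_peak_offset = e2_off), class = "cycle_truth")
}

#' @export
print.cycle_truth <- function(x, ...) {
  cat(sprintf("<cycle_truth> %s %s, %d d", x$participant, x$group, x$cycle_length))
  if (x$group == "premenopausal") {
    cat(sprintf(", LH onset day %d (surge %d d)\n", x$lh_onset_day, x$surge_length))
    ev <- x$events$dbt
    cat(sprintf("  dbt events rel. onset: inflection %.2f, peak %.2f, trough %.2f\n",
                ev["inflection"], ev["peak"], ev["trough"]))
  } else cat(", tonic LH (midcycle day ", x$midcycle_day, ")\n", sep = "")
  invisible(x)
}
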