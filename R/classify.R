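# Cycle inclusion/exclusion and group assignment.

#' Detect the LH surge onset from daily strip results
#'
#' Onset is the first positive day when the positives form a single
#' localized run of at most `max_run` days. A series positive on at
#' least `tonic_frac` of its sampled days (spanning the cycle) is the
#' tonic pattern seen in perimenopausal cycles and yields no onset.
#' The "localized" and "tonic" thresholds operationalize the study's
#' qualitative wording and are exposed as arguments.
#'
#' @param lh data.frame with `day` and `positive` (0/1).
#' @param max_run maximum length of a localized surge run (default 5).
#' @param tonic_frac fraction of positive sampled days that defines the
#'   tonic pattern (default 0.8).
#' @return List: `onset` (day or `NA`), `pattern` one of `"localized"`,
#'   `"tonic"`, `"none"`, `"non-localized"`.
#' @export
detect_lh_onset <- function(lh, max_run = 5, tonic_frac = 0.8) {
  stopifnot(all(c("day", "positive") %in% names(lh)))
  lh <- lh[order(lh$day), ]
  pos <- lh$day[lh$positive == 1]
  if (!length(pos)) return(list(onset = NA_integer_, pattern = "none"))
  if (length(pos) / nrow(lh) >= tonic_frac)
    return(list(onset = NA_integer_, pattern = "tonic"))
  runs <- split(pos, cumsum(c(1, diff(pos) > 1)))
  if (length(runs) == 1 && length(runs[[1]]) <= max_run)
    return(list(onset = as.integer(pos[1]), pattern = "localized"))
  list(onset = NA_integer_, pattern = "non-localized")
}

#' Classify a cycle for inclusion
#'
#' Applies the study rules: a cycle is premenopausal-included when (a) a
#' localized LH surge onset exists, (d) the nightly temperature deviation
#' is positive from two days after onset to the end of the cycle
#' (wherever defined), and, when daily hormones were collected, (b) E2
#' rises before or coincident with the surge (max over onset-4..onset
#' above 1.5x the follicular median) and (c) both pregnanediol
#' metabolites subsequently rise (means over onset+3..onset+8 above 2x
#' their follicular medians). A cycle with any night lacking channel
#' data within 16 days of onset is excluded (missing data distorts the
#' rhythmic power estimate). The tonic LH pattern with age > 45 defines
#' a perimenopausal cycle.
#'
#' @param record a `cycle_record`.
#' @param onset output of [detect_lh_onset()] (computed if missing).
#' @param deviations output of [nightly_temperature_deviation()]
#'   (computed if missing).
#' @return A `cycle_status`: `group` in
#'   {premenopausal-included, perimenopausal, excluded} and `reasons`.
#' @export
classify_cycle <- function(record, onset = NULL, deviations = NULL) {
  stopifnot(inherits(record, "cycle_record"))
  if (is.null(onset)) onset <- detect_lh_onset(record$lh)
  reasons <- character(0)

  if (!is.na(onset$onset) && identical(onset$pattern, "tonic"))
    stop("contradictory LH pattern: onset present and tonic", call. = FALSE)

  if (identical(onset$pattern, "tonic")) {
    if (!is.null(record$age) && record$age > 45)
      return(structure(list(group = "perimenopausal", reasons = character(0)),
                       class = "cycle_status"))
    return(structure(list(group = "excluded",
                          reasons = "perimenopausal-definition"),
                     class = "cycle_status"))
  }
  if (is.na(onset$onset)) reasons <- c(reasons, "a")

  if (!is.na(onset$onset)) {
    # (d) positive deviation from onset+2 to cycle end (where defined)
    if (is.null(deviations)) deviations <- nightly_temperature_deviation(record)
    dd <- deviations[deviations$night >= onset$onset + 2, , drop = FALSE]
    if (nrow(dd) && any(dd$deviation <= 0, na.rm = TRUE))
      reasons <- c(reasons, "d")

    # missing-data rule: every night within 16 days of onset must have
    # data on all collected channels
    nights <- record$nights
    nr <- nights[nights$night >= onset$onset - 16 & nights$night <= onset$onset + 16, ,
                 drop = FALSE]
    miss <- FALSE
    for (ch in names(record$channels)) {
      t <- record$channels[[ch]]$t_min
      covered <- if (ch == "dbt") unique(floor(t / 1440) + 1)
                 else unique(sleep_night_of(t, nights))
      if (!all(nr$night %in% covered)) { miss <- TRUE; break }
    }
    if (miss) reasons <- c(reasons, "missing-data")

    # (b)/(c) hormonal criteria when the panel exists
    h <- record$hormones
    if (!is.null(h)) {
      fol <- h[h$day < onset$onset - 4, , drop = FALSE]
      if (nrow(fol) >= 3) {
        peri <- h[h$day >= onset$onset - 4 & h$day <= onset$onset, , drop = FALSE]
        if (!nrow(peri) || max(peri$e2) <= 1.5 * median(fol$e2))
          reasons <- c(reasons, "b")
        lut <- h[h$day >= onset$onset + 3 & h$day <= onset$onset + 8, , drop = FALSE]
        if (!nrow(lut) || mean(lut$apg) <= 2 * median(fol$apg) ||
            mean(lut$bpg) <= 2 * median(fol$bpg))
          reasons <- c(reasons, "c")
      }
    }
  }

  structure(list(group = if (length(reasons)) "excluded" else "premenopausal-included",
                 reasons = reasons),
            class = "cycle_status")
}
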