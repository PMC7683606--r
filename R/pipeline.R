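# End-to-end wiring: per-cycle analysis chain, cohort analysis, and the
# simulate / analyze / report entry points used by the analysis scripts.

#' Analyze one cycle on one channel
#'
#' The full chain: clean, excerpt waking (DBT) or sleeping (HR/RMSSD)
#' samples, concatenate, Morse wavelet transform, band-mean power, trim
#' the first and last day, z-score + daily smoothing, detect the
#' anticipation features relative to the detected LH onset (midcycle for
#' perimenopausal cycles).
#'
#' @param record a `cycle_record`.
#' @param channel channel name.
#' @param band_h analysis band in hours (default ultradian 2-5 h).
#' @param morse [morse_params()].
#' @param cleaning [cleaning_config()].
#' @param detection [detection_config()].
#' @param power `"squared"` or `"modulus"`.
#' @return List: `features` (`feature_set`), `wp` (trimmed
#'   `wavelet_power` with `$processed`), `align_day`, `used_midcycle`,
#'   `audit` (replacement/interpolation/missing-night counts).
#' @export
analyze_cycle <- function(record, channel = "dbt", band_h = c(2, 5),
                          morse = morse_params(),
                          cleaning = cleaning_config(),
                          detection = detection_config(),
                          power = "squared") {
  stopifnot(inherits(record, "cycle_record"))
  ch <- record$channels[[channel]]
  if (is.null(ch)) stop("record ", record$cycle_id, " lacks channel ", channel,
                        call. = FALSE)
  cl <- clean_series(ch$value, dt_min = if (channel == "dbt") 1 else 5,
                     config = cleaning)
  series <- segment_and_concatenate(record, channel, values = cl$values)
  wp <- channel_band_power(series, band_h = band_h, params = morse, power = power)
  wp <- trim_edge_days(wp)
  wp <- zscore_and_smooth(wp, config = detection, cycle_id = record$cycle_id)

  onset <- detect_lh_onset(record$lh)
  used_mid <- is.na(onset$onset)
  align_day <- if (used_mid) floor(record$cycle_length / 2) else onset$onset
  fs <- detect_anticipation_features(wp, align_day, config = detection)
  list(features = fs, wp = wp, align_day = align_day, used_midcycle = used_mid,
       audit = list(n_replaced = cl$n_replaced,
                    n_interpolated = sum(series$interpolated),
                    missing_days = series$missing_days))
}

#' Analyze a cohort of cycles
#'
#' Classifies every cycle (inclusion rules and group assignment), then
#' runs [analyze_cycle()] on each analyzable cycle and channel, builds
#' the aligned cohort curves, the cumulative anticipation summary and
#' the cohort statistics (slope-trend and peak-vs-trough Kruskal-Wallis
#' per channel).
#'
#' @param records list of `cycle_record`s.
#' @param channels channels to analyze.
#' @param classify apply the inclusion rules (default TRUE); when FALSE
#'   all cycles are analyzed as-is.
#' @param ... passed to [analyze_cycle()].
#' @return List: `status` (data.frame), `features` (data.frame),
#'   `aligned` (per channel), `summary`, `stats` (per channel), `audit`.
#' @export
analyze_cohort <- function(records, channels = c("dbt", "rmssd"),
                           classify = TRUE, ...) {
  stopifnot(length(records) >= 1)
  status <- lapply(records, function(r)
    if (classify) classify_cycle(r) else
      structure(list(group = if (r$group == "perimenopausal") "perimenopausal"
                     else "premenopausal-included",
                     reasons = character(0)), class = "cycle_status"))
  status_df <- data.frame(
    cycle_id = vapply(records, `[[`, "", "cycle_id"),
    participant = vapply(records, `[[`, "", "participant"),
    group = vapply(status, `[[`, "", "group"),
    reasons = vapply(status, function(s) paste(s$reasons, collapse = ";"), ""))
  usable <- status_df$group != "excluded"
  if (!any(usable))
    stop("no cycles pass the inclusion rules: ",
         paste(unique(status_df$reasons[status_df$reasons != ""]), collapse = ", "),
         call. = FALSE)

  feats <- list(); wps <- list(); aligns <- list(); audits <- list()
  for (ch in channels) {
    res <- lapply(which(usable), function(i) analyze_cycle(records[[i]], ch, ...))
    feats[[ch]] <- data.frame(
      cycle_id = status_df$cycle_id[usable],
      participant = status_df$participant[usable],
      channel = ch,
      inflection = vapply(res, function(r) r$features$inflection, numeric(1)),
      peak = vapply(res, function(r) r$features$peak, numeric(1)),
      trough = vapply(res, function(r) r$features$trough, numeric(1)))
    wps[[ch]] <- lapply(res, `[[`, "wp")
    aligns[[ch]] <- vapply(res, `[[`, numeric(1), "align_day")
    audits[[ch]] <- lapply(res, `[[`, "audit")
    attr(wps[[ch]], "feature_sets") <- lapply(res, `[[`, "features")
  }
  features_df <- do.call(rbind, feats)

  aligned <- lapply(channels, function(ch)
    align_and_aggregate(wps[[ch]], aligns[[ch]]))
  names(aligned) <- channels

  stats_out <- lapply(channels, function(ch) {
    list(slope_trend = tryCatch(slope_trend_test(aligned[[ch]]),
                                error = function(e) NULL, warning = function(w)
                                  suppressWarnings(slope_trend_test(aligned[[ch]]))),
         peak_trough = tryCatch(peak_trough_test(wps[[ch]],
                                                 attr(wps[[ch]], "feature_sets")),
                                error = function(e) NULL))
  })
  names(stats_out) <- channels

  list(status = status_df, features = features_df,
       aligned = aligned,
       summary = anticipation_summary(features_df),
       stats = stats_out,
       audit = audits)
}

config_digest <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Simulate a cohort and write it to disk
#'
#' @param config a [cohort_config()].
#' @param out output dataset directory.
#' @param overwrite replace an existing dataset.
#' @return The dataset path, invisibly; a `manifest.json` with the
#'   config hash and seed is written alongside the cycles.
#' @export
run_simulate <- function(config, out, overwrite = FALSE) {
  ds <- generate_cohort(config)
  tmp <- paste0(out, ".partial")
  unlink(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  write_dataset(ds, tmp, overwrite = TRUE)
  jsonlite::write_json(list(n_cycles = config$n_cycles, group = config$group,
                            seed = config$seed, config_md5 = config_digest(config)),
                       file.path(tmp, "manifest.json"), auto_unbox = TRUE)
  if (dir.exists(out)) {
    if (!overwrite) stop("output exists: ", out, call. = FALSE)
    unlink(out, recursive = TRUE)
  }
  file.rename(tmp, out)
  ok <- TRUE
  invisible(out)
}

#' Analyze a dataset directory and write results
#'
#' Runs [analyze_cohort()] and writes `status.csv`, `features.json`,
#' `aligned_<channel>.csv` (relative_day, mean, sd, n), `summary.json`,
#' `stats.json` and `audit.json` under `out`.
#'
#' @param dataset a dataset directory path, or a list of `cycle_record`s.
#' @param out results directory (created).
#' @param channels channels to analyze.
#' @param ... passed to [analyze_cohort()].
#' @return The [analyze_cohort()] result, invisibly.
#' @export
run_analyze <- function(dataset, out, channels = c("dbt", "rmssd"), ...) {
  records <- if (is.character(dataset)) read_dataset(dataset) else dataset
  res <- analyze_cohort(records, channels = channels, ...)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(res$status, file.path(out, "status.csv"))
  jsonlite::write_json(res$features, file.path(out, "features.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (ch in names(res$aligned)) {
    al <- res$aligned[[ch]]
    data.table::fwrite(data.table::data.table(
      relative_day = al$days, mean = al$mean, sd = al$sd, n = al$n),
      file.path(out, paste0("aligned_", ch, ".csv")))
  }
  jsonlite::write_json(list(days = res$summary$days,
                            cumulative = res$summary$cumulative,
                            range_ratio = as.list(res$summary$range_ratio),
                            n_cycles = res$summary$n_cycles),
                       file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
  st <- lapply(res$stats, function(s) lapply(s, function(x)
    if (is.null(x)) NULL else unclass(x)))
  jsonlite::write_json(st, file.path(out, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(res$audit, file.path(out, "audit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Render a human-readable summary of an analysis results directory
#'
#' Aggregates (no recomputation) the per-cycle features and summaries
#' already on disk into a markdown report: mean +/- SD detected event
#' days per channel, cumulative anticipation fractions, statistics.
#'
#' @param results_dir directory written by [run_analyze()].
#' @param out output markdown file (default `report.md` inside
#'   `results_dir`).
#' @return The report path, invisibly.
#' @export
run_report <- function(results_dir, out = file.path(results_dir, "report.md")) {
  need <- c("features.json", "summary.json", "stats.json")
  miss <- need[!file.exists(file.path(results_dir, need))]
  if (length(miss))
    stop("incomplete results directory; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  feats <- jsonlite::read_json(file.path(results_dir, "features.json"),
                               simplifyVector = TRUE)
  summ <- jsonlite::read_json(file.path(results_dir, "summary.json"),
                              simplifyVector = TRUE)
  stats <- jsonlite::read_json(file.path(results_dir, "stats.json"),
                               simplifyVector = TRUE)
  lines <- c("# Ultradian power surge-anticipation report", "",
             sprintf("Cycles analyzed: %d", summ$n_cycles), "",
             "## Detected feature days (relative to LH onset)", "",
             "| channel | inflection | peak | trough |",
             "|---|---|---|---|")
  for (ch in unique(feats$channel)) {
    f <- feats[feats$channel == ch, ]
    msd <- function(v) sprintf("%.2f (%.2f), n=%d",
                               mean(v, na.rm = TRUE), sd(v, na.rm = TRUE),
                               sum(!is.na(v)))
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", ch,
                              msd(f$inflection), msd(f$peak), msd(f$trough)))
  }
  lines <- c(lines, "", "## Cumulative anticipation fractions", "",
             paste0("| day | ", paste(names(summ$cumulative), collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(summ$cumulative) + 1), collapse = "|"), "|"))
  for (i in seq_along(summ$days)) {
    lines <- c(lines, paste0("| ", summ$days[i], " | ",
                             paste(sprintf("%.2f", vapply(summ$cumulative,
                                                          `[`, numeric(1), i)),
                                   collapse = " | "), " |"))
  }
  lines <- c(lines, "", "## Cohort statistics", "")
  for (ch in names(stats)) {
    for (nm in names(stats[[ch]])) {
      s <- stats[[ch]][[nm]]
      if (is.null(s) || is.null(s$H)) next
      lines <- c(lines, sprintf("- %s %s: chi2 = %.3f, df = %d, p = %.4g",
                                ch, nm, s$H, s$df, s$p))
    }
  }
  writeLines(lines, out)
  invisible(out)
}
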