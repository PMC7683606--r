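# Dataset directory layout (one subdirectory per cycle):
#   channels.csv  timestamp (ISO-8601, local, tz-naive), channel, value
#   nights.csv    night, sleep_onset, sleep_offset (ISO-8601)
#   lh.csv        date, positive (0/1)
#   hormones.csv  date, e2, apg, bpg, *_censored   (optional)
#   meta.yaml     participant, cycle id, age, group, menses start
#   truth.json    generator ground truth (generator output only)

iso_ts <- function(start_date, t_min) {
  format(as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC") + round(t_min) * 60,
         "%Y-%m-%dT%H:%M:%S")
}

parse_iso_min <- function(ts, start_date, file) {
  tt <- as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- which(is.na(tt))
  if (length(bad))
    stop(sprintf("%s: unparseable timestamp '%s' at row %d", file, ts[bad[1]], bad[1]),
         call. = FALSE)
  as.numeric(difftime(tt, as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC"),
                      units = "mins"))
}

#' Write a synthetic dataset to a directory
#'
#' One subdirectory per cycle with the CSV/YAML/JSON files documented in
#' the package layout; ground truth is written to `truth.json` so
#' recovery tests can compare detected event days to latent ones.
#'
#' @param dataset a `synthetic_dataset` from [generate_cohort()].
#' @param path output directory (created; must not be an existing
#'   non-empty dataset unless `overwrite = TRUE`).
#' @param overwrite replace existing cycle directories.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, overwrite = FALSE) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (dir.exists(path) && length(dir(path)) && !overwrite)
    stop("output directory exists and is not empty: ", path, call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    tr <- dataset$truths[[i]]
    d <- file.path(path, rec$cycle_id)
    dir.create(d, showWarnings = FALSE)
    ch_tab <- data.table::rbindlist(lapply(names(rec$channels), function(ch)
      data.table::data.table(timestamp = iso_ts(rec$start_date, rec$channels[[ch]]$t_min),
                             channel = ch, value = rec$channels[[ch]]$value)))
    data.table::fwrite(ch_tab, file.path(d, "channels.csv"))
    data.table::fwrite(data.table::data.table(
      night = rec$nights$night,
      sleep_onset = iso_ts(rec$start_date, rec$nights$onset_min),
      sleep_offset = iso_ts(rec$start_date, rec$nights$offset_min)),
      file.path(d, "nights.csv"))
    data.table::fwrite(data.table::data.table(
      date = format(rec$start_date + rec$lh$day - 1), positive = rec$lh$positive),
      file.path(d, "lh.csv"))
    if (!is.null(rec$hormones)) {
      h <- rec$hormones
      data.table::fwrite(data.table::data.table(
        date = format(rec$start_date + h$day - 1),
        e2 = h$e2, apg = h$apg, bpg = h$bpg,
        e2_censored = as.integer(h$e2_censored),
        apg_censored = as.integer(h$apg_censored),
        bpg_censored = as.integer(h$bpg_censored)),
        file.path(d, "hormones.csv"))
    }
    yaml::write_yaml(list(cycle_id = rec$cycle_id, participant = rec$participant,
                          age = rec$age, group = rec$group,
                          menses_start = format(rec$start_date),
                          cycle_length = rec$cycle_length),
                     file.path(d, "meta.yaml"))
    jsonlite::write_json(unclass(tr), file.path(d, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

read_one_cycle <- function(d) {
  need <- c("channels.csv", "nights.csv", "lh.csv", "meta.yaml")
  miss <- need[!file.exists(file.path(d, need))]
  if (length(miss))
    stop(sprintf("cycle '%s': missing required file(s) %s",
                 basename(d), paste(miss, collapse = ", ")), call. = FALSE)
  meta <- yaml::read_yaml(file.path(d, "meta.yaml"))
  start_date <- as.Date(meta$menses_start)

  ch_tab <- data.table::fread(file.path(d, "channels.csv"))
  if (!all(c("timestamp", "channel", "value") %in% names(ch_tab)))
    stop(sprintf("cycle '%s': channels.csv lacks required columns", basename(d)),
         call. = FALSE)
  if (anyNA(ch_tab$value))
    stop(sprintf("cycle '%s': channels.csv has a non-numeric value at row %d",
                 basename(d), which(is.na(ch_tab$value))[1]), call. = FALSE)
  ch_tab <- as.data.frame(ch_tab)
  ch_tab$t_min <- parse_iso_min(ch_tab$timestamp, start_date, "channels.csv")
  channels <- lapply(split(ch_tab, ch_tab$channel), function(s) {
    s <- s[order(s$t_min), , drop = FALSE]
    if (anyDuplicated(s$t_min))
      stop(sprintf("cycle '%s': duplicate timestamps in channel %s",
                   basename(d), s$channel[1]), call. = FALSE)
    list(t_min = s$t_min, value = s$value)
  })

  nt <- data.table::fread(file.path(d, "nights.csv"))
  nights <- data.frame(night = nt$night,
                       onset_min = parse_iso_min(nt$sleep_onset, start_date, "nights.csv"),
                       offset_min = parse_iso_min(nt$sleep_offset, start_date, "nights.csv"))
  nights <- nights[order(nights$night), , drop = FALSE]

  lh_tab <- data.table::fread(file.path(d, "lh.csv"))
  lh <- data.frame(day = as.integer(as.Date(lh_tab$date) - start_date) + 1L,
                   positive = as.integer(lh_tab$positive))
  lh <- lh[order(lh$day), , drop = FALSE]
  if (any(lh$day < 1 | lh$day > meta$cycle_length))
    stop(sprintf("cycle '%s': LH date outside the cycle", basename(d)), call. = FALSE)

  hormones <- NULL
  if (file.exists(file.path(d, "hormones.csv"))) {
    h <- data.table::fread(file.path(d, "hormones.csv"))
    hormones <- data.frame(day = as.integer(as.Date(h$date) - start_date) + 1L,
                           e2 = h$e2, apg = h$apg, bpg = h$bpg,
                           e2_censored = as.logical(h$e2_censored),
                           apg_censored = as.logical(h$apg_censored),
                           bpg_censored = as.logical(h$bpg_censored))
    hormones <- hormones[order(hormones$day), , drop = FALSE]
  }
  truth <- NULL
  if (file.exists(file.path(d, "truth.json"))) {
    truth <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
    if (!is.null(truth$events))
      truth$events <- lapply(truth$events, function(e) unlist(e))
    truth <- structure(truth, class = "cycle_truth")
  }
  rec <- structure(list(cycle_id = meta$cycle_id, participant = meta$participant,
                        age = meta$age, group = meta$group,
                        start_date = start_date, cycle_length = meta$cycle_length,
                        channels = channels, nights = nights, lh = lh,
                        hormones = hormones), class = "cycle_record")
  list(record = rec, truth = truth)
}

#' Read a dataset directory
#'
#' Parses every cycle subdirectory into a `cycle_record`; malformed files
#' raise errors naming the cycle and offending row. Records are returned
#' sorted by participant then cycle id. Strictly increasing timestamps
#' within each channel are enforced.
#'
#' @param path dataset directory.
#' @param with_truth also read `truth.json` files when present.
#' @return List of `cycle_record` (with a `truths` attribute when
#'   `with_truth` and truth files exist).
#' @export
read_dataset <- function(path, with_truth = TRUE) {
  if (!dir.exists(path)) stop("dataset directory not found: ", path, call. = FALSE)
  dirs <- list.dirs(path, recursive = FALSE)
  if (!length(dirs)) stop("no cycle subdirectories in ", path, call. = FALSE)
  parsed <- lapply(dirs, read_one_cycle)
  ord <- order(vapply(parsed, function(p) p$record$participant, ""),
               vapply(parsed, function(p) p$record$cycle_id, ""))
  parsed <- parsed[ord]
  records <- lapply(parsed, `[[`, "record")
  if (with_truth) {
    truths <- lapply(parsed, `[[`, "truth")
    if (!all(vapply(truths, is.null, TRUE))) attr(records, "truths") <- truths
  }
  records
}
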