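# Whole-cohort generation: individuals of 2-3 cycles, per-cycle ground
# truth, channels and hormone panels assembled into `cycle_record`
# objects (the same shape [read_dataset()] returns).

#' Generate a synthetic cohort
#'
#' Draws individuals (2-3 cycles each), their per-cycle ground truth,
#' and the wearable + hormone series. Generation is a pure function of
#' the configuration: a fixed `config$seed` reproduces the dataset
#' bit-for-bit. Each cycle uses derived sub-seeds, so truths are
#' unaffected by which channels are generated.
#'
#' @param config a [cohort_config()].
#' @param channels channels to synthesize (default all three).
#' @param hormones fraction (0-1) or count of cycles that carry the daily
#'   urinary hormone panel; default 1 (all cycles).
#' @return An object of class `synthetic_dataset`: list of `records`
#'   (`cycle_record`), parallel `truths` (`cycle_truth`), and the
#'   `config`.
#' @export
generate_cohort <- function(config, channels = c("dbt", "hr", "rmssd"),
                            hormones = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_cycles

  # individual sizes: 2 or 3 cycles each, adjusted to sum exactly to n
  if (n == 1L) {
    sizes <- 1L
  } else {
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, ifelse(runif(1) < config$individuals$p_three, 3L, 2L))
    over <- sum(sizes) - n
    if (over == 1L) {
      i3 <- which(sizes == 3L)
      if (length(i3)) sizes[i3[1]] <- 2L
      else { sizes <- sizes[-1]; sizes[1] <- 3L }   # two 2s -> one 3
    } else if (over == 2L) {
      i2 <- which(sizes == 2L)
      if (length(i2)) sizes <- sizes[-i2[1]]
      else { i3 <- which(sizes == 3L); sizes[i3[1:2]] <- 2L }  # 3+3 -> 2+2
    }
  }

  truths <- vector("list", n)
  idx <- 0L
  for (i in seq_along(sizes)) {
    ind <- draw_individual(config, participant = sprintf("P%03d", i))
    for (k in seq_len(sizes[i])) {
      idx <- idx + 1L
      tr <- draw_cycle_truth(config, ind)
      tr$cycle_id <- sprintf("%s_c%d", ind$participant, k)
      truths[[idx]] <- tr
    }
  }

  n_h <- if (hormones <= 1) round(hormones * n) else min(round(hormones), n)
  records <- vector("list", n)
  date_cursor <- config$start_date
  prev_part <- ""
  for (i in seq_len(n)) {
    tr <- truths[[i]]
    if (tr$participant != prev_part) {
      date_cursor <- config$start_date + (match(tr$participant, sprintf("P%03d", seq_along(sizes))) - 1) * 150
      prev_part <- tr$participant
    }
    cyc_seed <- config$seed + i * 1000L
    chs <- synthesize_channels(tr, config, channels = channels, seed = cyc_seed)
    hl <- synthesize_hormones_and_lh(tr, config, seed = cyc_seed)
    records[[i]] <- structure(list(
      cycle_id = tr$cycle_id, participant = tr$participant,
      age = tr$age, group = tr$group,
      start_date = date_cursor, cycle_length = tr$cycle_length,
      channels = chs$channels, nights = chs$nights,
      lh = hl$lh,
      hormones = if (i <= n_h) hl$hormones else NULL
    ), class = "cycle_record")
    date_cursor <- date_cursor + tr$cycle_length
  }
  structure(list(records = records, truths = truths, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d %s cycles, %d individuals, seed %d\n",
              length(x$records), x$config$group,
              length(unique(vapply(x$records, `[[`, "", "participant"))),
              x$config$seed))
  invisible(x)
}

#' @export
print.cycle_record <- function(x, ...) {
  cat(sprintf("<cycle_record> %s (%s, age %d): %d d from %s; channels: %s%s\n",
              x$cycle_id, x$group, x$age, x$cycle_length, format(x$start_date),
              paste(names(x$channels), collapse = ", "),
              if (is.null(x$hormones)) "" else "; daily hormones"))
  invisible(x)
}
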