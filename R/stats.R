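# Cohort statistics: Kruskal-Wallis comparisons of slopes and of
# peak/trough band power, and one-way repeated-measures ANOVA with
# per-day contrasts for the hormone panels.

#' Kruskal-Wallis test across groups
#'
#' Mid-rank H statistic with tie correction (chi-squared distributed
#' with k-1 df), as used for all cohort power comparisons; identical
#' pooled values across groups return H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return A `kw_result`: `H`, `df`, `p`, `n` (group sizes).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(!lengths(groups)))
    stop("need at least two non-empty groups", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1)
    return(structure(list(H = 0, df = length(groups) - 1L, p = 1,
                          n = unname(lengths(groups))), class = "kw_result"))
  kt <- kruskal.test(x, g)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, n = unname(lengths(groups))),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi2 = %.4g, df = %d, p = %.4g (n = %s)\n",
              x$H, x$df, x$p, paste(x$n, collapse = "/")))
  invisible(x)
}

ls_slope <- function(x, y) {
  if (anyNA(y)) return(NA_real_)
  cov(x, y) / var(x)
}

#' Slope-trend comparison around the surge
#'
#' The dominant cohort pattern is an inflection followed by a peak, so
#' the trend leading up to the surge is compared with the trend after it
#' on slopes rather than raw values: per cycle, the least-squares slope
#' of aligned daily power over the pre-window (default -7..0) and the
#' post-window (0..+7); the two slope sets are compared by
#' Kruskal-Wallis. Cycles lacking a complete window are dropped (with a
#' warning; dropped count returned).
#'
#' @param aligned output of [align_and_aggregate()].
#' @param window_pre,window_post inclusive relative-day windows.
#' @return A `kw_result` with `n_dropped` attached.
#' @export
slope_trend_test <- function(aligned, window_pre = c(-7, 0), window_post = c(0, 7)) {
  d <- aligned$days
  pre_i <- d >= window_pre[1] & d <= window_pre[2]
  post_i <- d >= window_post[1] & d <= window_post[2]
  pre <- apply(aligned$per_cycle[, pre_i, drop = FALSE], 1,
               function(y) ls_slope(d[pre_i], y))
  post <- apply(aligned$per_cycle[, post_i, drop = FALSE], 1,
                function(y) ls_slope(d[post_i], y))
  ok <- !is.na(pre) & !is.na(post)
  if (!all(ok))
    warning(sum(!ok), " cycle(s) lacking a complete window dropped from the slope test")
  if (sum(ok) < 2) stop("fewer than two cycles with complete windows", call. = FALSE)
  res <- kruskal_wallis(list(pre = pre[ok], post = post[ok]))
  res$n_dropped <- sum(!ok)
  res
}

#' Peak-versus-trough band power comparison
#'
#' Each cycle contributes one peak value and one trough value: the mean
#' raw (un-z-scored) band power over a short window (default 25 min)
#' centered on its detected peak and trough; the two sets are compared
#' by Kruskal-Wallis so each cycle enters each group exactly once.
#'
#' @param wps list of (trimmed, un-z-scored) `wavelet_power` objects.
#' @param features list of `feature_set`s, parallel to `wps`.
#' @param window_min window width in minutes.
#' @return A `kw_result` with `n_omitted` (cycles lacking a feature).
#' @export
peak_trough_test <- function(wps, features, window_min = 25) {
  stopifnot(length(wps) == length(features))
  pk <- tr <- numeric(0)
  omitted <- 0L
  for (i in seq_along(wps)) {
    wp <- wps[[i]]; fs <- features[[i]]
    ipk <- fs$idx["peak"]; itr <- fs$idx["trough"]
    if (is.na(ipk) || is.na(itr)) { omitted <- omitted + 1L; next }
    half <- max(0L, floor(window_min / wp$dt_min / 2))
    win <- function(j) {
      sel <- max(1, j - half):min(length(wp$power), j + half)
      mean(wp$power[sel])
    }
    pk <- c(pk, win(ipk)); tr <- c(tr, win(itr))
  }
  if (length(pk) < 2) stop("fewer than two feature-complete cycles", call. = FALSE)
  res <- kruskal_wallis(list(peak = pk, trough = tr))
  res$n_omitted <- omitted
  res
}

#' One-way repeated-measures ANOVA with per-day contrasts
#'
#' Subjects x days matrix (e.g. one hormone, days aligned to LH onset).
#' Subjects with any missing day are dropped. The day effect F comes
#' from the standard within-subject decomposition (fitted via `aov` with
#' an `Error(subject)` stratum); each non-reference day is then compared
#' to `reference_day` by a paired t-test with Holm correction (the
#' correction label is carried in the output).
#'
#' @param mat numeric matrix, rows = subjects, columns = days (named).
#' @param reference_day column name of the reference day.
#' @return An `rmanova_result`: `F`, `df1`, `df2`, `p`, `contrasts`
#'   (day, p_raw, p_adj), `correction`, `n_subjects`.
#' @export
rm_anova_with_contrasts <- function(mat, reference_day) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- seq_len(ncol(mat))
  reference_day <- as.character(reference_day)
  if (!reference_day %in% colnames(mat))
    stop("reference day not among the columns", call. = FALSE)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  ns <- nrow(mat); nd <- ncol(mat)
  if (ns < 2 || nd < 2)
    stop("repeated-measures ANOVA needs >= 2 subjects and >= 2 days", call. = FALSE)

  if (diff(range(mat)) == 0) {
    other <- setdiff(colnames(mat), reference_day)
    return(structure(list(F = 0, df1 = nd - 1L, df2 = (ns - 1L) * (nd - 1L),
                          p = 1,
                          contrasts = data.frame(day = other,
                                                 p_raw = rep(1, length(other)),
                                                 p_adj = rep(1, length(other))),
                          correction = "holm", n_subjects = ns),
                     class = "rmanova_result"))
  }

  long <- data.frame(value = as.vector(mat),
                     subject = factor(rep(seq_len(ns), times = nd)),
                     day = factor(rep(colnames(mat), each = ns),
                                  levels = colnames(mat)))
  fit <- aov(value ~ day + Error(subject), data = long)
  sm <- summary(fit)[["Error: Within"]][[1]]
  Fv <- sm["day", "F value"]
  if (is.na(Fv)) Fv <- 0   # zero residual + zero effect degenerate case
  res_p <- sm["day", "Pr(>F)"]

  other <- setdiff(colnames(mat), reference_day)
  p_raw <- vapply(other, function(d) {
    dif <- mat[, d] - mat[, reference_day]
    if (all(dif == dif[1])) return(if (dif[1] == 0) 1 else 0)
    t.test(mat[, d], mat[, reference_day], paired = TRUE)$p.value
  }, numeric(1))
  structure(list(F = unname(Fv), df1 = sm["day", "Df"],
                 df2 = sm["Residuals", "Df"],
                 p = unname(res_p),
                 contrasts = data.frame(day = other, p_raw = p_raw,
                                        p_adj = p.adjust(p_raw, "holm")),
                 correction = "holm", n_subjects = ns),
            class = "rmanova_result")
}

#' @export
print.rmanova_result <- function(x, ...) {
  cat(sprintf("rmANOVA: F(%d, %d) = %.4g, p = %.4g (n = %d subjects; %s-corrected contrasts)\n",
              x$df1, x$df2, x$F, x$p, x$n_subjects, x$correction))
  invisible(x)
}

#' Subject-by-day hormone matrix aligned to LH onset
#'
#' Builds the input of [rm_anova_with_contrasts()] from cycle records
#' with daily hormone panels: one row per cycle, one column per relative
#' day (LH onset = day 0; midcycle for perimenopausal cycles).
#'
#' @param records list of `cycle_record`s (those without a hormone panel
#'   are skipped).
#' @param analyte `"e2"`, `"apg"` or `"bpg"`.
#' @param days relative-day window (default -7..+7).
#' @return Numeric matrix (cycles x days, `NA` where unsampled) with
#'   day names.
#' @export
hormone_day_matrix <- function(records, analyte = c("e2", "apg", "bpg"),
                               days = -7:7) {
  analyte <- match.arg(analyte)
  rows <- list()
  for (rec in records) {
    h <- rec$hormones
    if (is.null(h)) next
    onset <- detect_lh_onset(rec$lh)
    align <- if (is.na(onset$onset)) floor(rec$cycle_length / 2) else onset$onset
    v <- h[[analyte]][match(days + align, h$day)]
    rows[[rec$cycle_id]] <- v
  }
  if (!length(rows)) stop("no records carry a hormone panel", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- days
  m
}
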