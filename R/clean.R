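# Artifact cleaning for raw channel series.

#' Clean a channel series
#'
#' Two-pass rule: (1) points outside `sd_threshold` standard deviations
#' of the whole input series, (2) points whose absolute first difference
#' exceeds `derivative_threshold`. Each flagged point is replaced, in a
#' single left-to-right sweep, by the median of the preceding hour of
#' already-cleaned samples (so a replacement is never contaminated by a
#' not-yet-removed spike); if fewer than 3 prior samples exist the input
#' series median is used. A constant series (SD 0) produces no pass-1
#' flags.
#'
#' @param values numeric series (non-empty).
#' @param dt_min sampling interval in minutes (defines "the prior hour").
#' @param config a [cleaning_config()].
#' @return List: `values` (cleaned), `flags` (logical), `n_replaced`.
#' @export
clean_series <- function(values, dt_min, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  n <- length(values)
  if (n == 0) stop("cannot clean an empty series", call. = FALSE)
  mu <- mean(values); sig <- sd(values)
  flags <- if (is.na(sig) || sig == 0) rep(FALSE, n)
           else abs(values - mu) > config$sd_threshold * sig
  if (n > 1) {
    # point i is flagged when |x[i] - x[i-1]| exceeds the cutoff
    flags <- flags | c(FALSE, abs(diff(values)) > config$derivative_threshold)
  }
  out <- values
  wlen <- max(1L, floor(config$replace_window_min / dt_min))
  ser_med <- median(values)
  for (i in which(flags)) {
    lo <- max(1L, i - wlen)
    prior <- out[seq(lo, i - 1L)][seq_len(max(0L, i - lo))]
    out[i] <- if (length(prior) >= 3) median(prior) else ser_med
  }
  list(values = out, flags = flags, n_replaced = sum(flags))
}
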