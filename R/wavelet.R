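# Generalized Morse wavelet continuous transform, band-averaged power and
# edge-day trimming.
#
# The analytic Morse filter in the frequency domain is
#   Psi(w) = a * w^beta * exp(-w^gamma),  w > 0;  Psi(w <= 0) = 0,
# with `a` chosen so the peak value is 2 ("analytic" peak-amplitude
# convention): a real unit-amplitude sinusoid whose period matches a scale's
# peak period then yields |W| ~ 1 at that scale, which makes closed-form
# checks straightforward. The transform is computed per scale as
# ifft(fft(x) * Psi_s) with no padding (circular); edge contamination is
# handled downstream by dropping the first and last day of each cycle.

#' Morse wavelet parameters
#'
#' @param beta,gamma positive shape parameters of the generalized Morse
#'   wavelet. The defaults (`beta = 5`, `gamma = 3`) give a low-oscillation
#'   wavelet that favours detection of transitions in band power; findings
#'   downstream are expected to be stable for `beta` in 3-8 and `gamma`
#'   in 2-5.
#' @return An object of class `morse_params`.
#' @export
morse_params <- function(beta = 5, gamma = 3) {
  if (beta <= 0 || gamma <= 0) stop("morse parameters must be positive", call. = FALSE)
  structure(list(beta = beta, gamma = gamma), class = "morse_params")
}

#' Peak (radian) frequency of the mother Morse wavelet
#'
#' The maximum of `w^beta * exp(-w^gamma)` is at `(beta/gamma)^(1/gamma)`.
#' @param params a [morse_params()] object.
#' @export
morse_peak_freq <- function(params) {
  (params$beta / params$gamma)^(1 / params$gamma)
}

#' Geometric grid of wavelet periods
#'
#' @param span_h two-element range of periods in hours. Default spans
#'   0.5-48 h (full-day channels); sleeping-only channels use c(0.5, 8).
#' @param voices number of voices (scales) per octave.
#' @return Increasing numeric vector of periods in hours, of class
#'   `scale_grid`.
#' @export
scale_grid <- function(span_h = c(0.5, 48), voices = 16) {
  if (length(span_h) != 2 || span_h[1] <= 0 || span_h[1] >= span_h[2])
    stop("span_h must be an increasing positive range", call. = FALSE)
  n_oct <- log2(span_h[2] / span_h[1])
  p <- span_h[1] * 2^(seq(0, n_oct, by = 1 / voices))
  if (p[length(p)] < span_h[2] * (1 - 1e-9)) p <- c(p, span_h[2])
  structure(p, class = c("scale_grid", "numeric"))
}

#' Morse wavelet frequency-domain filter bank
#'
#' Evaluates the analytic Morse filter on the DFT frequency grid of an
#' `n_samples`-long series with sampling interval `dt_min` minutes, one
#' column per requested period. Peak value 2, zero at DC and at all
#' negative frequencies.
#'
#' @param params a [morse_params()] object.
#' @param periods_h wavelet peak periods in hours (e.g. a [scale_grid()]).
#' @param n_samples series length (>= 2).
#' @param dt_min sampling interval in minutes.
#' @return `n_samples` x `length(periods_h)` numeric matrix of filter
#'   values.
#' @export
morse_filter_bank <- function(params, periods_h, n_samples, dt_min) {
  stopifnot(inherits(params, "morse_params"))
  if (n_samples < 2) stop("need at least 2 samples", call. = FALSE)
  if (dt_min <= 0) stop("dt_min must be positive", call. = FALSE)
  dt_h <- dt_min / 60
  if (any(periods_h < 2 * dt_h))
    stop("scale grid contains periods below the Nyquist limit (2*dt)", call. = FALSE)
  beta <- params$beta; gamma <- params$gamma
  wp <- morse_peak_freq(params)
  k <- 0:(n_samples - 1)
  npos <- floor(n_samples / 2)               # positive-frequency bins 1..npos
  omega <- 2 * pi * k / (n_samples * dt_h)   # rad / hour
  bank <- matrix(0, nrow = n_samples, ncol = length(periods_h))
  pos <- 2:(npos + 1)
  for (j in seq_along(periods_h)) {
    s <- periods_h[j] * wp / (2 * pi)        # scale: peak at 2*pi/period
    wo <- s * omega[pos]
    # log-domain evaluation, normalized so Psi(wp) = 2
    bank[pos, j] <- 2 * exp(beta * (log(wo) - log(wp)) - (wo^gamma - beta / gamma))
  }
  bank
}

#' Continuous wavelet transform with analytic Morse filters
#'
#' FFT-based transform: per scale, the inverse DFT of `fft(x)` multiplied
#' by the Morse filter. The input is mean-removed first. No padding is
#' applied; the first and last day of each cycle are discarded downstream
#' via [trim_edge_days()].
#'
#' @param x numeric series (a concatenated, cleaned channel).
#' @param params a [morse_params()] object.
#' @param periods_h wavelet periods in hours.
#' @param dt_min sampling interval in minutes.
#' @return Complex matrix, `length(x)` rows (time) by
#'   `length(periods_h)` columns (scale).
#' @export
cwt_analytic <- function(x, params, periods_h, dt_min) {
  n <- length(x)
  if (n < 2) stop("series too short for a wavelet transform", call. = FALSE)
  dt_h <- dt_min / 60
  if (n * dt_h < 2 * max(periods_h))
    warning("series shorter than twice the longest wavelet period; edges dominate")
  bank <- morse_filter_bank(params, periods_h, n, dt_min)
  X <- fft(x - mean(x))
  M <- bank * as.complex(X)   # column-major recycling of X over scales
  mvfft(M, inverse = TRUE) / n
}

#' Band-averaged wavelet power
#'
#' Per time point, the mean over all scales whose period lies inside
#' `band_h` of the squared coefficient modulus (or the modulus itself with
#' `power = "modulus"`).
#'
#' @param coefs complex coefficient matrix from [cwt_analytic()].
#' @param periods_h the periods (hours) of the coefficient columns.
#' @param band_h two-element band in hours, e.g. `c(2, 5)` for the
#'   ultradian band or `c(23, 25)` for the circadian band.
#' @param power `"squared"` (default) or `"modulus"`.
#' @return Numeric vector of non-negative band power per sample.
#' @export
band_mean_power <- function(coefs, periods_h, band_h, power = c("squared", "modulus")) {
  power <- match.arg(power)
  in_band <- periods_h >= band_h[1] & periods_h <= band_h[2]
  if (!any(in_band)) stop("no wavelet scales inside the requested band", call. = FALSE)
  m <- Mod(coefs[, in_band, drop = FALSE])
  if (power == "squared") m <- m^2
  rowMeans(m)
}

# One-call band power for a concatenated series: transforms only the scales
# inside the band (numerically identical to computing the full grid and
# averaging the in-band columns, but much cheaper for long cohort runs).
#' Band power of a concatenated channel
#'
#' Convenience wrapper: builds the scale grid, transforms the in-band
#' scales of a [segment_and_concatenate()] result and returns a
#' `wavelet_power` object carrying the sample map.
#'
#' @param series a `concat_series` object.
#' @param band_h band of periods in hours.
#' @param params a [morse_params()] object.
#' @param grid a [scale_grid()]; defaults to 0.5-48 h for `dbt` and
#'   0.5-8 h for sleeping channels, 16 voices per octave.
#' @param power see [band_mean_power()].
#' @export
channel_band_power <- function(series, band_h = c(2, 5), params = morse_params(),
                               grid = NULL, power = "squared") {
  stopifnot(inherits(series, "concat_series"))
  if (is.null(grid)) {
    span <- if (series$channel == "dbt") c(0.5, 48) else c(0.5, 8)
    grid <- scale_grid(span)
  }
  use <- grid[grid >= band_h[1] & grid <= band_h[2]]
  if (!length(use)) stop("no wavelet scales inside the requested band", call. = FALSE)
  W <- cwt_analytic(series$values, params, use, series$dt_min)
  p <- band_mean_power(W, use, band_h, power = power)
  structure(list(power = p, day = series$day, tau = series$tau,
                 dt_min = series$dt_min, channel = series$channel,
                 band_h = band_h, trimmed = FALSE),
            class = "wavelet_power")
}

#' Drop the first and last day of a band-power series
#'
#' Wavelet transforms are contaminated at the edges of the record, so only
#' the second through second-to-last days (nights, for sleeping channels)
#' of each cycle are analyzed.
#'
#' @param wp a `wavelet_power` object.
#' @return The trimmed `wavelet_power` object (empty, with a warning, if
#'   fewer than 3 days are present).
#' @export
trim_edge_days <- function(wp) {
  stopifnot(inherits(wp, "wavelet_power"))
  days <- unique(wp$day)
  if (length(days) < 3) {
    warning("fewer than 3 days of data; edge trimming leaves nothing")
    keep <- rep(FALSE, length(wp$day))
  } else {
    keep <- wp$day != min(days) & wp$day != max(days)
  }
  wp$power <- wp$power[keep]
  wp$tau <- wp$tau[keep]
  wp$day <- wp$day[keep]
  wp$trimmed <- TRUE
  wp
}
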