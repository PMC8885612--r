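# internal: centered sliding mean with truncated (renormalized) windows at
# the record edges. Window length in samples is round(window_s * fs); an
# even length is centered up to half a sample ([i-n/2, i+n/2-1]), which
# keeps an integer number of carrier cycles inside a 1 s window at 250 Hz.
sliding_mean <- function(x, n_w) {
  n <- length(x)
  if (n_w < 2L) abort("sliding window shorter than 2 samples")
  h <- n_w %/% 2L
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L)
  hi <- pmin(idx + (n_w - h) - 1L, n)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

window_samples <- function(fs, window_s) {
  n_w <- as.integer(round(window_s * fs))
  if (n_w < 2L) abort("sliding window shorter than 2 samples")
  n_w
}

#' Band-pass filter an acceleration trace
#'
#' Applies a Butterworth band-pass (default fourth order, 0.2-50 Hz) to
#' remove slow baseline drift and the stationary gravity offset below the
#' band, and high-frequency noise above it. By default the filter is run
#' forward-backward (zero phase), so subsequent period markers carry no
#' phase delay; the effective magnitude response is then the squared
#' single-pass response.
#'
#' @param trace A uniformly sampled trace tibble (columns `t`, `v`).
#' @param cfg A [detector_config()].
#' @return A trace tibble with the same time base and the filtered values.
#' @examples
#' t <- seq(0, 10, by = 1 / 250)
#' tr <- as_trace(t = t, v = sin(2 * pi * 2 * t) + 9.8)
#' filt <- bandpass(tr, detector_config())
#' @export
bandpass <- function(trace, cfg = detector_config()) {
  trace <- as_trace(trace)
  check_uniform(trace)
  fs <- trace_fs(trace)
  if (fs <= 2 * cfg$band_high) abort("band edge above Nyquist")
  filt <- signal::butter(
    cfg$filter_order, c(cfg$band_low, cfg$band_high) / (fs / 2), type = "pass"
  )
  # demean and odd-extend around the endpoints before filtering so the
  # zero initial filter state sees no step; the high-pass edge at 0.2 Hz
  # otherwise rings for seconds into the record
  x <- trace$v - mean(trace$v)
  n <- length(x)
  p <- min(n - 1L, as.integer(round(2 * fs / cfg$band_low)))
  x_ext <- c(
    2 * x[1L] - x[(p + 1L):2L],
    x,
    2 * x[n] - x[(n - 1L):(n - p)]
  )
  v <- if (cfg$zero_phase) {
    signal::filtfilt(filt, x_ext)
  } else {
    as.numeric(signal::filter(filt, x_ext))
  }
  tibble(t = trace$t, v = v[(p + 1L):(p + n)])
}

#' Sliding absolute-mean envelope
#'
#' Computes the centered sliding mean, over a `window_s` interval, of the
#' absolute value of the (band-pass filtered) acceleration. The result is
#' nearly constant and non-vanishing while compressions are present and
#' approximately vanishing during pauses; it is the quantity all detector
#' decisions are made on. Windows are truncated and renormalized at the
#' record edges, so a constant |input| yields the same constant envelope
#' everywhere, including the edges.
#'
#' @param trace A uniformly sampled trace tibble (normally the output of
#'   [bandpass()]).
#' @param cfg A [detector_config()].
#' @return A tibble with columns `t` and `e` (envelope, input units),
#'   the same length as the input.
#' @export
sliding_abs_mean <- function(trace, cfg = detector_config()) {
  trace <- as_trace(trace)
  check_uniform(trace)
  fs <- trace_fs(trace)
  n_w <- window_samples(fs, cfg$window_s)
  tibble(t = trace$t, e = sliding_mean(abs(trace$v), n_w))
}

#' Smoothed derivative of the envelope
#'
#' First derivative of the envelope by central finite differences
#' (one-sided at the two edge samples), followed by the same centered
#' `window_s` sliding mean used for the envelope. Not yet soft-shrunk.
#'
#' @param env An envelope tibble (columns `t`, `e`) from
#'   [sliding_abs_mean()].
#' @param cfg A [detector_config()].
#' @return A tibble with columns `t` and `d` (envelope units per second).
#' @export
smooth_derivative <- function(env, cfg = detector_config()) {
  stopifnot(is.data.frame(env), all(c("t", "e") %in% names(env)))
  n <- nrow(env)
  if (n < 3L) abort("envelope too short to differentiate")
  dt <- median(diff(env$t))
  fs <- 1 / dt
  e <- env$e
  d_raw <- numeric(n)
  d_raw[2:(n - 1L)] <- (e[3:n] - e[1:(n - 2L)]) / (2 * dt)
  d_raw[1L] <- (e[2L] - e[1L]) / dt
  d_raw[n] <- (e[n] - e[n - 1L]) / dt
  n_w <- window_samples(fs, cfg$window_s)
  tibble(t = env$t, d = sliding_mean(d_raw, n_w))
}

#' Soft shrinkage of the smoothed derivative
#'
#' Applies the soft-shrinkage operator `sign(x) * max(|x| - lambda, 0)`
#' elementwise, zeroing the small, non-significant minima and maxima of
#' the derivative so that only genuine envelope transitions survive as
#' extrema. When `cfg$shrink_lambda` is `NULL`, the threshold is set
#' adaptively to `cfg$shrink_frac` times the 95th percentile of `|d|`, so
#' the detector is independent of the accelerometer's internal unit scale.
#'
#' @param deriv A derivative tibble (columns `t`, `d`) from
#'   [smooth_derivative()].
#' @param cfg A [detector_config()].
#' @return A tibble with columns `t` and `d`, with attribute `lambda`
#'   holding the threshold used.
#' @export
soft_shrink <- function(deriv, cfg = detector_config()) {
  stopifnot(is.data.frame(deriv), all(c("t", "d") %in% names(deriv)))
  lambda <- shrink_threshold(deriv, cfg)
  out <- tibble(t = deriv$t, d = soft_shrink_num(deriv$d, lambda))
  attr(out, "lambda") <- lambda
  out
}

#' @rdname soft_shrink
#' @export
shrink_threshold <- function(deriv, cfg = detector_config()) {
  if (!is.null(cfg$shrink_lambda)) return(cfg$shrink_lambda)
  as.numeric(cfg$shrink_frac * quantile(abs(deriv$d), 0.95, names = FALSE))
}

soft_shrink_num <- function(x, lambda) {
  sign(x) * pmax(abs(x) - lambda, 0)
}
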