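#' Build and validate a uniformly sampled channel trace
#'
#' A trace is a tibble with columns `t` (seconds elapsed since the
#' defibrillator was switched on) and `v` (channel values in the channel's
#' native units: internal acceleration units, mV or mmHg). Timestamps are
#' carried as-is; they are never re-based to zero.
#'
#' @param x A data frame with numeric columns `t` and `v` (extra columns are
#'   dropped), or two numeric vectors via `t` and `v`.
#' @param t,v Numeric vectors of timestamps and values, used when `x` is
#'   missing.
#' @param fs_nominal Nominal sample rate in Hz, or `NULL` to skip the rate
#'   check. The observed rate (1 / median timestep) must agree within 1%.
#'
#' @return A tibble with columns `t` and `v`.
#' @examples
#' tr <- as_trace(t = seq(0, 1, by = 1 / 250), v = 0, fs_nominal = 250)
#' trace_fs(tr)
#' @export
as_trace <- function(x, t = NULL, v = NULL, fs_nominal = NULL) {
  if (missing(x)) {
    x <- tibble(t = as.numeric(t), v = as.numeric(v))
  }
  if (!is.data.frame(x) || !all(c("t", "v") %in% names(x))) {
    abort("a trace needs columns `t` and `v`")
  }
  out <- tibble(t = as.numeric(x$t), v = as.numeric(x$v))
  if (nrow(out) < 2L) abort("a trace needs at least 2 samples")
  if (anyNA(out$t) || any(!is.finite(out$t))) abort("non-finite timestamps")
  if (any(diff(out$t) <= 0)) abort("non-monotone timestamps")
  if (!is.null(fs_nominal)) {
    fs_obs <- trace_fs(out)
    if (abs(fs_obs - fs_nominal) > 0.01 * fs_nominal) {
      abort(sprintf(
        "sample-rate mismatch: observed %.3f Hz, nominal %g Hz (> 1%%)",
        fs_obs, fs_nominal
      ))
    }
  }
  out
}

#' Observed sample rate of a trace
#'
#' @param trace A trace tibble (see [as_trace()]).
#' @return Sample rate in Hz, `1 / median(diff(t))`.
#' @export
trace_fs <- function(trace) {
  1 / median(diff(trace$t))
}

# internal: fail loudly when a trace is not close enough to uniform for
# filtering / windowing (timestep spread beyond 1% of the median)
check_uniform <- function(trace) {
  dt <- diff(trace$t)
  if (any(dt <= 0)) abort("non-monotone timestamps")
  if ((max(dt) - min(dt)) > 0.01 * median(dt)) {
    abort("trace is not uniformly sampled")
  }
  invisible(trace)
}
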