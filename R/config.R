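#' Detector configuration
#'
#' Collects every tunable of the compression-period detector. Defaults are
#' the algorithm's published constants where one is published; the two
#' thresholds the method leaves open (the soft-shrinkage level and the
#' minimum compression envelope) default to adaptive, amplitude-free
#' fractions so that the detector works in the defibrillator's uncalibrated
#' internal units.
#'
#' @param band_low,band_high Butterworth band-pass critical frequencies in
#'   Hz (defaults 0.2 and 50). The band removes baseline drift and the
#'   gravity offset below, and high-frequency noise above.
#' @param filter_order Butterworth order (default 4).
#' @param zero_phase Apply the filter forward-backward (default `TRUE`), so
#'   markers are not phase-delayed; set `FALSE` for a causal single pass.
#' @param window_s Width in seconds of the centered sliding mean used for
#'   both the absolute-value envelope and the derivative smoothing
#'   (default 1.0).
#' @param pause_ratio A candidate pause is accepted only if its envelope
#'   mean is below this fraction of the average envelope of the two
#'   flanking compression periods (default 0.35).
#' @param min_pause_s Minimum accepted pause duration in seconds
#'   (default 1.6).
#' @param cc_min_level Absolute envelope floor (internal units) below which
#'   a candidate compression period is discarded, or `NULL` (default) to
#'   use `cc_min_frac` of the 90th percentile of the envelope over the
#'   candidate compression periods.
#' @param cc_min_frac Fraction for the adaptive compression floor
#'   (default 0.2).
#' @param shrink_lambda Absolute soft-shrinkage threshold in envelope
#'   units/s, or `NULL` (default) to use `shrink_frac` of the 95th
#'   percentile of the absolute smoothed derivative.
#' @param shrink_frac Fraction for the adaptive shrinkage threshold
#'   (default 0.1).
#' @param refine_window_s Width in seconds of the weighted-mean marker
#'   refinement window (default 1.0).
#' @param similar_max_ratio A second derivative maximum counts as "similarly
#'   large" — triggering the weighted-mean refinement — when its magnitude
#'   is at least this fraction of the primary maximum (default 0.5).
#' @param refine_starts,refine_stops Whether start / stop markers are
#'   refined (both default `TRUE`).
#'
#' @return A `cc_config` list.
#' @examples
#' cfg <- detector_config(min_pause_s = 2)
#' cfg$min_pause_s
#' @export
detector_config <- function(band_low = 0.2,
                            band_high = 50,
                            filter_order = 4L,
                            zero_phase = TRUE,
                            window_s = 1.0,
                            pause_ratio = 0.35,
                            min_pause_s = 1.6,
                            cc_min_level = NULL,
                            cc_min_frac = 0.2,
                            shrink_lambda = NULL,
                            shrink_frac = 0.1,
                            refine_window_s = 1.0,
                            similar_max_ratio = 0.5,
                            refine_starts = TRUE,
                            refine_stops = TRUE) {
  cfg <- structure(
    list(
      band_low = band_low, band_high = band_high,
      filter_order = as.integer(filter_order), zero_phase = isTRUE(zero_phase),
      window_s = window_s, pause_ratio = pause_ratio,
      min_pause_s = min_pause_s,
      cc_min_level = cc_min_level, cc_min_frac = cc_min_frac,
      shrink_lambda = shrink_lambda, shrink_frac = shrink_frac,
      refine_window_s = refine_window_s,
      similar_max_ratio = similar_max_ratio,
      refine_starts = isTRUE(refine_starts), refine_stops = isTRUE(refine_stops)
    ),
    class = "cc_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(band_low > 0 && band_low < band_high)) {
      abort("need 0 < band_low < band_high")
    }
    if (window_s <= 0) abort("window_s must be positive")
    if (!(pause_ratio > 0 && pause_ratio < 1)) {
      abort("pause_ratio must be in (0, 1)")
    }
    if (min_pause_s <= 0) abort("min_pause_s must be positive")
    if (!is.null(shrink_lambda) && shrink_lambda < 0) {
      abort("shrink_lambda must be >= 0")
    }
    if (!is.null(cc_min_level) && cc_min_level < 0) {
      abort("cc_min_level must be >= 0")
    }
    if (filter_order < 1L) abort("filter_order must be >= 1")
    if (refine_window_s <= 0) abort("refine_window_s must be positive")
    if (!(similar_max_ratio > 0 && similar_max_ratio <= 1)) {
      abort("similar_max_ratio must be in (0, 1]")
    }
  })
  invisible(cfg)
}

#' Read a detector configuration from a YAML file
#'
#' Any subset of the [detector_config()] fields may be given; missing
#' fields keep their defaults. Unknown fields are an error.
#'
#' @param path YAML file path.
#' @return A `cc_config` list.
#' @export
read_detector_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(detector_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(detector_config, vals)
}

#' @export
print.cc_config <- function(x, ...) {
  cat("<cc_config>\n")
  cat(sprintf("  band: %g-%g Hz, Butterworth order %d, %s\n",
              x$band_low, x$band_high, x$filter_order,
              if (x$zero_phase) "zero-phase" else "causal"))
  cat(sprintf("  window: %g s\n", x$window_s))
  cat(sprintf("  pause: >= %g s, envelope ratio < %g\n",
              x$min_pause_s, x$pause_ratio))
  cat(sprintf("  compression floor: %s\n",
              if (is.null(x$cc_min_level)) {
                sprintf("adaptive (%g x q90 envelope)", x$cc_min_frac)
              } else sprintf("%g units", x$cc_min_level)))
  cat(sprintf("  shrinkage: %s\n",
              if (is.null(x$shrink_lambda)) {
                sprintf("adaptive (%g x q95 |derivative|)", x$shrink_frac)
              } else sprintf("%g units/s", x$shrink_lambda)))
  cat(sprintf("  refinement: %g s window, similar ratio %g\n",
              x$refine_window_s, x$similar_max_ratio))
  invisible(x)
}
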