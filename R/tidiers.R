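#' Tidy a detection result
#'
#' @param x A `cc_detection` from [detect_compressions()].
#' @param ... Unused.
#' @return A tibble with one row per detected compression period: `period`,
#'   `start_s`, `stop_s`, `duration_s`, plus the pre-refinement boundaries
#'   `start_raw_s` and `stop_raw_s`.
#' @method tidy cc_detection
#' @export
tidy.cc_detection <- function(x, ...) {
  seg <- x$segmentation
  tibble(
    period = seq_len(nrow(seg)),
    start_s = seg$start_s,
    stop_s = seg$stop_s,
    duration_s = seg$stop_s - seg$start_s,
    start_raw_s = seg$start_raw_s,
    stop_raw_s = seg$stop_raw_s
  )
}

#' Summarise a detection result in one row
#'
#' @param x A `cc_detection`.
#' @param ... Unused.
#' @return A one-row tibble: number of periods, total compression time,
#'   record span, the chest compression fraction over the whole record,
#'   number of accepted pauses, and the resolved shrinkage threshold and
#'   compression floor.
#' @method glance cc_detection
#' @export
glance.cc_detection <- function(x, ...) {
  rng <- range(x$trace$t)
  final_it <- if (nrow(x$gaps) > 0L) max(x$gaps$iteration) else 0L
  acc <- x$gaps[x$gaps$iteration == final_it & x$gaps$verdict == "accepted", ]
  tibble(
    n_periods = nrow(x$segmentation),
    total_cc_s = sum(x$segmentation$stop_s - x$segmentation$start_s),
    record_s = rng[2L] - rng[1L],
    ccf = ccf_or_zero(x$segmentation, rng[1L], rng[2L]),
    n_pauses = nrow(acc),
    shrink_lambda = x$lambda,
    cc_level = x$cc_level
  )
}

ccf_or_zero <- function(seg, a, b) {
  if (b <= a) return(NA_real_)
  ccf(as_segmentation(seg[, c("start_s", "stop_s")]), a, b)
}

#' Tidy an agreement report
#'
#' @param x A `cc_agreement` from [compare_segmentations()].
#' @param ... Unused.
#' @return The matched-boundary tibble: `kind`, `t_alg`, `t_ann`,
#'   `deviation_s`.
#' @method tidy cc_agreement
#' @export
tidy.cc_agreement <- function(x, ...) {
  as_tibble(x$matched)
}

#' Summarise an agreement report in one row
#'
#' @param x A `cc_agreement`.
#' @param ... Unused.
#' @return A one-row tibble: matched and unmatched boundary counts, mean
#'   and max-absolute deviation, the overlap (Jaccard) fraction and the
#'   matching tolerance.
#' @method glance cc_agreement
#' @export
glance.cc_agreement <- function(x, ...) {
  tibble(
    n_matched = nrow(x$matched),
    unmatched_alg = x$unmatched_alg,
    unmatched_ann = x$unmatched_ann,
    mean_deviation_s = if (nrow(x$matched)) mean(x$matched$deviation_s) else NA_real_,
    max_abs_deviation_s = if (nrow(x$matched)) max(abs(x$matched$deviation_s)) else NA_real_,
    overlap_fraction = x$overlap_fraction,
    tolerance_s = x$tolerance_s
  )
}
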