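#' Chest compression fraction (CCF)
#'
#' Fraction of the arrest interval during which chest compressions are
#' delivered: the total compression time intersected with
#' `[t_arrest, t_end]`, divided by `t_end - t_arrest`. Periods partially
#' outside the window are clipped, not dropped. CCF is a standard CPR
#' quality metric; the window is usually Arrest to ROSC/Termination.
#'
#' @param seg A segmentation tibble (or anything [as_segmentation()]
#'   accepts, e.g. `tidy()` of a `cc_detection`).
#' @param t_arrest,t_end Window boundaries in seconds; `t_arrest < t_end`.
#' @return A single number in `[0, 1]`.
#' @examples
#' seg <- as_segmentation(data.frame(start_s = 0, stop_s = 60))
#' ccf(seg, t_arrest = 0, t_end = 100)
#' @export
ccf <- function(seg, t_arrest, t_end) {
  seg <- as_segmentation(seg)
  if (t_end <= t_arrest) abort("t_end must exceed t_arrest")
  lo <- pmax(seg$start_s, t_arrest)
  hi <- pmin(seg$stop_s, t_end)
  sum(pmax(hi - lo, 0)) / (t_end - t_arrest)
}

#' Agreement between two segmentations
#'
#' Quantifies how well an algorithmic segmentation reproduces an annotated
#' one. Like-kind boundaries (starts with starts, stops with stops) are
#' matched one-to-one greedily by ascending absolute deviation (ties broken
#' by earlier annotation time), keeping only pairs within `tolerance_s` —
#' the default 0.5 s is the consensus bound used when two annotators
#' disagree. Overlap is the Jaccard fraction of compression time:
#' intersection over union.
#'
#' @param alg,ann Segmentation tibbles (algorithm and annotation).
#' @param tolerance_s Maximum matched boundary deviation in seconds
#'   (default 0.5).
#' @return A `cc_agreement` object: `matched` (tibble `kind`, `t_alg`,
#'   `t_ann`, `deviation_s = t_alg - t_ann`), counts `unmatched_alg` and
#'   `unmatched_ann`, `overlap_fraction`, and `tolerance_s`.
#' @examples
#' a <- as_segmentation(data.frame(start_s = 10, stop_s = 30))
#' b <- as_segmentation(data.frame(start_s = 10.2, stop_s = 29.9))
#' compare_segmentations(a, b)
#' @export
compare_segmentations <- function(alg, ann, tolerance_s = 0.5) {
  alg <- as_segmentation(alg)
  ann <- as_segmentation(ann)
  if (tolerance_s <= 0) abort("tolerance_s must be positive")

  match_kind <- function(ta, tn, kind) {
    if (length(ta) == 0L || length(tn) == 0L) {
      return(tibble(kind = character(), t_alg = numeric(),
                    t_ann = numeric(), deviation_s = numeric()))
    }
    pairs <- tidyr::expand_grid(i = seq_along(ta), j = seq_along(tn))
    pairs$dev <- ta[pairs$i] - tn[pairs$j]
    pairs <- pairs[abs(pairs$dev) <= tolerance_s, ]
    pairs <- pairs[order(abs(pairs$dev), tn[pairs$j]), ]
    used_i <- logical(length(ta))
    used_j <- logical(length(tn))
    keep <- logical(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE; used_j[j] <- TRUE; keep[r] <- TRUE
      }
    }
    pairs <- pairs[keep, ]
    tibble(kind = kind, t_alg = ta[pairs$i], t_ann = tn[pairs$j],
           deviation_s = pairs$dev)
  }
  matched <- dplyr::bind_rows(
    match_kind(alg$start_s, ann$start_s, "start"),
    match_kind(alg$stop_s, ann$stop_s, "stop")
  )
  matched <- matched[order(matched$t_ann), ]
  n_bound <- function(s) 2L * nrow(s)

  structure(
    list(
      matched = matched,
      unmatched_alg = n_bound(alg) - nrow(matched),
      unmatched_ann = n_bound(ann) - nrow(matched),
      overlap_fraction = segmentation_overlap(alg, ann),
      tolerance_s = tolerance_s
    ),
    class = "cc_agreement"
  )
}

#' Jaccard overlap of compression time between two segmentations
#'
#' `|intersection| / |union|` of the time covered by the two period sets;
#' 1 when both are empty (perfect vacuous agreement), symmetric in its
#' arguments.
#'
#' @param a,b Segmentation tibbles.
#' @return A number in `[0, 1]`.
#' @export
segmentation_overlap <- function(a, b) {
  a <- as_segmentation(a)
  b <- as_segmentation(b)
  if (nrow(a) == 0L && nrow(b) == 0L) return(1)
  inter <- 0
  for (k in seq_len(nrow(a))) {
    lo <- pmax(b$start_s, a$start_s[k])
    hi <- pmin(b$stop_s, a$stop_s[k])
    inter <- inter + sum(pmax(hi - lo, 0))
  }
  len <- function(s) sum(s$stop_s - s$start_s)
  union <- len(a) + len(b) - inter
  if (union <= 0) return(1)
  inter / union
}

#' @export
print.cc_agreement <- function(x, ...) {
  cat("<cc_agreement>\n")
  cat(sprintf("  matched boundaries: %d (tolerance %.2f s)\n",
              nrow(x$matched), x$tolerance_s))
  if (nrow(x$matched) > 0L) {
    cat(sprintf("  deviation: mean %+.3f s, max |.| %.3f s\n",
                mean(x$matched$deviation_s), max(abs(x$matched$deviation_s))))
  }
  cat(sprintf("  unmatched: %d algorithm, %d annotation\n",
              x$unmatched_alg, x$unmatched_ann))
  cat(sprintf("  overlap fraction: %.3f\n", x$overlap_fraction))
  invisible(x)
}
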