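#' Build and validate a segmentation of chest-compression periods
#'
#' A segmentation is a tibble with columns `start_s` and `stop_s`, one row
#' per chest-compression period, sorted by start time. Periods must be
#' pairwise disjoint with `start_s < stop_s`.
#'
#' @param x A data frame with columns `start_s` and `stop_s`, or `NULL` /
#'   missing for an empty segmentation.
#' @return A validated segmentation tibble.
#' @examples
#' as_segmentation(data.frame(start_s = c(10, 40), stop_s = c(30, 70)))
#' @export
as_segmentation <- function(x = NULL) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(tibble(start_s = numeric(), stop_s = numeric()))
  }
  if (!is.data.frame(x) || !all(c("start_s", "stop_s") %in% names(x))) {
    abort("a segmentation needs columns `start_s` and `stop_s`")
  }
  out <- tibble(start_s = as.numeric(x$start_s), stop_s = as.numeric(x$stop_s))
  validate_segmentation(out)
  out
}

#' @rdname as_segmentation
#' @export
validate_segmentation <- function(x) {
  if (any(!is.finite(x$start_s)) || any(!is.finite(x$stop_s))) {
    abort("invalid segmentation: non-finite boundary")
  }
  if (any(x$stop_s <= x$start_s)) {
    abort("invalid segmentation: stop <= start")
  }
  if (nrow(x) > 1L) {
    if (is.unsorted(x$start_s, strictly = TRUE)) {
      abort("invalid segmentation: periods out of order")
    }
    if (any(x$start_s[-1L] < x$stop_s[-nrow(x)])) {
      abort("invalid segmentation: overlapping periods")
    }
  }
  invisible(x)
}

#' Write a segmentation to a two-column CSV file
#'
#' Writes the `Alg_CC-periods.csv` format: header `start_s,stop_s`, one row
#' per period, millisecond precision. `read_segmentation()` of the written
#' file reproduces the segmentation to 1 ms.
#'
#' @param seg A segmentation tibble (see [as_segmentation()]).
#' @param path Output file path.
#' @return `seg`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  seg <- as_segmentation(seg)
  df <- data.frame(
    start_s = sprintf("%.3f", seg$start_s),
    stop_s = sprintf("%.3f", seg$stop_s)
  )
  readr::write_csv(df, path)
  invisible(seg)
}

#' Read a segmentation from a two-column CSV file
#'
#' Reads period start/stop markers (the `Ann_CC-periods.csv` /
#' `Alg_CC-periods.csv` layout). A header-only file yields an empty
#' segmentation. Unordered, overlapping or inverted periods are rejected.
#'
#' @param path CSV file with columns `start_s` and `stop_s` (files with
#'   other headers are read positionally with a warning).
#' @return A validated segmentation tibble.
#' @export
read_segmentation <- function(path) {
  df <- read_channel_csv(path, c("start_s", "stop_s"))
  as_segmentation(df)
}
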