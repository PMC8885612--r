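#' Alternating extrema of the shrunk derivative
#'
#' Scans the soft-shrunk smoothed derivative for alternating maxima and
#' minima: between consecutive extrema of one kind, the absolutely largest
#' extremum of the other kind is selected. Positive extrema (envelope
#' rising) are candidate period starts, negative extrema (envelope falling)
#' candidate stops. Soft shrinkage has already zeroed non-significant
#' wiggles, so candidate regions are the non-zero sign runs of the
#' derivative; within each run the earliest absolutely largest sample wins
#' (deterministic on flat inputs).
#'
#' @param deriv A soft-shrunk derivative tibble (columns `t`, `d`) from
#'   [soft_shrink()].
#' @return A tibble of candidates with columns `time` (s), `kind`
#'   (`"start"` or `"stop"`), `strength` (`|d|` at the extremum) and `idx`
#'   (sample index), sorted by time, kinds strictly alternating. Empty when
#'   `d` is identically zero.
#' @export
alternating_extrema <- function(deriv) {
  stopifnot(is.data.frame(deriv), all(c("t", "d") %in% names(deriv)))
  d <- deriv$d
  nz <- which(d != 0)
  if (length(nz) == 0L) {
    return(tibble(time = numeric(), kind = character(),
                  strength = numeric(), idx = integer()))
  }
  s <- sign(d[nz])
  run <- cumsum(c(1L, as.integer(s[-1L] != s[-length(s)])))
  picks <- vapply(split(nz, run), function(ii) {
    ii[which.max(abs(d[ii]))]
  }, integer(1))
  picks <- unname(picks)
  tibble(
    time = deriv$t[picks],
    kind = ifelse(d[picks] > 0, "start", "stop"),
    strength = abs(d[picks]),
    idx = as.integer(picks)
  )
}

# internal: mean of the envelope over a closed time interval
env_mean <- function(env, a, b) {
  sel <- env$t >= a & env$t <= b
  if (!any(sel)) return(NA_real_)
  mean(env$e[sel])
}

# internal: the compression-envelope floor in absolute units
resolve_cc_level <- function(env, periods, cfg) {
  if (!is.null(cfg$cc_min_level)) return(cfg$cc_min_level)
  if (nrow(periods) == 0L) return(0)
  sel <- rep(FALSE, nrow(env))
  for (k in seq_len(nrow(periods))) {
    sel <- sel | (env$t >= periods$start_s[k] & env$t <= periods$stop_s[k])
  }
  if (!any(sel)) return(0)
  as.numeric(cfg$cc_min_frac * quantile(env$e[sel], 0.9, names = FALSE))
}

#' Filter candidate markers with the three acceptance rules
#'
#' Pairs alternating start/stop candidates into potential compression
#' periods and tests every pause between consecutive periods against the
#' two pause rules — duration at least `min_pause_s`, and pause envelope
#' mean below `pause_ratio` times the average envelope mean of the two
#' flanking periods — and every period against the envelope floor
#' `cc_min_level`. Rejected pauses are merged into their neighbours;
#' rejected periods are absorbed into the surrounding pause. Because a
#' merge or removal changes the neighbouring intervals, the rules are
#' re-applied until a fixpoint is reached, which makes the result
#' insensitive to the order the three conditions are listed in.
#'
#' @param candidates A candidate tibble from [alternating_extrema()], with
#'   kinds alternating, starting with `"start"` and ending with `"stop"`
#'   (use [detect_compressions()] for automatic handling of records that
#'   begin or end mid-compression).
#' @param env The envelope tibble the decisions are made on.
#' @param cfg A [detector_config()].
#' @return A list with `segmentation` (tibble `start_s`, `stop_s`,
#'   `start_strength`, `stop_strength`), `gaps` (one row per pause verdict
#'   per iteration: `iteration`, `start_s`, `stop_s`, `duration_s`,
#'   `pause_env_mean`, `flank_env_mean_pre`, `flank_env_mean_post`,
#'   `verdict` in accepted / rejected_ratio / rejected_short) and
#'   `cc_level` (the envelope floor used, units of `e`).
#' @export
filter_candidates <- function(candidates, env, cfg = detector_config()) {
  empty_gaps <- tibble(
    iteration = integer(), start_s = numeric(), stop_s = numeric(),
    duration_s = numeric(), pause_env_mean = numeric(),
    flank_env_mean_pre = numeric(), flank_env_mean_post = numeric(),
    verdict = character()
  )
  if (nrow(candidates) == 0L) {
    return(list(
      segmentation = tibble(start_s = numeric(), stop_s = numeric(),
                            start_strength = numeric(),
                            stop_strength = numeric()),
      gaps = empty_gaps, cc_level = resolve_cc_level(env, as_segmentation(), cfg)
    ))
  }
  kinds <- candidates$kind
  if (kinds[1L] != "start" || kinds[length(kinds)] != "stop" ||
      any(kinds[-1L] == kinds[-length(kinds)])) {
    abort("candidates must alternate, starting with start and ending with stop")
  }
  periods <- tibble(
    start_s = candidates$time[kinds == "start"],
    stop_s = candidates$time[kinds == "stop"],
    start_strength = candidates$strength[kinds == "start"],
    stop_strength = candidates$strength[kinds == "stop"]
  )
  cc_level <- resolve_cc_level(env, periods, cfg)

  gap_log <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    changed <- FALSE
    n <- nrow(periods)

    if (n >= 2L) {
      pre <- vapply(seq_len(n), function(k) {
        env_mean(env, periods$start_s[k], periods$stop_s[k])
      }, numeric(1))
      g_start <- periods$stop_s[-n]
      g_stop <- periods$start_s[-1L]
      g_dur <- g_stop - g_start
      g_mean <- vapply(seq_len(n - 1L), function(k) {
        env_mean(env, g_start[k], g_stop[k])
      }, numeric(1))
      flank <- (pre[-n] + pre[-1L]) / 2
      verdict <- ifelse(
        g_dur < cfg$min_pause_s, "rejected_short",
        ifelse(g_mean < cfg$pause_ratio * flank, "accepted", "rejected_ratio")
      )
      gap_log[[length(gap_log) + 1L]] <- tibble(
        iteration = it, start_s = g_start, stop_s = g_stop,
        duration_s = g_dur, pause_env_mean = g_mean,
        flank_env_mean_pre = pre[-n], flank_env_mean_post = pre[-1L],
        verdict = verdict
      )
      if (any(verdict != "accepted")) {
        # merge periods across every rejected gap
        grp <- cumsum(c(1L, as.integer(verdict == "accepted")))
        periods <- dplyr::summarise(
          dplyr::group_by(periods, grp = grp),
          start_strength = start_strength[1L],
          stop_strength = stop_strength[dplyr::n()],
          start_s = start_s[1L],
          stop_s = stop_s[dplyr::n()],
          .groups = "drop"
        )[, c("start_s", "stop_s", "start_strength", "stop_strength")]
        changed <- TRUE
      }
    }

    if (nrow(periods) > 0L) {
      pm <- vapply(seq_len(nrow(periods)), function(k) {
        env_mean(env, periods$start_s[k], periods$stop_s[k])
      }, numeric(1))
      keep <- pm >= cc_level & pm > 0
      if (!all(keep)) {
        periods <- periods[keep, ]
        changed <- TRUE
      }
    }

    if (!changed) break
  }

  gaps <- if (length(gap_log) > 0L) dplyr::bind_rows(gap_log) else empty_gaps
  list(segmentation = periods, gaps = gaps, cc_level = cc_level)
}

#' Refine a period marker by a derivative-weighted mean
#'
#' The oscillatory character of the acceleration can split a single
#' envelope transition into two similarly large maxima of the absolute
#' derivative; the true boundary lies between them. When a second local
#' maximum of `|d|` with at least `similar_max_ratio` of the primary
#' strength lies within the `refine_window_s` interval centered on the
#' marker, the marker is moved to the `|d|`-weighted mean time over that
#' interval; otherwise it is returned unchanged.
#'
#' @param t0 Marker time (s), a surviving candidate extremum.
#' @param deriv The soft-shrunk derivative tibble (`t`, `d`); the weight is
#'   `|d|`.
#' @param cfg A [detector_config()].
#' @return The refined marker time in seconds.
#' @export
refine_marker <- function(t0, deriv, cfg = detector_config()) {
  half <- cfg$refine_window_s / 2
  sel <- which(deriv$t >= t0 - half & deriv$t <= t0 + half)
  if (length(sel) < 3L) return(t0)
  a <- abs(deriv$d[sel])
  tt <- deriv$t[sel]
  i0 <- which.min(abs(tt - t0))
  s0 <- a[i0]
  if (s0 <= 0 || sum(a) <= 0) return(t0)
  interior <- 2:(length(a) - 1L)
  is_max <- a[interior] >= a[interior - 1L] &
    a[interior] >= a[interior + 1L] & a[interior] > 0
  peaks <- interior[is_max]
  dt <- median(diff(tt))
  second <- peaks[abs(tt[peaks] - t0) > 2 * dt & a[peaks] >= cfg$similar_max_ratio * s0]
  if (length(second) == 0L) return(t0)
  sum(tt * a) / sum(a)
}

#' Detect chest-compression periods in an accelerometer trace
#'
#' Runs the full detection chain on a raw accelerometer trace: band-pass
#' filtering ([bandpass()]), the 1 s absolute-mean envelope
#' ([sliding_abs_mean()]), the smoothed derivative ([smooth_derivative()]),
#' soft shrinkage ([soft_shrink()]), alternating-extrema candidate search
#' ([alternating_extrema()]), the three acceptance rules
#' ([filter_candidates()]) and weighted-mean marker refinement
#' ([refine_marker()]).
#'
#' Records that begin or end mid-compression are handled by pinning the
#' corresponding boundary to the record edge: a candidate list beginning
#' with a stop gets a synthetic start at the first sample, one ending with
#' a start a synthetic stop at the last sample, and a record with no
#' derivative extrema at all is a single full-record period whenever its
#' envelope clears the compression floor.
#'
#' @param x A trace tibble (columns `t`, `v`), or a `cc_case` (its `accel`
#'   channel is used).
#' @param cfg A [detector_config()].
#' @return A `cc_detection` object; see [tidy.cc_detection()] for the
#'   period table, `$gaps` for the pause audit log, and
#'   [autoplot.cc_detection()] for a diagnostic plot.
#' @examples
#' sim <- generate_case(preset_scenario("clean"))
#' det <- detect_compressions(sim$case)
#' tidy(det)
#' @export
detect_compressions <- function(x, cfg = detector_config()) {
  trace <- if (inherits(x, "cc_case")) x$accel else as_trace(x)
  check_uniform(trace)
  fs <- trace_fs(trace)
  n <- nrow(trace)
  if ((trace$t[n] - trace$t[1L]) < 2 * cfg$window_s) abort("record too short")

  filt <- bandpass(trace, cfg)
  env <- sliding_abs_mean(filt, cfg)
  deriv <- smooth_derivative(env, cfg)
  shr <- soft_shrink(deriv, cfg)
  lambda <- attr(shr, "lambda")

  cand <- alternating_extrema(shr)
  t_lo <- trace$t[1L]
  t_hi <- trace$t[n]

  if (nrow(cand) == 0L) {
    whole <- tibble(start_s = t_lo, stop_s = t_hi)
    cc_level <- resolve_cc_level(env, whole, cfg)
    seg <- if (mean(env$e) > cc_level && mean(env$e) > 0) {
      tibble(start_s = t_lo, stop_s = t_hi,
             start_raw_s = t_lo, stop_raw_s = t_hi)
    } else {
      tibble(start_s = numeric(), stop_s = numeric(),
             start_raw_s = numeric(), stop_raw_s = numeric())
    }
    res <- filter_candidates(cand, env, cfg)
    return(new_cc_detection(seg, res$gaps, cand, trace, filt, env, shr,
                            lambda, cc_level, cfg))
  }

  # records truncated mid-compression: pin the missing boundary to the edge
  if (cand$kind[1L] == "stop") {
    cand <- dplyr::bind_rows(
      tibble(time = t_lo, kind = "start", strength = NA_real_, idx = 1L), cand
    )
  }
  if (cand$kind[nrow(cand)] == "start") {
    cand <- dplyr::bind_rows(
      cand, tibble(time = t_hi, kind = "stop", strength = NA_real_, idx = n)
    )
  }

  res <- filter_candidates(cand, env, cfg)
  per <- res$segmentation

  # envelope and derivative inside the first/last window are computed on
  # truncated windows; when compressions are clearly ongoing at a record
  # edge, pin the adjacent boundary to the edge instead of trusting a
  # marker found inside that window
  if (nrow(per) > 0L) {
    if (env$e[1L] >= res$cc_level &&
        per$start_s[1L] - t_lo <= cfg$window_s) {
      per$start_s[1L] <- t_lo
      per$start_strength[1L] <- NA_real_
    }
    if (env$e[nrow(env)] >= res$cc_level &&
        t_hi - per$stop_s[nrow(per)] <= cfg$window_s) {
      per$stop_s[nrow(per)] <- t_hi
      per$stop_strength[nrow(per)] <- NA_real_
    }
  }

  refine_one <- function(t0, strength, enabled) {
    if (!enabled || is.na(strength)) return(t0)
    refine_marker(t0, shr, cfg)
  }
  start_ref <- vapply(seq_len(nrow(per)), function(k) {
    refine_one(per$start_s[k], per$start_strength[k], cfg$refine_starts)
  }, numeric(1))
  stop_ref <- vapply(seq_len(nrow(per)), function(k) {
    refine_one(per$stop_s[k], per$stop_strength[k], cfg$refine_stops)
  }, numeric(1))
  start_ref <- pmin(pmax(start_ref, t_lo), t_hi)
  stop_ref <- pmin(pmax(stop_ref, t_lo), t_hi)
  bad <- which(start_ref >= stop_ref)
  if (length(bad) > 0L) {
    start_ref[bad] <- per$start_s[bad]
    stop_ref[bad] <- per$stop_s[bad]
  }
  seg <- tibble(
    start_s = start_ref, stop_s = stop_ref,
    start_raw_s = per$start_s, stop_raw_s = per$stop_s
  )
  validate_segmentation(seg)

  new_cc_detection(seg, res$gaps, cand, trace, filt, env, shr,
                   lambda, res$cc_level, cfg)
}

new_cc_detection <- function(segmentation, gaps, candidates, trace, filtered,
                             env, deriv, lambda, cc_level, config) {
  structure(
    list(
      segmentation = segmentation, gaps = gaps, candidates = candidates,
      trace = trace, filtered = filtered, env = env, deriv = deriv,
      lambda = lambda, cc_level = cc_level, config = config
    ),
    class = "cc_detection"
  )
}

#' @export
print.cc_detection <- function(x, ...) {
  rng <- range(x$trace$t)
  cat(sprintf("<cc_detection> %.1f-%.1f s record\n", rng[1L], rng[2L]))
  cat(sprintf("  %d compression period(s), total %.1f s\n",
              nrow(x$segmentation),
              sum(x$segmentation$stop_s - x$segmentation$start_s)))
  acc <- x$gaps[x$gaps$verdict == "accepted" &
                  x$gaps$iteration == max(c(x$gaps$iteration, 1L)), ]
  cat(sprintf("  %d accepted pause(s)\n", nrow(acc)))
  cat(sprintf("  shrinkage lambda %.4g, compression floor %.4g\n",
              x$lambda, x$cc_level))
  invisible(x)
}
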