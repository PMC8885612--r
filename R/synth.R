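# run code with a local, restored RNG state so generation is seeded and
# leaves the caller's RNG untouched
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Describe one scenario segment
#'
#' Building blocks for [scenario()]: a chest-compression segment
#' (`seg_cc()`) delivers a sinusoidal acceleration at the compression rate;
#' a pause segment (`seg_pause()`) carries only residual motion (patient
#' handling, ventilations) of smaller amplitude.
#'
#' @param duration_s Segment duration in seconds.
#' @param rate_hz Compression (or residual-motion) frequency in Hz;
#'   default 1.833 Hz, about 110 compressions per minute.
#' @param amplitude Compression amplitude in internal acceleration units
#'   (default 1; the device's internal unit is uncalibrated, so the scale
#'   is arbitrary).
#' @param residual_amplitude Residual-motion amplitude during a pause, in
#'   the same units (default 0).
#' @return A one-row tibble with columns `kind`, `duration_s`,
#'   `cc_rate_hz`, `cc_amplitude`, `residual_amplitude`.
#' @export
seg_cc <- function(duration_s, rate_hz = 1.833, amplitude = 1) {
  stopifnot(duration_s > 0)
  tibble(kind = "cc", duration_s = duration_s, cc_rate_hz = rate_hz,
         cc_amplitude = amplitude, residual_amplitude = 0)
}

#' @rdname seg_cc
#' @export
seg_pause <- function(duration_s, residual_amplitude = 0, rate_hz = 1.833) {
  stopifnot(duration_s > 0)
  tibble(kind = "pause", duration_s = duration_s, cc_rate_hz = rate_hz,
         cc_amplitude = 0, residual_amplitude = residual_amplitude)
}

#' Define a synthetic resuscitation scenario
#'
#' A scenario is an exact schedule of compression and pause segments plus
#' the nuisance components a sternal accelerometer sees: a constant gravity
#' offset, a slow baseline drift, and broadband Gaussian noise. The
#' generated acceleration reproduces what the detector relies on — a 1 s
#' absolute-mean envelope that is nearly constant and non-vanishing during
#' compressions and nearly zero during pauses — without modelling
#' per-compression biomechanics.
#'
#' @param segments Row-bound [seg_cc()] / [seg_pause()] tibble, in order.
#' @param noise_sigma Gaussian noise standard deviation, internal units
#'   (default 0.02).
#' @param gravity_offset Constant offset, internal units (default 5);
#'   removed by the detector's high-pass edge.
#' @param drift_amplitude,drift_freq_hz Slow sinusoidal baseline drift
#'   (defaults 0.1 units at 0.01 Hz).
#' @param fs Sample rate in Hz (default 250, the accelerometer channel
#'   rate).
#' @param t0 Timestamp of the first sample in seconds since device
#'   power-on (default 0; timestamps are arbitrary offsets).
#' @param ramp_s Width of the smooth amplitude ramp at each segment
#'   boundary (default 0.3 s); the ramp is centered on the boundary, so the
#'   ground-truth boundary is the ramp midpoint.
#' @param seed Integer seed; the same scenario always generates the same
#'   case.
#' @return A `cc_scenario` object.
#' @seealso [generate_case()], [preset_scenario()]
#' @export
scenario <- function(segments, noise_sigma = 0.02, gravity_offset = 5,
                     drift_amplitude = 0.1, drift_freq_hz = 0.01,
                     fs = 250, t0 = 0, ramp_s = 0.3, seed = 1L) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L,
            all(segments$duration_s > 0), fs > 0, noise_sigma >= 0,
            ramp_s >= 0)
  if (fs <= 2 * max(segments$cc_rate_hz)) {
    abort("fs must exceed twice the compression rate")
  }
  structure(
    list(
      segments = as_tibble(segments), noise_sigma = noise_sigma,
      gravity_offset = gravity_offset, drift_amplitude = drift_amplitude,
      drift_freq_hz = drift_freq_hz, fs = fs, t0 = t0, ramp_s = ramp_s,
      seed = as.integer(seed)
    ),
    class = "cc_scenario"
  )
}

#' Named preset scenarios
#'
#' Fixed, seeded scenarios each exercising one detector behaviour:
#' `clean` — well-separated compression periods for baseline boundary
#' recovery; `noisy` — the same schedule under heavy broadband noise;
#' `residual_motion` — pauses containing residual motion around the
#' envelope-ratio acceptance boundary; `short_pauses` — pauses of 1.0 s
#' (below the duration floor) and 3.0 s (above it); `edge_truncated` — a
#' record that starts and ends mid-compression.
#'
#' @param name One of `"clean"`, `"noisy"`, `"residual_motion"`,
#'   `"short_pauses"`, `"edge_truncated"`.
#' @return A `cc_scenario` object.
#' @export
preset_scenario <- function(name) {
  clean_segments <- dplyr::bind_rows(
    seg_pause(4), seg_cc(20), seg_pause(5), seg_cc(20), seg_pause(4)
  )
  switch(name,
    clean = scenario(clean_segments, seed = 101L),
    noisy = scenario(clean_segments, noise_sigma = 0.15, seed = 102L),
    residual_motion = scenario(
      dplyr::bind_rows(
        seg_pause(3), seg_cc(20), seg_pause(3, residual_amplitude = 0.2),
        seg_cc(20), seg_pause(3, residual_amplitude = 0.5),
        seg_cc(20), seg_pause(3)
      ),
      seed = 103L
    ),
    short_pauses = scenario(
      dplyr::bind_rows(
        seg_pause(3), seg_cc(15), seg_pause(1.0), seg_cc(15),
        seg_pause(3.0), seg_cc(15), seg_pause(3)
      ),
      seed = 104L
    ),
    edge_truncated = scenario(
      dplyr::bind_rows(seg_cc(10), seg_pause(3), seg_cc(10)),
      seed = 105L
    ),
    abort(sprintf("unknown preset: %s", name))
  )
}

#' Generate a synthetic case with exact ground truth
#'
#' Renders a [scenario()] into a full `cc_case`: the accelerometer channel
#' at `fs` (compression sinusoid with smooth ramps, residual pause motion,
#' gravity offset, drift, seeded Gaussian noise), placeholder shock-pad ECG
#' (250 Hz) and capnography (125 Hz) channels that exist only to satisfy
#' the directory format, a PhysioStatus table with Arrest at the first
#' sample and ROSC/Termination at the last, and the exact compression
#' schedule both as the case's annotation and as ground truth.
#'
#' @param sc A `cc_scenario`.
#' @return A list with `case` (a `cc_case`) and `truth` (list of `periods`,
#'   the exact compression-period segmentation with boundaries at the ramp
#'   midpoints, and `env_targets`, the per-segment expected envelope level
#'   `2/pi * amplitude`).
#' @examples
#' sim <- generate_case(preset_scenario("clean"))
#' sim$truth$periods
#' @export
generate_case <- function(sc) {
  stopifnot(inherits(sc, "cc_scenario"))
  fs <- sc$fs
  total <- sum(sc$segments$duration_s)
  n <- as.integer(round(total * fs))
  t <- sc$t0 + (seq_len(n) - 1L) / fs
  rel <- t - sc$t0

  bounds <- cumsum(sc$segments$duration_s)
  seg_idx <- findInterval(rel, c(0, head(bounds, -1L)), rightmost.closed = FALSE)
  seg_idx <- pmin(seg_idx, nrow(sc$segments))

  amp_step <- ifelse(
    sc$segments$kind[seg_idx] == "cc",
    sc$segments$cc_amplitude[seg_idx],
    sc$segments$residual_amplitude[seg_idx]
  )
  amp <- smooth_profile(amp_step, m = 2L * floor(sc$ramp_s * fs / 2) + 1L)

  freq <- sc$segments$cc_rate_hz[seg_idx]
  phase <- 2 * pi * cumsum(freq) / fs

  v <- with_local_seed(sc$seed, {
    amp * sin(phase) +
      sc$gravity_offset +
      sc$drift_amplitude * sin(2 * pi * sc$drift_freq_hz * rel) +
      rnorm(n, 0, sc$noise_sigma)
  })
  accel <- as_trace(t = t, v = v, fs_nominal = fs)

  ecg <- as_trace(t = t, v = 0.8 * sin(2 * pi * 1.3 * rel), fs_nominal = fs)
  n_cap <- as.integer(round(total * 125))
  t_cap <- sc$t0 + (seq_len(n_cap) - 1L) / 125
  capno <- as_trace(
    t = t_cap, v = 38 + 4 * sin(2 * pi * 0.25 * (t_cap - sc$t0)),
    fs_nominal = 125
  )

  truth_periods <- schedule_periods(sc)
  # the last schedule boundary can exceed the final sample by < 1 sample
  truth_periods$start_s <- pmax(truth_periods$start_s, t[1L])
  truth_periods$stop_s <- pmin(truth_periods$stop_s, t[n])
  physio <- tibble(
    label = c("Arrest", "ROSC/Termination"),
    time_s = c(t[1L], t[n])
  )
  env_targets <- tibble(
    segment = seq_len(nrow(sc$segments)),
    kind = sc$segments$kind,
    env_target = (2 / pi) * ifelse(sc$segments$kind == "cc",
                                   sc$segments$cc_amplitude,
                                   sc$segments$residual_amplitude)
  )

  case <- new_cc_case(
    accel = accel, ecg_pads = ecg, capno = capno, physio = physio,
    ann_periods = truth_periods, defib_events = NULL, path = NULL
  )
  list(case = case, truth = list(periods = truth_periods,
                                 env_targets = env_targets))
}

# exact compression periods of a scenario's schedule (adjacent cc segments
# merge into one period); boundaries are the ramp midpoints
schedule_periods <- function(sc) {
  bounds <- sc$t0 + c(0, cumsum(sc$segments$duration_s))
  is_cc <- sc$segments$kind == "cc"
  if (!any(is_cc)) return(as_segmentation())
  r <- rle(is_cc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  as_segmentation(tibble(
    start_s = bounds[starts[keep]],
    stop_s = bounds[ends[keep] + 1L]
  ))
}

# centered Hann-weighted smoothing of a stepwise profile; replicate-padded
# at the edges so a record that starts mid-compression stays at full
# amplitude from the first sample
smooth_profile <- function(x, m) {
  if (m < 3L) return(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1L)) / (m - 1L))
  w <- w / sum(w)
  h <- (m - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  y <- stats::filter(xp, w, sides = 2)
  as.numeric(y[(h + 1L):(h + length(x))])
}

#' @export
print.cc_scenario <- function(x, ...) {
  cat(sprintf("<cc_scenario> %d segments, %.1f s total, fs %g Hz, seed %d\n",
              nrow(x$segments), sum(x$segments$duration_s), x$fs, x$seed))
  cat(sprintf("  noise sigma %g, gravity %g, drift %g @ %g Hz\n",
              x$noise_sigma, x$gravity_offset, x$drift_amplitude,
              x$drift_freq_hz))
  print(x$segments, n = nrow(x$segments))
  invisible(x)
}
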