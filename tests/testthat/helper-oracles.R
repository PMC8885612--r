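# Independent oracles and small builders used across the suite.

quiet_read_case <- function(dir) suppressWarnings(read_case(dir))

make_trace <- function(v, fs = 250, t0 = 0) {
  tibble::tibble(t = t0 + (seq_along(v) - 1) / fs, v = v)
}

sine_trace <- function(dur_s, freq = 2, fs = 250, amp = 1, t0 = 0) {
  t <- t0 + seq(0, dur_s, by = 1 / fs)
  tibble::tibble(t = t, v = amp * sin(2 * pi * freq * (t - t0)))
}

# two compression blocks around one gap, built through the package's own
# generator (2 Hz carrier so envelope levels are analytic)
gap_scenario <- function(gap_s, residual = 0, noise = 0.02, seed = 1L,
                         cc_s = 20) {
  scenario(
    dplyr::bind_rows(
      seg_cc(cc_s, rate_hz = 2),
      seg_pause(gap_s, residual_amplitude = residual, rate_hz = 2),
      seg_cc(cc_s, rate_hz = 2)
    ),
    noise_sigma = noise, seed = seed
  )
}

# Oracle for the alternating-extrema search: an explicit stateful scan,
# independent of the vectorized implementation. Walks the non-zero
# samples; a sign change commits the running extremum, a same-sign sample
# replaces it only when strictly larger (earliest tie wins).
oracle_alternating <- function(deriv) {
  d <- deriv$d
  idx <- integer()
  cur <- NA_integer_
  cur_sign <- 0
  for (i in seq_along(d)) {
    if (d[i] == 0) next
    s <- sign(d[i])
    if (s != cur_sign) {
      if (!is.na(cur)) idx <- c(idx, cur)
      cur <- i
      cur_sign <- s
    } else if (abs(d[i]) > abs(d[cur])) {
      cur <- i
    }
  }
  if (!is.na(cur)) idx <- c(idx, cur)
  tibble::tibble(
    time = deriv$t[idx],
    kind = ifelse(d[idx] > 0, "start", "stop"),
    strength = abs(d[idx]),
    idx = idx
  )
}

# Direct check of the defining properties of an alternating candidate
# list: kinds alternate; every candidate is the earliest absolutely
# largest sample of its sign strictly between its neighbours of the other
# kind (record ends otherwise); no non-zero sample of the "wrong" sign
# lies before the first or after the last candidate.
check_alternating_properties <- function(deriv, cand) {
  d <- deriv$d
  if (nrow(cand) == 0) return(all(d == 0))
  s <- ifelse(cand$kind == "start", 1, -1)
  if (any(s[-1] == s[-length(s)])) return(FALSE)
  m <- nrow(cand)
  lo <- c(0L, cand$idx[-m])
  hi <- c(cand$idx[-1L], length(d) + 1L)
  for (k in seq_len(m)) {
    ii <- seq.int(lo[k] + 1L, hi[k] - 1L)
    same <- ii[sign(d[ii]) == s[k]]
    if (length(same) == 0) return(FALSE)
    best <- same[which.max(abs(d[same]))]
    if (best != cand$idx[k]) return(FALSE)
  }
  before <- seq_len(cand$idx[1L] - 1L)
  if (any(sign(d[before]) == -s[1L])) return(FALSE)
  after <- seq.int(cand$idx[m] + 1L, length(d) + 1L)[-1L] - 1L
  if (length(after) > 0 && any(sign(d[after]) == -s[m])) return(FALSE)
  TRUE
}

# random soft-shrunk-like derivative series: sparse lobes with zeros
random_deriv <- function(n, fs = 50) {
  d <- numeric(n)
  k <- sample(0:6, 1)
  if (k > 0) {
    centers <- sample(seq_len(n), k)
    for (c0 in centers) {
      w <- sample(1:5, 1)
      a <- stats::runif(1, 0.1, 3) * sample(c(-1, 1), 1)
      ii <- intersect(seq(c0 - w, c0 + w), seq_len(n))
      d[ii] <- d[ii] + a * (1 - abs(ii - c0) / (w + 1))
    }
  }
  tibble::tibble(t = (seq_len(n) - 1) / fs, d = d)
}

# fraction of ground-truth boundaries matched within tol by detection
boundary_recovery <- function(det, truth, tol = 0.5) {
  alg <- tidy(det)[, c("start_s", "stop_s")]
  ag <- compare_segmentations(alg, truth, tolerance_s = tol)
  nrow(ag$matched) / (2 * nrow(truth))
}
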