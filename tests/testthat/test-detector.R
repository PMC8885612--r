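cfg <- detector_config()

test_that("alternating extrema agree with the stateful-scan oracle and its
           defining properties on random derivative series", {
  expect_equal(
    nrow(alternating_extrema(tibble::tibble(t = 1:100 / 50, d = rep(0, 100)))),
    0L
  )

  # one positive then one negative lobe -> start at argmax, stop at argmin
  t <- seq(0, 4, by = 0.02)
  d <- dnorm(t, 1, 0.15) - dnorm(t, 3, 0.15)
  d[abs(d) < 0.2] <- 0
  cand <- alternating_extrema(tibble::tibble(t = t, d = d))
  expect_equal(cand$kind, c("start", "stop"))
  expect_equal(cand$time, c(1, 3), tolerance = 0.03)

  # two positive lobes (1 and 3) then one negative: start sits on the
  # taller lobe
  d2 <- dnorm(t, 0.7, 0.1) / dnorm(0, 0, 0.1) +
    3 * dnorm(t, 1.8, 0.1) / dnorm(0, 0, 0.1) -
    2 * dnorm(t, 3.2, 0.1) / dnorm(0, 0, 0.1)
  d2[abs(d2) < 0.05] <- 0
  cand2 <- alternating_extrema(tibble::tibble(t = t, d = d2))
  expect_equal(cand2$kind, c("start", "stop"))
  expect_equal(cand2$time[1], 1.8, tolerance = 0.03)

  set.seed(314)
  for (i in 1:200) {
    dv <- random_deriv(sample(20:200, 1))
    got <- alternating_extrema(dv)
    expect_identical(got$idx, oracle_alternating(dv)$idx)
    expect_true(check_alternating_properties(dv, got))
  }
})

test_that("candidate filtering enforces the three acceptance rules", {
  # two strong periods separated by a 1.0 s silent gap: merged, logged as
  # rejected_short
  sim <- generate_case(gap_scenario(1.0, seed = 21L))
  det <- detect_compressions(sim$case)
  expect_equal(nrow(det$segmentation), 1L)
  expect_true("rejected_short" %in% det$gaps$verdict)
  expect_false("accepted" %in%
                 det$gaps$verdict[det$gaps$iteration == max(det$gaps$iteration)])

  # 3 s gap with residual motion at 50 % of the flank envelope: merged,
  # logged as rejected_ratio
  sim2 <- generate_case(gap_scenario(3, residual = 0.5, seed = 22L))
  det2 <- detect_compressions(sim2$case)
  expect_equal(nrow(det2$segmentation), 1L)
  expect_true("rejected_ratio" %in% det2$gaps$verdict)

  # the same 3 s gap, silent: accepted, two periods
  sim3 <- generate_case(gap_scenario(3, seed = 23L))
  det3 <- detect_compressions(sim3$case)
  expect_equal(nrow(det3$segmentation), 2L)
  final <- det3$gaps[det3$gaps$iteration == max(det3$gaps$iteration), ]
  expect_equal(final$verdict, "accepted")
  expect_gte(final$duration_s, cfg$min_pause_s)
  expect_lt(
    final$pause_env_mean,
    cfg$pause_ratio * (final$flank_env_mean_pre + final$flank_env_mean_post) / 2
  )

  # a low-amplitude "period" below the compression floor between two real
  # pauses is absorbed
  sc <- scenario(
    dplyr::bind_rows(
      seg_cc(15, rate_hz = 2), seg_pause(4),
      seg_cc(6, rate_hz = 2, amplitude = 0.05), seg_pause(4),
      seg_cc(15, rate_hz = 2)
    ),
    noise_sigma = 0.01, seed = 24L
  )
  det4 <- detect_compressions(generate_case(sc)$case)
  expect_equal(nrow(det4$segmentation), 2L)
  expect_false(any(det4$segmentation$start_s > 18 &
                     det4$segmentation$stop_s < 26))
})

test_that("marker refinement uses the |d|-weighted mean when two similar
           maxima are close", {
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)
  lobe <- function(c0, a, w = 0.05) a * pmax(1 - abs(t - c0) / w, 0)

  # isolated single maximum: unchanged
  d1 <- tibble::tibble(t = t, d = lobe(2, 1))
  expect_equal(refine_marker(2, d1, cfg), 2)

  # two equal maxima at t0 +/- 0.2 with |d| symmetric about t0: the
  # refined marker is the midpoint, whichever maximum is the anchor
  d2 <- tibble::tibble(t = t, d = lobe(1.8, 1) + lobe(2.2, 1))
  expect_equal(refine_marker(1.8, d2, cfg), 2, tolerance = 1e-6)
  expect_equal(refine_marker(2.2, d2, cfg), 2, tolerance = 1e-6)

  # two unequal maxima: the direct-summation centroid over the window
  d3 <- tibble::tibble(t = t, d = lobe(1.9, 1) + lobe(2.3, 0.7))
  sel <- t >= 1.9 - 0.5 & t <= 1.9 + 0.5
  centroid <- sum(t[sel] * abs(d3$d[sel])) / sum(abs(d3$d[sel]))
  expect_equal(refine_marker(1.9, d3, cfg), centroid)

  # a secondary maximum below similar_max_ratio does not trigger refinement
  d4 <- tibble::tibble(t = t, d = lobe(1.9, 1) + lobe(2.3, 0.3))
  expect_equal(refine_marker(1.9, d4, cfg), 1.9)
})

test_that("degenerate inputs are handled: zero records, no pauses, truncated
           records, too-short records", {
  # all-zero 60 s trace -> empty segmentation
  z <- make_trace(rep(0, 15000))
  expect_equal(nrow(detect_compressions(z, cfg)$segmentation), 0L)

  # uninterrupted sinusoid -> one period covering >= 95 % of the record
  tr <- sine_trace(60, freq = 2)
  det <- detect_compressions(tr, cfg)
  expect_equal(nrow(det$segmentation), 1L)
  expect_gte(
    det$segmentation$stop_s - det$segmentation$start_s, 0.95 * 60
  )

  # record starting and ending mid-compression pins boundaries to the edges
  sim <- generate_case(preset_scenario("edge_truncated"))
  det2 <- detect_compressions(sim$case)
  seg <- det2$segmentation
  expect_equal(seg$start_s[1], sim$case$accel$t[1])
  expect_equal(seg$stop_s[nrow(seg)], max(sim$case$accel$t), tolerance = 0.05)

  expect_error(detect_compressions(make_trace(rnorm(300)), cfg),
               "record too short")
})

test_that("detection recovers the generator's schedule on the preset
           scenarios", {
  sim <- generate_case(gap_scenario(5, seed = 31L))
  det <- detect_compressions(sim$case)
  expect_equal(nrow(det$segmentation), 2L)
  expect_equal(boundary_recovery(det, sim$truth$periods), 1)

  for (name in c("clean", "noisy", "short_pauses")) {
    sim <- generate_case(preset_scenario(name))
    det <- detect_compressions(sim$case)
    alg <- tidy(det)[, c("start_s", "stop_s")]
    # every accepted pause satisfies both pause rules, straight from the log
    final <- det$gaps[det$gaps$iteration == max(det$gaps$iteration) &
                        det$gaps$verdict == "accepted", ]
    expect_true(all(final$duration_s >= cfg$min_pause_s))
    expect_true(all(
      final$pause_env_mean <
        cfg$pause_ratio * (final$flank_env_mean_pre + final$flank_env_mean_post) / 2
    ))
    # detected periods are disjoint and inside the record
    validate_segmentation(alg)
    expect_gte(min(alg$start_s), min(sim$case$accel$t))
    expect_lte(max(alg$stop_s), max(sim$case$accel$t))
  }
})

test_that("the segmentation is equivariant under amplitude scaling and time
           shifts", {
  sim <- generate_case(preset_scenario("clean"))
  base <- tidy(detect_compressions(sim$case))

  # amplitude: adaptive thresholds make the result scale-free
  for (c0 in c(0.1, 10)) {
    scaled <- sim$case$accel
    scaled$v <- scaled$v * c0
    segc <- tidy(detect_compressions(scaled, cfg))
    expect_equal(segc$start_s, base$start_s, tolerance = 1 / 250)
    expect_equal(segc$stop_s, base$stop_s, tolerance = 1 / 250)
  }

  # time: shifting the time base shifts every marker by the same amount
  shifted <- sim$case$accel
  shifted$t <- shifted$t + 1234.5
  segs <- tidy(detect_compressions(shifted, cfg))
  expect_equal(segs$start_s, base$start_s + 1234.5, tolerance = 1e-6)
  expect_equal(segs$stop_s, base$stop_s + 1234.5, tolerance = 1e-6)
})

test_that("lowering the pause-duration floor never removes reported pauses", {
  sim <- generate_case(preset_scenario("short_pauses"))
  floors <- c(2.5, 1.6, 0.8, 0.4)
  n_pauses <- sapply(floors, function(mp) {
    det <- detect_compressions(sim$case, detector_config(min_pause_s = mp))
    nrow(tidy(det)) - 1L
  })
  expect_true(all(diff(n_pauses) >= 0))
})
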