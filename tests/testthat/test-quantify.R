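test_that("latency reference frames convert exactly through 198 ms", {
  expect_equal(to_change_ref(300), 102)   # earliest MMN bound post-change
  expect_equal(to_change_ref(650), 452)   # LDN upper bound post-change
  expect_equal(to_change_ref(250), 52)    # pMMR lower bound post-change
  expect_equal(to_onset_ref(to_change_ref(437)), 437)
})

test_that("MMN detector finds the largest negative deflection in 300-450 ms", {
  t <- default_grid()
  dw <- make_diff_wave(gaussian_on(t, -3, 370, 80))
  m <- detect_mmn(dw)
  expect_lt(abs(m$peak_latency_ms - 370), 1000 / 256 + 1e-9)  # within 1 sample
  expect_equal(m$change_latency_ms, m$peak_latency_ms - 198)
  expect_equal(m$source, "ROI")
  expect_equal(m$flags, "")

  # all-positive waveform: window minimum with a flag
  pos <- make_diff_wave(gaussian_on(t, 3, 370, 80) + 1)
  mpos <- detect_mmn(pos)
  expect_match(mpos$flags, "window_edge")
  # two negative peaks: the deeper wins
  two <- make_diff_wave(gaussian_on(t, -2, 330, 40) +
                          gaussian_on(t, -4, 420, 40))
  expect_lt(abs(detect_mmn(two)$peak_latency_ms - 420), 4)
})

test_that("pMMR precedes the MMN, with lower-bound and electrode fallbacks", {
  t <- default_grid()
  dw <- make_diff_wave(gaussian_on(t, 2, 270, 50) +
                         gaussian_on(t, -3, 370, 60))
  mmn <- detect_mmn(dw)
  p <- detect_pmmr(dw, mmn = mmn)
  expect_lt(abs(p$peak_latency_ms - 270), 1000 / 256 + 1e-9)
  expect_lt(p$peak_latency_ms, mmn$peak_latency_ms)

  # monotone negative ramp: no positive peak anywhere -> 250 ms, flagged
  ramp <- make_diff_wave(-seq_along(t) / length(t))
  mmn_r <- detect_mmn(ramp)
  p_r <- detect_pmmr(ramp, mmn = mmn_r)
  expect_equal(p_r$peak_latency_ms, 250)
  expect_match(p_r$flags, "lower_bound_latency")
  expect_equal(p_r$change_latency_ms, 52)

  # positive peak only on one electrode -> fallback electrode reported
  dw_fb <- make_diff_wave(gaussian_on(t, -3, 370, 60))
  dw_fb$channels["F3", ] <- dw_fb$channels["F3", ] +
    gaussian_on(t, 2, 280, 40)
  p_fb <- detect_pmmr(dw_fb, mmn = detect_mmn(dw_fb))
  expect_equal(p_fb$source, "F3")
  expect_match(p_fb$flags, "fallback_electrode")

  # an MMN at the lower bound leaves no room for the pMMR
  mmn_at_250 <- detect_mmn(dw)
  mmn_at_250$peak_latency_ms <- 250
  expect_error(detect_pmmr(dw, mmn = mmn_at_250), "empty")
})

test_that("P3a follows the MMN; LDN follows the P3a (or MMN when absent)", {
  t <- default_grid()
  dw <- make_diff_wave(gaussian_on(t, -3, 370, 60) +
                         gaussian_on(t, 2.5, 460, 60) +
                         gaussian_on(t, -2, 560, 80))
  mmn <- detect_mmn(dw)
  p3a <- detect_p3a(dw, mmn = mmn)
  expect_lt(abs(p3a$peak_latency_ms - 460), 1000 / 256 + 1e-9)
  expect_gt(p3a$peak_latency_ms, mmn$peak_latency_ms)

  ldn <- detect_ldn(dw, mmn = mmn, p3a = p3a)
  expect_lt(abs(ldn$peak_latency_ms - 560), 1000 / 256 + 1e-9)
  expect_gt(ldn$peak_latency_ms, p3a$peak_latency_ms)

  # without an observable P3a, the LDN window starts at the MMN peak
  dw2 <- make_diff_wave(gaussian_on(t, -3, 370, 60) +
                          gaussian_on(t, -2, 500, 80))
  mmn2 <- detect_mmn(dw2)
  ldn2 <- detect_ldn(dw2, mmn = mmn2, p3a = NULL)
  expect_lt(abs(ldn2$peak_latency_ms - 500), 6)

  # all-negative P3a window: maximum with a flag
  p3a_neg <- detect_p3a(dw2, mmn = mmn2)
  expect_match(p3a_neg$flags, "window_edge|fallback")
})

test_that("mean amplitude is the windowed mean, matching a direct oracle", {
  t <- default_grid()
  const <- make_diff_wave(rep(3.3, length(t)))
  expect_equal(as.numeric(mean_amplitude(const, 400)), 3.3)

  # symmetric triangle of half-width 25 ms peaking at v: window mean = v / 2
  tri <- make_diff_wave(pmax(0, 1 - abs(t - 400) / 25) * 4)
  expect_equal(as.numeric(mean_amplitude(tri, 400)), 2, tolerance = 0.05)

  set.seed(9)
  rnd <- make_diff_wave(rnorm(length(t)))
  for (peak in c(300, 425, 600)) {
    idx <- which(t >= peak - 25 & t <= peak + 25)
    expect_equal(as.numeric(mean_amplitude(rnd, peak)),
                 mean(rnd$roi[idx]))
  }
  # truncation at the epoch edge is flagged
  expect_true(attr(mean_amplitude(rnd, max(t) - 10), "truncated"))
})

test_that("windowed mean attenuates a Gaussian peak by the analytic factor", {
  t <- default_grid()
  for (fwhm in c(80, 120)) {
    g <- make_diff_wave(gaussian_on(t, 5, 400, fwhm))
    got <- as.numeric(mean_amplitude(g, 400)) / 5
    expect_equal(got, window_attenuation(fwhm), tolerance = 0.01)
  }
  # the default 80 ms width loses less than 10% of the peak
  expect_gt(window_attenuation(80), 0.9)
})

test_that("detect_all recovers noiseless injected components in order", {
  t <- default_grid()
  amps <- c(pMMR = 2, MMN = -4, P3a = 3, LDN = -3)
  lats <- c(pMMR = 266, MMN = 371, P3a = 453, LDN = 547)
  fwhm <- c(pMMR = 80, MMN = 80, P3a = 80, LDN = 120)
  sig <- numeric(length(t))
  for (cp in names(amps)) sig <- sig + gaussian_on(t, amps[cp], lats[cp],
                                                   fwhm[cp])
  dw <- make_diff_wave(sig)
  det <- detect_all(dw)
  expect_equal(det$component, c("pMMR", "MMN", "P3a", "LDN"))
  # latency within one sample
  expect_true(all(abs(det$peak_latency_ms - lats[det$component]) <=
                    1000 / 256 + 1e-9))
  # amplitudes equal the direct windowed mean of the injected sum (oracle)
  for (i in seq_len(nrow(det))) {
    idx <- which(t >= det$peak_latency_ms[i] - 25 &
                   t <= det$peak_latency_ms[i] + 25)
    expect_equal(det$amplitude_uv[i], mean(sig[idx]))
  }
  # an isolated component is attenuated by no more than the analytic factor
  iso <- make_diff_wave(gaussian_on(t, -4, 371, 80))
  det_iso <- detect_all(iso)
  expect_equal(det_iso$amplitude_uv[det_iso$component == "MMN"] / -4,
               window_attenuation(80), tolerance = 0.01)
  # temporal ordering and the exact reference-frame relation
  expect_true(all(diff(det$peak_latency_ms) > 0))
  expect_equal(det$change_latency_ms, det$peak_latency_ms - 198)
})

test_that("group-latency mode measures amplitudes at the supplied peaks", {
  t <- default_grid()
  dw <- make_diff_wave(gaussian_on(t, -4, 371, 80))
  group_lat <- c(pMMR = 266, MMN = 371, P3a = 453, LDN = 547)
  det <- detect_all(dw, group_latencies = group_lat)
  expect_equal(det$peak_latency_ms, unname(group_lat[det$component]))
  expect_true(all(det$source == "group"))
  # ordering of the published cell replicated: 266 < 371 < 453 < 547
  expect_true(all(diff(det$peak_latency_ms[match(c("pMMR", "MMN", "P3a",
                                                   "LDN"),
                                                 det$component)]) > 0))
  # the MMN amplitude is the windowed mean at 371
  expect_equal(det$amplitude_uv[det$component == "MMN"],
               as.numeric(mean_amplitude(dw, 371)))

  # zero waveform: pMMR pinned to the lower bound, all amplitudes zero
  zero <- make_diff_wave(rep(0, length(t)))
  dz <- detect_all(zero)
  expect_equal(dz$amplitude_uv, rep(0, 4))
  expect_equal(dz$peak_latency_ms[dz$component == "pMMR"], 250)
  expect_true(all(nzchar(dz$flags)))
})

test_that("detector ordering holds on noisy synthetic difference waves", {
  lats <- c(pMMR = 266, MMN = 371, P3a = 453, LDN = 547)
  amps <- c(pMMR = 2.5, MMN = -4, P3a = 3, LDN = -3)
  for (seed in 1:100) {
    dw <- synthetic_difference_wave(amps, lats, seed = seed)
    det <- detect_all(dw)
    ord <- det$peak_latency_ms[match(c("pMMR", "MMN", "P3a", "LDN"),
                                     det$component)]
    expect_true(ord[1] < ord[2] && ord[2] < ord[3] && ord[3] < ord[4])
    expect_equal(det$change_latency_ms, det$peak_latency_ms - 198)
  }
})

test_that("latency recovery at default SNR stays within two samples", {
  lats <- c(pMMR = 266, MMN = 371, P3a = 453, LDN = 547)
  amps <- c(pMMR = 2.5, MMN = -4, P3a = 3, LDN = -3)
  errs <- list(pMMR = c(), MMN = c(), P3a = c(), LDN = c())
  for (seed in 1:60) {
    dw <- synthetic_difference_wave(amps, lats, seed = 300 + seed)
    det <- detect_all(dw)
    for (cp in names(lats)) {
      errs[[cp]] <- c(errs[[cp]],
                      abs(det$peak_latency_ms[det$component == cp] -
                            lats[cp]))
    }
  }
  for (cp in names(errs)) {
    expect_lte(stats::median(errs[[cp]]), 2 * 1000 / 256)
  }
})
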