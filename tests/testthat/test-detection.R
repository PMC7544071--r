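test_that("presets carry the published detection parameters", {
  eeg <- detection_preset("eeg")
  expect_equal(eeg$band, c(4, 20))
  expect_equal(eeg$min_peak_sep, 60L)
  expect_equal(eeg$s, 0.6)
  mec <- detection_preset("mec")
  expect_equal(mec$band, c(15, 35))
  expect_equal(mec$min_peak_sep, 22000L)
  expect_equal(mec$s, 1)
  expect_error(detection_params(c(20, 4), 60, 0.6))
})

test_that("preprocessing filters, z-normalises and rectifies", {
  fs <- 256
  t <- seq(0, 10, by = 1 / fs)
  x <- 3.7 * sin(2 * pi * 10 * t)          # in-band, arbitrary amplitude
  p <- preprocess_channel(x, fs, c(4, 20))
  expect_true(all(p >= 0))
  # a z-normalised sine has sd 1 and peak sqrt(2)
  core <- p[seq(fs, length(p) - fs)]       # away from filter edges
  expect_equal(max(core), sqrt(2), tolerance = 0.05)
  expect_equal(mean(core^2), 1, tolerance = 0.05)

  expect_error(preprocess_channel(rep(1, 4000), fs, c(4, 20)), "variance")
  expect_error(preprocess_channel(x, fs, c(4, 200)), "Nyquist|inside")
})

test_that("spline envelope tracks separated peaks and falls back safely", {
  fs <- 256
  t <- seq(0, 6, by = 1 / fs)
  x <- abs(sin(2 * pi * 8 * t))
  u <- spline_envelope(x, min_peak_sep = 10)   # < fs/(2*8) = 16 samples
  mid <- seq(fs, length(u) - fs)
  expect_lt(max(abs(u[mid] - 1)), 0.05)

  # of two conflicting peaks the larger contributes the knot
  y <- rep(0.1, 400)
  y[100] <- 1; y[104] <- 0.6; y[300] <- 0.9
  u2 <- spline_envelope(y, min_peak_sep = 20)
  expect_equal(u2[100], 1)
  expect_gt(u2[104], 0.6)   # interpolated from the retained neighbours

  expect_warning(u3 <- spline_envelope(seq(0, 1, length.out = 200), 5),
                 "constant")
  expect_equal(u3, rep(1, 200))
})

test_that("onset is the first threshold crossing, or absent", {
  x <- rep(0.1, 1000)
  u <- rep(1, 1000)
  expect_true(is.na(detect_channel_onset(x, u, s = 0.6, fs = 100)))
  x[501] <- 2
  expect_equal(detect_channel_onset(x, u, s = 0.6, fs = 100), 5)
  expect_error(detect_channel_onset(x, u[-1], 0.6, 100), "length")
})

test_that("detection is invariant to per-channel amplitude rescaling", {
  ot <- make_onset_times("slow", 6, jitter = 0.05, seed = 31)
  rec <- synthesize_recording(ot$tau, 256, 15, c(4, 20), snr = 8, seed = 32)
  det1 <- detect_recording(rec, detection_preset("eeg"))
  rec2 <- rec
  rec2$samples <- rec$samples * matrix(c(0.01, 1, 7, 100, 0.5, 3),
                                       nrow = 6, ncol = ncol(rec$samples))
  det2 <- detect_recording(rec2, detection_preset("eeg"))
  expect_identical(det1$tau, det2$tau)
})

test_that("a flat channel is reported without poisoning the others", {
  ot <- make_onset_times("fast", 5, jitter = 0.02, seed = 41)
  rec <- synthesize_recording(ot$tau, 256, 15, c(4, 20), snr = 8, seed = 42)
  rec$samples[3, ] <- 0
  det <- detect_recording(rec, detection_preset("eeg"))
  expect_false(det$all_detected)
  expect_true(is.na(det$tau[3]))
  expect_match(det$messages[3], "variance")
  expect_true(all(!is.na(det$tau[-3])))
})

test_that("onsets are recovered accurately on synthetic epochs", {
  errs <- c()
  orders_ok <- 0
  classes <- c("fast", "slow", "multi")
  n_ep <- 12
  for (k in seq_len(n_ep)) {
    ot <- make_onset_times(classes[1 + k %% 3], 19, jitter = 0.05,
                           seed = 500 + k)
    rec <- synthesize_recording(ot$tau, 256, 15, c(4, 20), snr = 8,
                                seed = 900 + k)
    det <- detect_recording(rec, detection_preset("eeg"))
    expect_true(det$all_detected)
    errs <- c(errs, abs(det$tau - ot$tau))
    # well-separated onsets keep their ordering
    slow_sep <- diff(sort(ot$tau)) > 0.15
    if (all(order(det$tau)[c(TRUE, slow_sep)] ==
            order(ot$tau)[c(TRUE, slow_sep)]))
      orders_ok <- orders_ok + 1
  }
  expect_lt(mean(errs), 0.25)
})

test_that("shifting the oscillation shifts the detected onset", {
  base <- 4.5
  for (delta in c(0, 0.5, 1.5)) {
    rec <- synthesize_recording(rep(base + delta, 3), 256, 15, c(4, 20),
                                snr = 8, seed = 77)
    det <- detect_recording(rec, detection_preset("eeg"))
    expect_lt(max(abs(det$tau - (base + delta))), 0.25)
  }
})

test_that("group assignment is robust over the s threshold range", {
  ot <- make_onset_times("multi", 19, jitter = 0.05, seed = 61)
  rec <- synthesize_recording(ot$tau, 256, 15, c(4, 20), snr = 8, seed = 62)
  cls <- sapply(c(0.4, 0.6, 0.8), function(s_val) {
    det <- detect_recording(rec, detection_params(c(4, 20), 60, s_val))
    expect_true(det$all_detected)
    pat <- recruitment_pattern(det)
    classify_domino(pat$r, pat$l)
  })
  expect_true(all(cls == "multi"))
})

test_that("the mEC preset detects the slow cascade in every channel", {
  evs <- mec_events()
  tbar <- rep(0, 16)
  for (rec in evs) {
    det <- detect_recording(rec, detection_preset("mec"))
    expect_true(det$all_detected)
    tbar <- tbar + (det$tau - min(det$tau)) / length(evs)
  }
  # mean recruitment advances from ventral to dorsal
  expect_gt(cor(tbar, 1:16, method = "spearman"), 0.95)
  that <- scale_times(tbar)
  expect_equal(max(that), 1)
})
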