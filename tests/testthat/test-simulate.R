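test_that("rms is the root of the grand mean square", {
  expect_equal(rms(matrix(1, 3, 4)), 1)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(matrix(0, 2, 5)), 0)
  expect_error(rms(numeric(0)), "empty")
})

test_that("pure EEG has the stated shape and band placement", {
  cfg <- sim_config(duration = 60, seed = 60)
  x <- generate_pseeg(cfg)
  expect_identical(dim(x), c(19L, 15360L))
  ## per-channel periodogram power concentrates in the 4-30 Hz band
  for (ch in c(1, 7, 19)) {
    p <- welch_psd(x[ch, ], fs = 256, window_s = 2)
    inband <- p$freq >= 3.5 & p$freq <= 30.5
    expect_gt(sum(p$psd[, inband]) / sum(p$psd), 0.95)
  }
  ## segment boundaries every 2 s: frequencies change between segments
  expect_identical(generate_pseeg(cfg), x)      # bitwise determinism
  expect_false(identical(generate_pseeg(sim_config(duration = 60, seed = 61)),
                         x))
})

test_that("the EOG generator is a 0.2 Hz square wave", {
  w <- generate_artifact("EOG", 60, 256, bursts = FALSE)
  runs <- rle(sign(w))
  expect_identical(length(runs$lengths), 24L)   # 12 full periods
  expect_true(all(runs$lengths == 640L))        # 2.5 s half-periods
  expect_equal(rms(w), 1)
})

test_that("the EMG generator concentrates in its 20-60 Hz pass band", {
  w <- generate_artifact("EMG", 30, 256, seed = 62, bursts = FALSE)
  p <- welch_psd(w, fs = 256)
  inband <- p$freq >= 18 & p$freq <= 62
  expect_gt(sum(p$psd[, inband]) / sum(p$psd), 0.9)
})

test_that("the blink generator concentrates between 1 and 3 Hz", {
  w <- generate_artifact("blink", 30, 256, seed = 63, bursts = FALSE)
  p <- welch_psd(w, fs = 256, window_s = 4)
  inband <- p$freq >= 0.5 & p$freq <= 3.5
  expect_gt(sum(p$psd[, inband]) / sum(p$psd), 0.9)
})

test_that("the fitted ECG autoregression is stable", {
  coefs <- eegclean:::ecg_ar_coefficients(256)
  expect_length(coefs, 12L)
  poles <- polyroot(c(rev(-coefs), 1))
  expect_true(all(Mod(poles) < 1))
  w <- generate_artifact("ECG", 10, 256, seed = 64)
  expect_true(all(is.finite(w)))
  expect_error(generate_artifact("hum", 10, 256), "arg")
})

test_that("burst gating keeps one burst of 0.5-2 s per 2-s window", {
  w <- generate_artifact("white_noise", 20, 256, seed = 65)
  act <- matrix(w != 0, nrow = 512)   # columns are 2-s windows
  frac <- colMeans(act)
  expect_true(all(frac >= 0.24 & frac <= 1))
  ## each window's activity is one contiguous run
  runs_per_window <- apply(act, 2, function(a) sum(rle(a)$values))
  expect_true(all(runs_per_window == 1))
})

test_that("random projections load at least ten channels", {
  set.seed(66)
  for (i in 1:20) {
    w <- rnorm(100)
    p <- random_projection(w, 19, seed = i)
    g <- attr(p, "gain")
    expect_gte(sum(g != 0), 10)
    expect_equal(unclass(p), tcrossprod(g, w), ignore_attr = TRUE)
  }
  z <- random_projection(numeric(50), 19, seed = 1)
  expect_true(all(z == 0))
  expect_identical(attr(random_projection(rnorm(10), 19, seed = 3), "gain"),
                   attr(random_projection(rnorm(10), 19, seed = 3), "gain"))
  expect_error(random_projection(rnorm(10), 5), "min_nonzero")
})

test_that("SNR mixing solves exactly for the artifact intensity", {
  pure <- matrix(2, 3, 100)        # RMS 2
  art <- matrix(4, 3, 100)         # RMS 4
  m <- mix_at_snr(pure, art, 1)
  expect_equal(m$lambda, 0.5)
  ## the requested SNR is achieved to 1e-9
  set.seed(67)
  p2 <- matrix(rnorm(500), 5); a2 <- matrix(rnorm(500, sd = 3), 5)
  for (snr in c(0.5, 1, 1.5, 2)) {
    mm <- mix_at_snr(p2, a2, snr)
    expect_lt(abs(rms(p2) / rms(mm$lambda * a2) - snr), 1e-9)
    expect_identical(mm$contaminated, p2 + mm$lambda * a2)
  }
  ## snr -> Inf: lambda -> 0 and the mixture approaches the pure EEG
  big <- mix_at_snr(p2, a2, 1e9)
  expect_lt(big$lambda, 1e-8)
  expect_lt(rms(big$contaminated - p2) / rms(p2), 1e-8)
  expect_error(mix_at_snr(p2, matrix(0, 5, 100), 1), "zero")
})

test_that("scenes satisfy the exact mixing identity and are reproducible", {
  sc <- build_scene(sim_config(duration = 4, seed = 68, snr = 1.3))
  expect_identical(sc$contaminated,
                   sc$pure + sc$lambda * sc$artifact_panel)
  expect_lt(abs(rms(sc$pure) / rms(sc$lambda * sc$artifact_panel) - 1.3),
            1e-9)
  sc2 <- build_scene(sim_config(duration = 4, seed = 68, snr = 1.3))
  expect_identical(sc$contaminated, sc2$contaminated)
  expect_error(build_scene(sim_config(duration = 4,
                                      artifact_kinds = character(0))))
})

test_that("seeded scenes are pairwise distinct", {
  prints <- vapply(1:200, function(i)
    fingerprint(build_scene(sim_config(duration = 2, seed = i))$contaminated),
    character(1))
  expect_identical(anyDuplicated(prints), 0L)
})

test_that("artifact injection into a supplied recording mirrors scene building", {
  cfg <- sim_config(duration = 4, seed = 69)
  sc <- build_scene(cfg)
  rec <- eeg_recording(sc$pure, cfg$fs)
  sc2 <- inject_into_recording(rec, cfg)
  expect_identical(sc2$contaminated, sc$contaminated)
  bad <- eeg_recording(sc$pure[1:5, ], cfg$fs)
  expect_error(inject_into_recording(bad, cfg), "channels")
  short <- eeg_recording(sc$pure[, 1:100], cfg$fs)
  expect_error(inject_into_recording(short, cfg), "duration")
})
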