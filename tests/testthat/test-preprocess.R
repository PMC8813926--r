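trimmed <- function(x, n = 1000) x[n:(length(x) - n)]

test_that("high-pass removes DC, preserves the passband, guards Nyquist", {
  t <- seq_len(20 * 500) / 500
  rec <- recording(matrix(5 + sin(2 * pi * 10 * t), nrow = 1), 500)
  out <- highpass(rec)
  core <- trimmed(out$data[1, ])
  expect_lt(abs(mean(core)), 1e-3 * 5)
  amp <- (max(core) - min(core)) / 2
  expect_equal(amp, 1, tolerance = 0.05)
  expect_error(highpass(rec, 300), class = "megpac_error_config")
})

test_that("band-stop notches 60 Hz and leaves neighbors untouched", {
  t <- seq_len(30 * 500) / 500
  mk <- function(f) recording(matrix(sin(2 * pi * f * t), nrow = 1), 500)
  r60 <- bandstop(mk(60))
  expect_lt(sqrt(mean(trimmed(r60$data[1, ])^2)), 0.1 * sqrt(0.5))
  for (f in c(50, 70, 80)) {
    rf <- bandstop(mk(f))
    expect_equal(sqrt(mean(trimmed(rf$data[1, ])^2)), sqrt(0.5),
                 tolerance = 0.05)
  }
  expect_error(bandstop(mk(60), width_hz = 0), class = "megpac_error_config")
})

test_that("filters are zero-phase in the passband", {
  t <- seq_len(20 * 500) / 500
  x <- sin(2 * pi * 10 * t)
  rec <- recording(matrix(x, nrow = 1), 500)
  y <- highpass(rec)$data[1, ]
  cc <- ccf(trimmed(x), trimmed(y), lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("resampling scales lengths, segments, and keeps spectral peaks", {
  t <- seq_len(10 * 1000) / 1000
  rec <- recording(matrix(sin(2 * pi * 20 * t), nrow = 1), 1000,
                   clean_segments = matrix(c(1000L, 2000L), 1))
  out <- resample_recording(rec, 500)
  expect_equal(ncol(out$data), 5000L)
  expect_equal(out$fs_hz, 500)
  expect_equal(unname(out$clean_segments), matrix(c(500L, 1000L), 1))

  spec <- Mod(fft(out$data[1, ]))[1:2500]
  peak_hz <- (which.max(spec) - 1) * 500 / 5000
  expect_equal(peak_hz, 20, tolerance = 0.1)

  expect_error(resample_recording(rec, 2000), class = "megpac_error_config")
})

test_that("artifact detection flags injected bursts and not clean noise", {
  rec <- noise_recording(2, duration_s = 60, seed = 11)
  burst <- inject_artifacts(rec, multiplier = 10, n_bursts = 1, width_s = 1,
                            seed = 4)
  mask <- detect_artifact_segments(burst)
  bs <- attr(burst, "burst_segments")
  overlap <- any(mask$flagged[, 1] < bs[1, 2] & mask$flagged[, 2] > bs[1, 1])
  expect_true(overlap)

  # false positives on clean Gaussian noise stay rare (a few seeds)
  fp <- vapply(1:5, function(s) {
    m <- detect_artifact_segments(noise_recording(1, duration_s = 60,
                                                  seed = 100 + s))
    sum(m$flagged[, 2] - m$flagged[, 1]) / (60 * 500)
  }, numeric(1))
  expect_lt(mean(fp), 0.02)

  expect_error(detect_artifact_segments(recording(matrix(1, 1, 1), 500),
                                        window_s = 1e-9),
               class = "megpac_error_config")
})

test_that("detection is idempotent after masking", {
  rec <- noise_recording(1, duration_s = 60, seed = 21)
  burst <- inject_artifacts(rec, multiplier = 10, n_bursts = 2, width_s = 1,
                            seed = 9)
  masked <- apply_segments(burst, detect_artifact_segments(burst))
  # re-running on the clean portion flags (almost) nothing
  keep <- megpac:::segment_indices(masked$clean_segments)
  rec2 <- recording(masked$data[, keep, drop = FALSE], masked$fs_hz)
  m2 <- detect_artifact_segments(rec2)
  frac <- sum(m2$flagged[, 2] - m2$flagged[, 1]) / length(keep)
  expect_lt(frac, 0.02)
})

test_that("a recording with spikes in every window is rejected as unusable", {
  # one 100x spike per 1-s window: every window's peak exceeds 5 clean SDs
  x <- rep(c(rep(0.01, 499), 100), 20)
  rec <- recording(matrix(x, nrow = 1), 500)
  expect_error(detect_artifact_segments(rec, window_s = 1),
               class = "megpac_error_numeric")
  expect_error(detect_artifact_segments(recording(matrix(0, 1, 0), 500)),
               class = "megpac_error_schema")
})

test_that("apply_segments performs the interval complement", {
  rec <- noise_recording(1, fs = 100, duration_s = 10)
  mask <- structure(list(flagged = matrix(c(100L, 200L), 1), k_sd = 5,
                         window_s = 1), class = "segment_mask")
  out <- apply_segments(rec, mask)
  expect_equal(unname(out$clean_segments),
               matrix(c(0L, 100L, 200L, 1000L), 2, byrow = TRUE))
  expect_equal(sum(out$clean_segments[, 2] - out$clean_segments[, 1]), 900L)
  expect_identical(out$data, rec$data)

  empty <- structure(list(flagged = matrix(integer(0), ncol = 2), k_sd = 5,
                          window_s = 1), class = "segment_mask")
  out2 <- apply_segments(rec, empty)
  expect_equal(unname(out2$clean_segments), matrix(c(0L, 1000L), 1))
})

test_that("the preprocessing pipeline runs in fixed order and logs discards", {
  rec <- inject_artifacts(noise_recording(2, fs = 1000, duration_s = 20,
                                          seed = 31),
                          multiplier = 12, n_bursts = 1, width_s = 1,
                          seed = 5)
  out <- preprocess(rec, target_hz = 500)
  expect_equal(out$fs_hz, 500)
  expect_equal(ncol(out$data), 10000L)
  expect_gte(nrow(attr(out, "discarded_segments")), 1L)
  # clean segments exclude the burst (rescaled to 500 Hz)
  bs <- attr(rec, "burst_segments") / 2
  idx <- megpac:::segment_indices(out$clean_segments)
  expect_false(any(idx > bs[1, 1] & idx <= bs[1, 2]))
})
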