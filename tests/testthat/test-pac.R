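# Independent SI oracle: explicit per-sample accumulation loop.
si_oracle <- function(tp, ta) {
  s <- 0 + 0i
  for (i in seq_along(tp)) s <- s + exp(1i * (tp[i] - ta[i]))
  Mod(s / length(tp))
}

test_that("SI equals the explicit-loop oracle on random inputs", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:200, 1)
    tp <- runif(n, -pi, pi)
    ta <- runif(n, -pi, pi)
    expect_equal(synchronization_index(tp, ta), si_oracle(tp, ta),
                 tolerance = 1e-12)
  }
})

test_that("SI has its closed-form values and stays in [0, 1]", {
  th <- runif(50, -pi, pi)
  expect_equal(synchronization_index(th, th), 1)
  expect_equal(synchronization_index(c(0, pi), c(0, 0)), 0, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    s <- synchronization_index(runif(30, -pi, pi), runif(30, -pi, pi))
    expect_gte(s, 0); expect_lte(s, 1)
  }
  expect_error(synchronization_index(numeric(0), numeric(0)),
               class = "megpac_error_numeric")
  expect_error(synchronization_index(1:3, 1:2),
               class = "megpac_error_numeric")
})

test_that("SI is symmetric and invariant to a common phase offset", {
  set.seed(6)
  tp <- runif(100, -pi, pi); ta <- runif(100, -pi, pi)
  expect_equal(synchronization_index(tp, ta),
               synchronization_index(ta, tp), tolerance = 1e-12)
  expect_equal(synchronization_index(tp + 0.7, ta + 0.7),
               synchronization_index(tp, ta), tolerance = 1e-12)
})

test_that("SI of independent uniform phases scales like the Rayleigh null", {
  set.seed(7)
  vals <- vapply(1:100, function(i) {
    synchronization_index(runif(10000, -pi, pi), runif(10000, -pi, pi))
  }, numeric(1))
  expect_gte(mean(vals <= 0.05), 0.95)
})

test_that("low-band phase advances linearly for a tone and is scale/sign aware", {
  fs <- 500
  x <- sin(2 * pi * 19 * seq_len(20 * fs) / fs)
  ph <- low_band_phase(x, fs, beta_band)
  slope <- mean(diff(unwrap_phase(ph)))
  expect_equal(slope, 2 * pi * 19 / fs, tolerance = 0.01 * 2 * pi * 19 / fs)

  expect_equal(low_band_phase(2 * x, fs, beta_band), ph, tolerance = 1e-9)

  ph_neg <- low_band_phase(-x, fs, beta_band)
  d <- (ph_neg - ph + pi) %% (2 * pi) - pi  # wrapped difference
  expect_lt(max(abs(abs(d) - pi)), 1e-6)

  expect_error(low_band_phase(x, fs, band_spec(200, 300)),
               class = "megpac_error_config")
})

test_that("envelope phase tracks a constructed amplitude modulation", {
  fs <- 500
  t <- seq_len(30 * fs) / fs
  x <- (1 + cos(2 * pi * 20 * t)) * sin(2 * pi * 75 * t)
  tha <- envelope_phase(x, fs, band_spec(50, 100), band_spec(16, 24))
  truth <- low_band_phase(cos(2 * pi * 20 * t), fs, band_spec(16, 24))
  circ_cor <- Mod(mean(exp(1i * (tha - truth))))
  expect_gte(circ_cor, 0.95)

  expect_equal(envelope_phase(3 * x, fs, band_spec(50, 100), band_spec(16, 24)),
               tha, tolerance = 1e-6)
})

test_that("phase rotation preserves values and inverts as a rotation", {
  th <- runif(500, -pi, pi)
  sh <- phase_shuffle(th, cut = 123)
  expect_equal(sort(sh), sort(th))
  expect_equal(phase_shuffle(sh, cut = 500 - 123), th)
  expect_error(phase_shuffle(1), class = "megpac_error_numeric")
})

test_that("surrogates separate strong coupling and bound the p-value", {
  rec <- simulate_recording(quick_sim(1, seed = 12, duration_s = 40))
  st <- surrogate_test(rec$data[1, ], 500, beta_band, gamma_band,
                       n_surr = 500, seed = 3)
  expect_equal(st$p, 1 / 501)
  expect_gte(mean(st$surrogate_si < st$si), 0.99)
  expect_gte(st$surrogate_mean, 0)
  expect_lte(st$surrogate_mean, 1)
  expect_error(surrogate_test(rec$data[1, ], 500, beta_band, gamma_band,
                              n_surr = 0), class = "megpac_error_config")
})

test_that("a one-cell comodulogram agrees with the surrogate-test observed SI", {
  rec <- simulate_recording(quick_sim(0.8, seed = 14, duration_s = 20))
  cm <- comodulogram(rec$data[1, ], 500, phase_grid = list(beta_band),
                     amp_grid = list(gamma_band))
  st <- surrogate_test(rec$data[1, ], 500, beta_band, gamma_band,
                       n_surr = 10, seed = 1)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$si, st$si, tolerance = 1e-12)
  expect_error(comodulogram(rec$data[1, ], 500, phase_grid = list()),
               class = "megpac_error_config")
})

test_that("phases pool across clean segments and respect the edge trim", {
  fs <- 500
  x <- rnorm(20 * fs)
  seg <- matrix(c(0L, 5000L, 6000L, 10000L), 2, byrow = TRUE)
  ph <- low_band_phase(x, fs, beta_band, segments = seg, trim_s = 1)
  expect_length(ph, (5000 - 2 * fs) + (4000 - 2 * fs))
  expect_true(all(ph > -pi & ph <= pi))
  # segments shorter than twice the trim are dropped; none left -> error
  seg2 <- matrix(c(0L, 900L), 1)
  expect_error(low_band_phase(x, fs, beta_band, segments = seg2, trim_s = 1),
               class = "megpac_error_numeric")
})

test_that("phase value has closed forms and a small uniform null", {
  expect_equal(phase_value(rep(1.3, 10)), 1)
  expect_equal(phase_value(c(0, pi)), 0, tolerance = 1e-12)
  set.seed(8)
  vals <- vapply(1:40, function(i) phase_value(runif(10000, -pi, pi)),
                 numeric(1))
  expect_gte(mean(vals <= 0.05), 0.95)
  expect_error(phase_value(numeric(0)), class = "megpac_error_numeric")
})

test_that("mean SI rises with injected coupling depth", {
  ks <- c(0, 0.5, 1)
  msi <- vapply(ks, function(k) {
    mean(vapply(1:3, function(s) {
      rec <- simulate_recording(quick_sim(k, seed = 300 + s,
                                          duration_s = 20))
      thp <- low_band_phase(rec$data[1, ], 500, beta_band)
      tha <- envelope_phase(rec$data[1, ], 500, gamma_band, beta_band)
      synchronization_index(thp, tha)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(msi) > 0))
})
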