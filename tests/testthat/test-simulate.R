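test_that("simulation config enforces its invariants", {
  expect_error(sim_config(fs_hz = 150, amp_band = band_spec(50, 100)),
               class = "megpac_error_config")
  expect_error(sim_config(coupling_depth = 1.2),
               class = "megpac_error_config")
  expect_error(sim_config(duration_s = 1.0005, fs_hz = 500.3),
               class = "megpac_error_config")
  expect_error(sim_config(n_parcels = 2, coupled_parcels = 3),
               class = "megpac_error_config")
})

test_that("recording generation is bit-reproducible given the seed", {
  cfg <- quick_sim(0.5, seed = 42, duration_s = 10, n_parcels = 2, coupled = 1L)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(quick_sim(0.5, seed = 43, duration_s = 10,
                                     n_parcels = 2, coupled = 1L))
  expect_false(identical(r1$data, r3$data))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- rnorm(3)
  set.seed(99)
  invisible(simulate_recording(quick_sim(0, seed = 1, duration_s = 5)))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("injected coupling appears only in coupled parcels", {
  cfg <- sim_config(duration_s = 40, n_parcels = 2, coupling_depth = 1,
                    coupled_parcels = 1L, seed = 8)
  rec <- simulate_recording(cfg)
  expect_equal(attr(rec, "coupling_depth"), c(1, 0))
  si <- vapply(1:2, function(p) {
    thp <- low_band_phase(rec$data[p, ], rec$fs_hz, beta_band)
    tha <- envelope_phase(rec$data[p, ], rec$fs_hz, gamma_band, beta_band)
    synchronization_index(thp, tha)
  }, numeric(1))
  expect_gt(si[1], 3 * si[2])
})

test_that("artifact injection returns ground truth and respects guards", {
  rec <- noise_recording(2, duration_s = 30, seed = 5)
  out <- inject_artifacts(rec, multiplier = 10, n_bursts = 3, width_s = 1,
                          seed = 2)
  bs <- attr(out, "burst_segments")
  expect_equal(nrow(bs), 3L)
  expect_true(all(bs[, 2] - bs[, 1] == 500L))

  same <- inject_artifacts(rec, multiplier = 10, n_bursts = 0)
  expect_identical(same$data, rec$data)

  expect_error(inject_artifacts(rec, multiplier = 0.5),
               class = "megpac_error_config")
  expect_error(inject_artifacts(rec, width_s = 31),
               class = "megpac_error_config")
})

test_that("cohort generation links akinesia to coupling depth and sizes the table", {
  sim <- sim_config(duration_s = 4, n_parcels = 2, coupled_parcels = 1L,
                    seed = 1)
  cd <- simulate_cohort(cohort_spec(n_patients = 23, n_controls = 23,
                                    seed = 3), sim)
  expect_equal(nrow(cd$cohort), 46L)
  expect_length(cd$recordings, 46L)
  pat <- cd$cohort[cd$cohort$group == "patient", ]
  ctl <- cd$cohort[cd$cohort$group == "control", ]
  expect_true(all(pat$coupling_depth >= 0 & pat$coupling_depth <= 1))
  expect_true(all(ctl$coupling_depth == 0))
  expect_true(all(is.na(ctl$akinesia_score)))
  expect_true(all(pat$akinesia_score >= 0))
  # the linear score link is recoverable from the ground-truth depths
  expect_gt(cor(pat$coupling_depth, pat$akinesia_score), 0.2)

  expect_error(simulate_cohort(cohort_spec(n_patients = 1),
                               sim), class = "megpac_error_config")
  sim0 <- sim_config(duration_s = 4, n_parcels = 2,
                     coupled_parcels = integer(0))
  expect_error(simulate_cohort(cohort_spec(), sim0),
               class = "megpac_error_config")
})

test_that("derived score noise hits the requested population correlation", {
  # with the default slope/depth settings and target_rho = 0.6, the
  # ground-truth depth-score correlation over a large synthetic population
  # should approach 0.6
  set.seed(7)
  k <- megpac:::rtruncnorm01(20000, 0.5, 0.2)
  spec <- cohort_spec(target_rho = 0.6)
  score <- spec$score_intercept + spec$score_slope * k +
    rnorm(20000, 0, spec$score_noise_sd)
  expect_equal(cor(k, score), 0.6, tolerance = 0.03)
})
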