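#' Simulation configuration
#'
#' Describes one synthetic resting-state recording: a 1/f (pink) noise
#' background on every parcel plus narrowband alpha/beta/gamma rhythms, with
#' phase-amplitude coupling of controlled depth injected into designated
#' parcels. Rhythms are band-limited Gaussian noise, not sinusoids: a pure
#' tone's phase ramp survives rotation surrogates up to an additive constant
#' (to which the synchronization index is invariant), so sinusoidal rhythms
#' would make injected coupling invisible to surrogate testing. Stochastic
#' narrowband rhythms match resting-state data and make rotation surrogates
#' informative.
#'
#' In coupled parcels the amplitude-band carrier `c(t)` is modulated
#' multiplicatively as `c(t) * (1 + k * cos(theta_low(t)))`, where
#' `theta_low` is the instantaneous (Hilbert) phase of the generated
#' phase-band rhythm and `k = coupling_depth`; `k = 0` reduces exactly to the
#' uncoupled construction.
#'
#' @param fs_hz Sampling rate, Hz. Must exceed twice the amplitude-band upper
#'   edge. Default 500.
#' @param duration_s Recording length in seconds (default 240).
#' @param n_parcels Number of parcels (default 8).
#' @param phase_band,amp_band `band_spec` for the modulating rhythm and the
#'   modulated carrier (defaults beta 13-25 Hz and gamma 50-100 Hz).
#' @param coupling_depth Modulation depth `k` in `[0, 1]`.
#' @param coupled_parcels Integer indices of parcels receiving the coupling
#'   (default `1:2`, the "sensorimotor" stand-ins).
#' @param rhythm_amplitudes Named vector `c(alpha=, beta=, gamma=)` of rhythm
#'   RMS amplitudes relative to the unit-SD 1/f background, or an
#'   `n_parcels x 3` matrix with those column names for per-parcel control.
#' @param amplitude_jitter_sd SD of per-parcel log-normal jitter applied to
#'   rhythm amplitudes (default 0.2), emulating anatomic variation; set 0 to
#'   disable.
#' @param noise_exponent Spectral exponent of the 1/f background (power ~
#'   1/f^exponent, default 1).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @param artifact_spec Optional `list(multiplier=, n_bursts=, width_s=)`
#'   passed to [inject_artifacts()] after generation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs_hz = 500, duration_s = 240, n_parcels = 8,
                       phase_band = band_spec(13, 25, "beta"),
                       amp_band = band_spec(50, 100, "gamma"),
                       coupling_depth = 0.5,
                       coupled_parcels = seq_len(min(2L, n_parcels)),
                       rhythm_amplitudes = c(alpha = 1, beta = 1, gamma = 0.5),
                       amplitude_jitter_sd = 0.2,
                       noise_exponent = 1, seed = 1L,
                       artifact_spec = NULL) {
  stopifnot(inherits(phase_band, "band_spec"), inherits(amp_band, "band_spec"))
  if (fs_hz <= 2 * amp_band$high_hz) {
    abort(sprintf("fs_hz = %g too low: need fs_hz > 2 x %g Hz (amplitude-band upper edge)",
                  fs_hz, amp_band$high_hz),
          class = "megpac_error_config")
  }
  if (coupling_depth < 0 || coupling_depth > 1) {
    abort("coupling_depth must lie in [0, 1]", class = "megpac_error_config")
  }
  n <- duration_s * fs_hz
  if (abs(n - round(n)) > 1e-9) {
    abort("duration_s x fs_hz must be an integer sample count",
          class = "megpac_error_config")
  }
  if (length(coupled_parcels) > 0 &&
      (any(coupled_parcels < 1) || any(coupled_parcels > n_parcels))) {
    abort("coupled_parcels out of range", class = "megpac_error_config")
  }
  amps <- rhythm_amplitudes
  if (is.matrix(amps)) {
    stopifnot(nrow(amps) == n_parcels,
              all(c("alpha", "beta", "gamma") %in% colnames(amps)))
  } else {
    stopifnot(all(c("alpha", "beta", "gamma") %in% names(amps)))
    amps <- matrix(rep(amps[c("alpha", "beta", "gamma")], each = n_parcels),
                   nrow = n_parcels,
                   dimnames = list(NULL, c("alpha", "beta", "gamma")))
  }
  structure(list(fs_hz = fs_hz, duration_s = duration_s,
                 n_parcels = as.integer(n_parcels),
                 phase_band = phase_band, amp_band = amp_band,
                 coupling_depth = coupling_depth,
                 coupled_parcels = as.integer(coupled_parcels),
                 rhythm_amplitudes = amps,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 noise_exponent = noise_exponent,
                 seed = as.integer(seed), artifact_spec = artifact_spec),
            class = "sim_config")
}

# 1/f^exponent noise by spectral shaping of white noise; unit SD.
pink_noise <- function(n, exponent = 1) {
  w <- rnorm(n)
  if (exponent == 0) return(w)
  x <- fft(w)
  freq <- c(0, seq_len(n - 1))
  freq <- pmin(freq, n - freq)  # symmetric frequency index
  gain <- c(0, freq[-1]^(-exponent / 2))
  y <- Re(fft(x * gain, inverse = TRUE)) / n
  y / sd(y)
}

# Band-limited unit-RMS Gaussian rhythm and its analytic phase.
narrowband_rhythm <- function(n, fs, band) {
  x <- bandpass_vec(rnorm(n), fs, band$low_hz, band$high_hz)
  x <- x / sd(x)
  list(signal = x, phase = Arg(analytic_signal(x)))
}

#' Simulate one parcel-level recording
#'
#' See [sim_config()] for the generative model. Deterministic given
#' `config$seed`: the same configuration always yields bit-identical data.
#'
#' @param config A [sim_config()].
#' @return A [recording()] with `config$n_parcels` parcels. The ground-truth
#'   per-parcel coupling depth is stored in `attr(rec, "coupling_depth")`.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs_hz
  n <- as.integer(round(config$duration_s * fs))
  with_local_seed(config$seed, {
    amps <- config$rhythm_amplitudes
    if (config$amplitude_jitter_sd > 0) {
      amps <- amps * matrix(exp(rnorm(length(amps), 0, config$amplitude_jitter_sd)),
                            nrow = nrow(amps))
    }
    alpha_band <- band_spec(8, 12, "alpha")
    dat <- matrix(0, nrow = config$n_parcels, ncol = n)
    k_true <- numeric(config$n_parcels)
    for (p in seq_len(config$n_parcels)) {
      bg <- pink_noise(n, config$noise_exponent)
      a_r <- narrowband_rhythm(n, fs, alpha_band)$signal
      b_r <- narrowband_rhythm(n, fs, config$phase_band)
      g_r <- narrowband_rhythm(n, fs, config$amp_band)$signal
      k <- if (p %in% config$coupled_parcels) config$coupling_depth else 0
      k_true[p] <- k
      carrier <- g_r * (1 + k * cos(b_r$phase))
      dat[p, ] <- bg + amps[p, "alpha"] * a_r + amps[p, "beta"] * b_r$signal +
        amps[p, "gamma"] * carrier
    }
    rec <- recording(dat, fs_hz = fs, participant_id = "SIM",
                     group = "patient")
    attr(rec, "coupling_depth") <- k_true
    if (!is.null(config$artifact_spec)) {
      a <- config$artifact_spec
      rec <- inject_artifacts(rec, multiplier = a$multiplier,
                              n_bursts = a$n_bursts, width_s = a$width_s,
                              seed = derive_seeds(config$seed, 1L))
    }
    rec
  })
}

#' Inject high-amplitude artifact bursts
#'
#' Multiplies the signal in every parcel by a smoothly tapered gain reaching
#' `multiplier` inside each of `n_bursts` randomly placed windows, emulating
#' muscle/environmental artifact bursts. `multiplier = 1` leaves the
#' recording unchanged (useful as a negative control for detection).
#'
#' @param rec A [recording()].
#' @param multiplier Peak amplitude gain (>= 1).
#' @param n_bursts Number of bursts.
#' @param width_s Burst width in seconds; must be shorter than the recording.
#' @param seed RNG seed for burst placement.
#' @return The recording with bursts applied; ground-truth burst intervals
#'   (0-based half-open, samples) in `attr(, "burst_segments")`.
#' @export
inject_artifacts <- function(rec, multiplier = 10, n_bursts = 3,
                             width_s = 1, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  if (multiplier < 1) {
    abort("burst multiplier must be >= 1", class = "megpac_error_config")
  }
  n <- n_samples(rec)
  w <- as.integer(round(width_s * rec$fs_hz))
  if (w >= n) {
    abort("burst width must be shorter than the recording",
          class = "megpac_error_config")
  }
  bursts <- matrix(integer(0), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  if (n_bursts > 0) {
    starts <- with_local_seed(seed,
      sort(sample.int(n - w, n_bursts, replace = FALSE)) - 1L)
    gain <- rep(1, n)
    taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = w))  # Hann
    for (s in starts) {
      idx <- (s + 1L):(s + w)
      gain[idx] <- pmax(gain[idx], 1 + (multiplier - 1) * taper)
    }
    rec$data <- sweep(rec$data, 2, gain, `*`)
    bursts <- matrix(c(starts, starts + w), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  }
  attr(rec, "burst_segments") <- bursts
  rec
}

# SD of a normal(mean, sd) truncated to [0, 1].
truncnorm01_sd <- function(mean, sd) {
  a <- (0 - mean) / sd; b <- (1 - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m1 <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  sqrt(v)
}

rtruncnorm01 <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd); hi <- pnorm(1, mean, sd)
  stats::qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

#' Cohort specification
#'
#' Defines a synthetic case-control cohort: patients draw a per-subject
#' coupling depth `k_i` from a normal distribution truncated to `[0, 1]`,
#' controls receive `control_depth` (default 0), and each patient's akinesia
#' score follows the linear model
#' `score_i = score_intercept + score_slope * k_i + eps_i`,
#' `eps_i ~ N(0, score_noise_sd^2)`, rounded to the nearest non-negative
#' integer (MDS-UPDRS sub-scores are integers).
#'
#' If `score_noise_sd` is `NULL` it is derived so that the population
#' correlation between `k` and the (unrounded) score equals `target_rho`:
#' `score_noise_sd = score_slope * sd(k) * sqrt(1 - rho^2) / rho`.
#'
#' @param n_patients,n_controls Group sizes (>= 2 each; defaults 23 and 23).
#' @param depth_mean,depth_sd Mean and SD of the pre-truncation coupling-depth
#'   distribution (defaults 0.5 and 0.2).
#' @param score_intercept,score_slope Linear link from depth to akinesia
#'   score (defaults 10 and 20).
#' @param score_noise_sd Score noise SD, or `NULL` to derive from
#'   `target_rho`.
#' @param target_rho Population depth-score correlation used when
#'   `score_noise_sd` is `NULL` (default 0.6).
#' @param control_depth Coupling depth given to controls (default 0).
#' @param seed Master RNG seed for the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 23, n_controls = 23,
                        depth_mean = 0.5, depth_sd = 0.2,
                        score_intercept = 10, score_slope = 20,
                        score_noise_sd = NULL, target_rho = 0.6,
                        control_depth = 0, seed = 1L) {
  if (n_patients < 2 || n_controls < 2) {
    abort("need at least 2 patients and 2 controls",
          class = "megpac_error_config")
  }
  if (is.null(score_noise_sd)) {
    stopifnot(target_rho > 0, target_rho < 1)
    sdk <- truncnorm01_sd(depth_mean, depth_sd)
    score_noise_sd <- abs(score_slope) * sdk * sqrt(1 - target_rho^2) / target_rho
  }
  if (score_noise_sd < 0) {
    abort("score_noise_sd must be >= 0", class = "megpac_error_config")
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 score_intercept = score_intercept, score_slope = score_slope,
                 score_noise_sd = score_noise_sd,
                 control_depth = control_depth, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a case-control cohort
#'
#' Generates one [recording()] per participant from `sim` (patients with
#' per-subject coupling depth, controls with `spec$control_depth`) plus a
#' cohort table with clinical covariates. Ages, sex, affected side,
#' medication state, LEDD and disease duration are sampled to resemble a
#' typical Parkinson's disease cohort; only the akinesia score is tied to the
#' generative model.
#'
#' @param spec A [cohort_spec()].
#' @param sim A [sim_config()]; its `coupling_depth` and `seed` are
#'   overridden per subject, everything else (bands, parcels, duration)
#'   defines the recordings. Patients receive coupling in
#'   `sim$coupled_parcels`; this set must be non-empty.
#' @return A list with `recordings` (named list of [recording()]) and
#'   `cohort` (a tibble: id, sex, age_years, affected_side, akinesia_score,
#'   state, ledd_mg, duration_years, group, coupling_depth).
#' @export
simulate_cohort <- function(spec, sim = sim_config()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(sim, "sim_config"))
  if (length(sim$coupled_parcels) == 0) {
    abort("patients need a non-empty coupled-parcel set",
          class = "megpac_error_config")
  }
  n_tot <- spec$n_patients + spec$n_controls
  with_local_seed(spec$seed, {
    k <- c(rtruncnorm01(spec$n_patients, spec$depth_mean, spec$depth_sd),
           rep(spec$control_depth, spec$n_controls))
    eps <- rnorm(spec$n_patients, 0, spec$score_noise_sd)
    score_raw <- spec$score_intercept + spec$score_slope * k[seq_len(spec$n_patients)] + eps
    score <- pmax(0L, as.integer(round(score_raw)))
    sex <- sample(c("M", "F"), n_tot, replace = TRUE)
    age <- pmin(85, pmax(40, round(rnorm(n_tot, 65, 8))))
    side <- sample(c("Left", "Right"), n_tot, replace = TRUE, prob = c(0.7, 0.3))
    state <- sample(c("On", "Off"), n_tot, replace = TRUE, prob = c(0.83, 0.17))
    ledd <- round(stats::rlnorm(n_tot, log(400), 0.9))
    dur <- pmax(1, round(stats::rgamma(n_tot, shape = 2, scale = 4)))
    seeds <- derive_seeds(spec$seed, n_tot)
    group <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
    id <- sprintf("%s%02d", ifelse(group == "patient", "PD", "HC"),
                  c(seq_len(spec$n_patients), seq_len(spec$n_controls)))
    recs <- vector("list", n_tot)
    names(recs) <- id
    for (i in seq_len(n_tot)) {
      cfg <- sim
      cfg$coupling_depth <- k[i]
      cfg$coupled_parcels <- if (group[i] == "patient" || spec$control_depth > 0)
        sim$coupled_parcels else integer(0)
      if (k[i] == 0) cfg$coupled_parcels <- integer(0)
      cfg$seed <- seeds[i]
      r <- simulate_recording(cfg)
      r$participant_id <- id[i]
      r$group <- group[i]
      recs[[i]] <- r
    }
    cohort <- tibble(
      id = id, sex = sex, age_years = as.numeric(age), affected_side = side,
      akinesia_score = ifelse(group == "patient",
                              c(score, rep(NA_integer_, spec$n_controls)), NA),
      state = state,
      ledd_mg = ifelse(group == "patient",
                       c(ledd[seq_len(spec$n_patients)],
                         rep(NA_real_, spec$n_controls)), NA),
      duration_years = ifelse(group == "patient",
                              c(dur[seq_len(spec$n_patients)],
                                rep(NA_real_, spec$n_controls)), NA),
      group = group, coupling_depth = k)
    list(recordings = recs, cohort = cohort)
  })
}
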