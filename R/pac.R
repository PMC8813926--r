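#' Analytic signal via the FFT half-spectrum method
#'
#' Returns the complex analytic signal `x + i * H(x)` (H = Hilbert
#' transform), computed by zeroing the negative-frequency half of the
#' spectrum and doubling the positive half.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) abort("empty input", class = "megpac_error_numeric")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Default edge trim: one second per segment side, covering the ringing of
# the zero-phase band-pass filters (the slowest band used is 4 Hz wide).
default_trim_s <- 1

# Extract per-segment vectors of x restricted to clean segments longer than
# the trim; returns a list of numeric vectors.
clean_segment_list <- function(x, fs, segments, trim_s) {
  trim <- as.integer(round(trim_s * fs))
  out <- list()
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, 1]; e <- segments[i, 2]
    if (e - s > 2 * trim) out[[length(out) + 1L]] <- x[(s + 1L):e]
  }
  if (length(out) == 0L) {
    abort("no clean segment longer than twice the edge trim",
          class = "megpac_error_numeric")
  }
  out
}

trim_edges <- function(v, fs, trim_s) {
  trim <- as.integer(round(trim_s * fs))
  v[(trim + 1L):(length(v) - trim)]
}

#' Low-frequency-band phase series
#'
#' Band-passes the signal at `band` (zero-phase Butterworth), takes the
#' analytic phase, trims `trim_s` seconds from each end of every contiguous
#' clean segment (filter edge transients), and pools the per-segment phases
#' into one vector.
#'
#' @param x Numeric signal vector (one parcel).
#' @param fs Sampling rate (Hz).
#' @param band A [band_spec()]; upper edge must be below Nyquist.
#' @param segments Clean-segment matrix (0-based half-open); default the
#'   whole signal.
#' @param trim_s Edge trim per segment side, seconds.
#' @return Numeric vector of phases in `(-pi, pi]`.
#' @export
low_band_phase <- function(x, fs, band, segments = NULL, trim_s = default_trim_s) {
  stopifnot(inherits(band, "band_spec"))
  if (band$high_hz >= fs / 2) {
    abort("band upper edge at or above Nyquist", class = "megpac_error_config")
  }
  if (is.null(segments)) segments <- matrix(c(0L, length(x)), ncol = 2L)
  segs <- clean_segment_list(x, fs, segments, trim_s)
  unlist(lapply(segs, function(v) {
    ph <- Arg(analytic_signal(bandpass_vec(v, fs, band$low_hz, band$high_hz)))
    trim_edges(ph, fs, trim_s)
  }))
}

#' Phase of the high-band amplitude envelope
#'
#' The signal is band-passed at `amp_band`, its analytic amplitude envelope
#' is taken, the envelope is band-passed again at `phase_band` (so the
#' envelope fluctuations are examined at the modulating rhythm's time
#' scale), and the analytic phase of that filtered envelope is returned,
#' edge-trimmed and pooled across clean segments exactly as in
#' [low_band_phase()].
#'
#' @inheritParams low_band_phase
#' @param amp_band High-frequency amplitude band.
#' @param phase_band Low-frequency band applied to the envelope.
#' @return Numeric vector of envelope phases in `(-pi, pi]`, the same length
#'   as the matching [low_band_phase()] output.
#' @export
envelope_phase <- function(x, fs, amp_band, phase_band, segments = NULL,
                           trim_s = default_trim_s) {
  stopifnot(inherits(amp_band, "band_spec"), inherits(phase_band, "band_spec"))
  if (amp_band$high_hz >= fs / 2) {
    abort("band upper edge at or above Nyquist", class = "megpac_error_config")
  }
  if (is.null(segments)) segments <- matrix(c(0L, length(x)), ncol = 2L)
  segs <- clean_segment_list(x, fs, segments, trim_s)
  unlist(lapply(segs, function(v) {
    env <- Mod(analytic_signal(bandpass_vec(v, fs, amp_band$low_hz, amp_band$high_hz)))
    env_f <- bandpass_vec(env, fs, phase_band$low_hz, phase_band$high_hz)
    ph <- Arg(analytic_signal(env_f))
    trim_edges(ph, fs, trim_s)
  }))
}

#' Synchronization index
#'
#' `SI = | (1/N) * sum_t exp(i * (theta_phs(t) - theta_amp(t))) |`: the
#' resultant length of the phase difference between the low-band phase and
#' the phase of the low-band-filtered high-band envelope. 0 means the two
#' phase series are unrelated; 1 means perfect phase locking.
#'
#' @param theta_phs,theta_amp Equal-length phase vectors (radians).
#' @return SI in `[0, 1]`.
#' @export
synchronization_index <- function(theta_phs, theta_amp) {
  if (length(theta_phs) == 0L || length(theta_amp) == 0L) {
    abort("empty phase series", class = "megpac_error_numeric")
  }
  if (length(theta_phs) != length(theta_amp)) {
    abort("phase series lengths differ", class = "megpac_error_numeric")
  }
  Mod(mean(exp(1i * (theta_phs - theta_amp))))
}

#' Resultant length of a single phase series
#'
#' `| (1/N) * sum_t exp(i * theta(t)) |`: the concentration of a phase
#' distribution (0 = uniform, 1 = constant). Computed for both the low-band
#' phase and the envelope phase when comparing phase structure between
#' groups.
#'
#' @param theta Phase vector (radians).
#' @return Value in `[0, 1]`.
#' @export
phase_value <- function(theta) {
  if (length(theta) == 0L) abort("empty phase series",
                                 class = "megpac_error_numeric")
  Mod(mean(exp(1i * theta)))
}

#' Rotation (phase-shuffle) surrogate of a phase series
#'
#' Cuts the series at one uniformly random time point `c` in `1..N-1` and
#' swaps the two blocks (a circular rotation), destroying the alignment with
#' any other series while preserving the multiset of values and all
#' within-block autocorrelation.
#'
#' @param theta Phase vector, length >= 2.
#' @param cut Optional fixed cut point (otherwise drawn from `seed`).
#' @param seed RNG seed for the cut.
#' @return Rotated phase vector.
#' @export
phase_shuffle <- function(theta, cut = NULL, seed = NULL) {
  n <- length(theta)
  if (n < 2L) abort("need at least 2 samples to shuffle",
                    class = "megpac_error_numeric")
  if (is.null(cut)) {
    cut <- with_local_seed(seed, sample.int(n - 1L, 1L))
  }
  stopifnot(cut >= 1L, cut <= n - 1L)
  c(theta[(cut + 1L):n], theta[seq_len(cut)])
}

#' Surrogate test of phase-amplitude coupling
#'
#' Computes the observed SI between [low_band_phase()] and
#' [envelope_phase()], then builds a null distribution by recomputing SI
#' after rotating the low-frequency phase series at a random cut point
#' (`n_surr` times; the envelope phase stays fixed). The empirical p-value
#' uses the add-one correction `p = (1 + #\{SI_surr >= SI_obs\}) / (1 + n_surr)`
#' and can therefore never be exactly zero.
#'
#' @inheritParams envelope_phase
#' @param n_surr Number of surrogates (default 1000).
#' @param seed Master seed; per-surrogate cut points derive from it.
#' @return An object of class `surrogate_result`: list with `si`,
#'   `surrogate_si` (vector), `surrogate_mean`, `p`, `n_surrogates`, `n`,
#'   bands and `seed`. Has [tidy()] and [glance()] methods.
#' @export
surrogate_test <- function(x, fs, phase_band, amp_band, segments = NULL,
                           n_surr = 1000, seed = 1L, trim_s = default_trim_s) {
  if (n_surr < 1) abort("n_surr must be >= 1", class = "megpac_error_config")
  th_p <- low_band_phase(x, fs, phase_band, segments, trim_s)
  th_a <- envelope_phase(x, fs, amp_band, phase_band, segments, trim_s)
  si_from_phases_surrogates(th_p, th_a, n_surr, seed, phase_band, amp_band)
}

# Shared core: observed SI + rotation surrogates from precomputed phases.
si_from_phases_surrogates <- function(th_p, th_a, n_surr, seed,
                                      phase_band = NULL, amp_band = NULL) {
  obs <- synchronization_index(th_p, th_a)
  n <- length(th_p)
  z <- exp(1i * th_p)
  w <- exp(-1i * th_a)
  cuts <- with_local_seed(seed, sample.int(n - 1L, n_surr, replace = TRUE))
  surr <- vapply(cuts, function(cu) {
    Mod(mean(c(z[(cu + 1L):n], z[seq_len(cu)]) * w))
  }, numeric(1))
  structure(list(si = obs, surrogate_si = surr,
                 surrogate_mean = mean(surr),
                 p = (1 + sum(surr >= obs)) / (1 + n_surr),
                 n_surrogates = as.integer(n_surr), n = n,
                 phase_band = phase_band, amp_band = amp_band,
                 seed = seed),
            class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("<surrogate_result> SI = %.4f, surrogate mean = %.4f, p = %.4g (%d surrogates, N = %d)\n",
              x$si, x$surrogate_mean, x$p, x$n_surrogates, x$n))
  invisible(x)
}

#' SI comodulogram over a band grid
#'
#' Computes the SI for every combination of phase band and amplitude band
#' (defaults: the nine 4-Hz phase bands 4-8 ... 20-24 Hz by the eight 50-Hz
#' amplitude bands 30-80 ... 100-150 Hz), using the pooled clean record as a
#' single analysis window. Optionally adds rotation-surrogate summaries per
#' cell.
#'
#' @inheritParams low_band_phase
#' @param phase_grid,amp_grid Lists of [band_spec()] (defaults
#'   [phase_band_grid()] and [amp_band_grid()]).
#' @param n_surr Surrogates per cell (0 = none, the default).
#' @param seed Master seed when `n_surr > 0`.
#' @return A tibble of class `comodulogram`: `phase_low`, `phase_high`,
#'   `phase_center`, `amp_low`, `amp_high`, `amp_center`, `si` (plus
#'   `surrogate_mean`, `p` when surrogates are requested).
#' @export
comodulogram <- function(x, fs, phase_grid = phase_band_grid(),
                         amp_grid = amp_band_grid(), segments = NULL,
                         n_surr = 0, seed = 1L, trim_s = default_trim_s) {
  if (length(phase_grid) == 0L || length(amp_grid) == 0L) {
    abort("empty band grid", class = "megpac_error_config")
  }
  th_p <- lapply(phase_grid, function(b) low_band_phase(x, fs, b, segments, trim_s))
  rows <- list()
  seeds <- derive_seeds(seed, length(phase_grid) * length(amp_grid))
  cell <- 0L
  for (ai in seq_along(amp_grid)) {
    for (pi_ in seq_along(phase_grid)) {
      cell <- cell + 1L
      pb <- phase_grid[[pi_]]; ab <- amp_grid[[ai]]
      th_a <- envelope_phase(x, fs, ab, pb, segments, trim_s)
      row <- tibble(phase_low = pb$low_hz, phase_high = pb$high_hz,
                    phase_center = band_center(pb),
                    amp_low = ab$low_hz, amp_high = ab$high_hz,
                    amp_center = band_center(ab),
                    si = synchronization_index(th_p[[pi_]], th_a))
      if (n_surr > 0) {
        sr <- si_from_phases_surrogates(th_p[[pi_]], th_a, n_surr, seeds[cell])
        row$surrogate_mean <- sr$surrogate_mean
        row$p <- sr$p
      }
      rows[[cell]] <- row
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("comodulogram", class(out))
  out
}

#' Per-parcel SI with surrogate summaries
#'
#' Runs [surrogate_test()] on every parcel of a recording at one
#' (phase band, amplitude band) pair — the canonical whole-brain analysis
#' uses alpha or beta phase against the 50-100 Hz gamma amplitude.
#'
#' @param rec A [recording()].
#' @param phase_band,amp_band [band_spec()]s.
#' @param n_surr Surrogates per parcel (default 1000; 0 skips surrogates and
#'   returns only `si`).
#' @param seed Master seed; per-parcel seeds derive from it.
#' @param trim_s Edge trim per segment side, seconds.
#' @return A tibble: `participant`, `parcel`, `si` (+ `surrogate_mean`, `p`
#'   when `n_surr > 0`).
#' @export
pac_parcels <- function(rec, phase_band = band_spec(13, 25, "beta"),
                        amp_band = band_spec(50, 100, "gamma"),
                        n_surr = 1000, seed = 1L, trim_s = default_trim_s) {
  stopifnot(inherits(rec, "recording"))
  seeds <- derive_seeds(seed, nrow(rec$data))
  rows <- lapply(seq_len(nrow(rec$data)), function(p) {
    x <- rec$data[p, ]
    if (n_surr > 0) {
      sr <- surrogate_test(x, rec$fs_hz, phase_band, amp_band,
                           rec$clean_segments, n_surr, seeds[p], trim_s)
      tibble(participant = rec$participant_id, parcel = rec$parcel_ids[p],
             si = sr$si, surrogate_mean = sr$surrogate_mean, p = sr$p)
    } else {
      th_p <- low_band_phase(x, rec$fs_hz, phase_band, rec$clean_segments, trim_s)
      th_a <- envelope_phase(x, rec$fs_hz, amp_band, phase_band,
                             rec$clean_segments, trim_s)
      tibble(participant = rec$participant_id, parcel = rec$parcel_ids[p],
             si = synchronization_index(th_p, th_a))
    }
  })
  bind_rows(rows)
}
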