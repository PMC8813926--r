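# Shared fixture builders (all generated in code; no stored data).

# Recording holding pure tones (one per parcel) plus optional noise.
tone_recording <- function(freqs, fs = 500, duration_s = 20, noise_sd = 0,
                           amplitude = 1, seed = 1) {
  t <- seq_len(duration_s * fs) / fs
  dat <- t(vapply(freqs, function(f) amplitude * sin(2 * pi * f * t),
                  numeric(length(t))))
  if (noise_sd > 0) {
    set.seed(seed)
    dat <- dat + matrix(rnorm(length(dat), 0, noise_sd), nrow = nrow(dat))
  }
  recording(dat, fs_hz = fs)
}

# Gaussian-noise recording.
noise_recording <- function(n_parcels = 1, fs = 500, duration_s = 20,
                            seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n_parcels * duration_s * fs),
                   nrow = n_parcels), fs_hz = fs)
}

# Small coupled simulation config used across tests.
quick_sim <- function(k, seed = 1, duration_s = 30, n_parcels = 1,
                      coupled = if (k > 0) 1L else integer(0)) {
  sim_config(duration_s = duration_s, n_parcels = n_parcels,
             coupling_depth = k, coupled_parcels = coupled, seed = seed)
}

beta_band <- band_spec(13, 25, "beta")
gamma_band <- band_spec(50, 100, "gamma")

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}
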