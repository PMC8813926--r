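#' Band power per parcel
#'
#' Welch-style band power: each parcel's clean signal is tiled into
#' overlapping windows (default 1 s shifted by 200 ms) lying entirely inside
#' a single clean segment, a Hamming window and FFT are applied, and the
#' periodogram bins with frequency in `(low_hz, high_hz]` are summed; the
#' band power is the mean over windows. The periodogram is one-sided and
#' normalized so that (with a rectangular window) its total equals the
#' signal's mean square — the absolute scale is internal, since downstream
#' Z-scoring removes it.
#'
#' @param rec A [recording()].
#' @param band A [band_spec()].
#' @param win_s Window length in seconds (default 1).
#' @param step_s Window shift in seconds (default 0.2).
#' @return A tibble: `participant`, `parcel`, `band`, `power`, `n_windows`.
#' @export
band_power <- function(rec, band, win_s = 1.0, step_s = 0.2) {
  stopifnot(inherits(rec, "recording"), inherits(band, "band_spec"))
  fs <- rec$fs_hz
  w <- as.integer(round(win_s * fs))
  step <- max(1L, as.integer(round(step_s * fs)))
  starts <- window_starts(rec$clean_segments, w, step)
  if (length(starts) == 0L) {
    abort("no analysis window fits inside the clean segments",
          class = "megpac_error_numeric")
  }
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
  freqs <- (seq_len(w %/% 2 + 1) - 1) * fs / w
  in_band <- freqs > band$low_hz & freqs <= band$high_hz
  if (!any(in_band)) {
    abort("no frequency bin falls inside the band; window too short",
          class = "megpac_error_numeric")
  }
  pow <- vapply(seq_len(nrow(rec$data)), function(p) {
    x <- rec$data[p, ]
    vals <- vapply(starts, function(s) {
      seg <- x[(s + 1L):(s + w)] * ham
      sum(periodogram_onesided(seg, ham)[in_band])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  tibble(participant = rec$participant_id, parcel = rec$parcel_ids,
         band = band$label, power = pow, n_windows = length(starts))
}

# 0-based start offsets of windows of length w, shifted by step, fully
# inside one clean segment.
window_starts <- function(segments, w, step) {
  unlist(lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, 1]; e <- segments[i, 2]
    if (e - s < w) return(integer(0))
    seq(s, e - w, by = step)
  }))
}

# One-sided periodogram of a (pre-windowed) segment; normalization such that
# sum(periodogram(x * rect)) == mean(x^2).
periodogram_onesided <- function(xw, win) {
  n <- length(xw)
  X <- fft(xw)[seq_len(n %/% 2 + 1)]
  p <- Mod(X)^2 / sum(win^2) / n
  scale <- rep(2, length(p)); scale[1] <- 1
  if (n %% 2 == 0) scale[length(p)] <- 1
  p * scale
}

#' Whole-brain Z normalization of a power map
#'
#' Z-scores `power` across parcels within each participant and band (sample
#' SD, `n - 1`), implementing whole-brain normalization per frequency band.
#'
#' @param pm A tibble as returned by [band_power()] (possibly several bands /
#'   participants row-bound).
#' @return The tibble with a `z` column added.
#' @export
zscore_parcels <- function(pm) {
  stopifnot(is.data.frame(pm), all(c("participant", "parcel", "band", "power") %in% names(pm)))
  out <- pm |>
    group_by(.data$participant, .data$band) |>
    mutate(z = {
      if (n() < 2) abort("Z normalization needs at least 2 parcels",
                         class = "megpac_error_numeric")
      s <- sd(.data$power)
      if (s == 0) abort("zero SD across parcels: Z scores undefined",
                        class = "megpac_error_numeric")
      (.data$power - mean(.data$power)) / s
    }) |>
    dplyr::ungroup()
  out
}

#' Average vertex-level values into parcels
#'
#' Arithmetic mean of vertex values per parcel, for users whose metrics live
#' on a vertex mesh; every vertex must map to exactly one parcel.
#'
#' @param vertex_values A data frame with columns `vertex` and `value`.
#' @param parcel_table A data frame with columns `vertex` and `parcel`.
#' @return A tibble `parcel`, `value` (mean), `n_vertices`.
#' @export
average_by_parcel <- function(vertex_values, parcel_table) {
  stopifnot(all(c("vertex", "value") %in% names(vertex_values)),
            all(c("vertex", "parcel") %in% names(parcel_table)))
  if (anyDuplicated(parcel_table$vertex)) {
    abort("a vertex maps to more than one parcel", class = "megpac_error_schema")
  }
  unmapped <- setdiff(vertex_values$vertex, parcel_table$vertex)
  if (length(unmapped) > 0) {
    abort(sprintf("unmapped vertices: %s",
                  paste(head(unmapped, 5), collapse = ", ")),
          class = "megpac_error_schema")
  }
  vertex_values |>
    left_join(parcel_table, by = "vertex") |>
    group_by(.data$parcel) |>
    summarise(value = mean(.data$value), n_vertices = n(), .groups = "drop")
}
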