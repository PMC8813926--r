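#' @importFrom signal butter filtfilt
NULL

# Zero-phase Butterworth helpers operating on one numeric vector.
# Orders are per pass; filtfilt doubles the effective order and cancels
# group delay. Order 2 is used where the normalized cutoff is extreme
# (0.5 Hz high-pass, 1.5 Hz-wide notch) because higher orders are
# numerically fragile there; band-pass uses order 4.
highpass_vec <- function(x, fs, cutoff_hz) {
  bf <- butter(2, cutoff_hz / (fs / 2), type = "high")
  as.numeric(filtfilt(bf, x))
}

bandstop_vec <- function(x, fs, center_hz, width_hz) {
  edges <- c(center_hz - width_hz / 2, center_hz + width_hz / 2)
  bf <- butter(2, edges / (fs / 2), type = "stop")
  as.numeric(filtfilt(bf, x))
}

bandpass_vec <- function(x, fs, low_hz, high_hz) {
  bf <- butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(filtfilt(bf, x))
}

apply_rowwise <- function(rec, f) {
  rec$data <- t(apply(rec$data, 1L, f))
  rec
}

#' Zero-phase high-pass filter (baseline correction)
#'
#' Removes DC and slow drift with a zero-phase (forward-backward)
#' Butterworth high-pass, default cutoff 0.5 Hz.
#'
#' @param rec A [recording()].
#' @param cutoff_hz Cutoff frequency in Hz (< Nyquist).
#' @return The filtered recording.
#' @export
highpass <- function(rec, cutoff_hz = 0.5) {
  stopifnot(inherits(rec, "recording"))
  if (cutoff_hz <= 0 || cutoff_hz >= rec$fs_hz / 2) {
    abort(sprintf("high-pass cutoff %g Hz must lie in (0, Nyquist = %g Hz)",
                  cutoff_hz, rec$fs_hz / 2),
          class = "megpac_error_config")
  }
  apply_rowwise(rec, function(x) highpass_vec(x, rec$fs_hz, cutoff_hz))
}

#' Zero-phase power-line band-stop filter
#'
#' Notches out power-line contamination, default 60 Hz with a total stop
#' width of 1.5 Hz.
#'
#' @param rec A [recording()].
#' @param center_hz Notch center frequency (Hz).
#' @param width_hz Total stop-band width (Hz), > 0.
#' @return The filtered recording.
#' @export
bandstop <- function(rec, center_hz = 60, width_hz = 1.5) {
  stopifnot(inherits(rec, "recording"))
  if (width_hz <= 0) {
    abort("band-stop width must be > 0", class = "megpac_error_config")
  }
  if (center_hz + width_hz / 2 >= rec$fs_hz / 2) {
    abort("band-stop edge reaches Nyquist", class = "megpac_error_config")
  }
  apply_rowwise(rec, function(x) bandstop_vec(x, rec$fs_hz, center_hz, width_hz))
}

#' Downsample a recording
#'
#' Anti-alias filters and resamples every parcel to `target_hz` (default
#' 500 Hz). Only downsampling is supported. The output length is
#' `floor(n * target_hz / fs_hz)` and clean segments are rescaled by the same
#' ratio (floor on both edges).
#'
#' @param rec A [recording()].
#' @param target_hz Target sampling rate, `<= fs_hz`.
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, target_hz = 500) {
  stopifnot(inherits(rec, "recording"))
  if (target_hz > rec$fs_hz) {
    abort("upsampling is out of contract: target_hz must be <= fs_hz",
          class = "megpac_error_config")
  }
  if (target_hz == rec$fs_hz) return(rec)
  ratio <- target_hz / rec$fs_hz
  n_out <- floor(n_samples(rec) * ratio)
  frac <- gcd_ratio(target_hz, rec$fs_hz)
  dat <- t(apply(rec$data, 1L, function(x) {
    y <- as.numeric(signal::resample(x, frac[1], frac[2]))
    length(y) <- n_out  # truncate (resample may round up)
    y
  }))
  seg <- rec$clean_segments
  seg <- matrix(as.integer(floor(seg * ratio)), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  seg <- seg[seg[, 1] < seg[, 2], , drop = FALSE]
  recording(dat, fs_hz = target_hz, participant_id = rec$participant_id,
            group = rec$group, clean_segments = seg,
            parcel_ids = rec$parcel_ids)
}

gcd_ratio <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(round(p), round(q))
  c(round(p) / d, round(q) / d)
}

#' Detect artifact-contaminated segments
#'
#' Implements the amplitude criterion for contaminated segments: the
#' recording is tiled into non-overlapping windows (default 1 s); a window is
#' flagged when its peak absolute amplitude in any parcel exceeds `k_sd`
#' (default 5) standard deviations of that parcel's currently clean samples.
#' The SD is then re-estimated excluding flagged windows and the rule is
#' iterated to convergence, so that large artifacts do not inflate their own
#' threshold. Flags are unioned across parcels (a contaminated segment is
#' discarded from all channels).
#'
#' @param rec A [recording()].
#' @param window_s Detection window length in seconds (default 1).
#' @param k_sd Threshold in clean-sample SD units (default 5).
#' @return A `segment_mask`: list with `flagged` (0-based half-open interval
#'   matrix) and `k_sd`.
#' @export
detect_artifact_segments <- function(rec, window_s = 1, k_sd = 5) {
  stopifnot(inherits(rec, "recording"))
  n <- n_samples(rec)
  if (n == 0L) abort("empty recording", class = "megpac_error_schema")
  w <- as.integer(floor(window_s * rec$fs_hz))
  if (w < 1L) abort("window_s x fs_hz must be >= 1", class = "megpac_error_config")
  n_win <- n %/% w
  if (n_win < 1L) abort("recording shorter than one window",
                        class = "megpac_error_config")
  win_of <- rep(seq_len(n_win), each = w)
  used <- seq_len(n_win * w)
  # per parcel x window peak |amplitude|
  peaks <- apply(rec$data[, used, drop = FALSE], 1L, function(x) {
    tapply(abs(x), win_of, max)
  })  # n_win x n_parcels
  peaks <- matrix(peaks, nrow = n_win)
  flagged <- rep(FALSE, n_win)
  repeat {
    if (all(flagged)) {
      abort("all windows flagged as artifact: unusable recording",
            class = "megpac_error_numeric")
    }
    clean_idx <- used[!flagged[win_of]]
    sds <- apply(rec$data[, clean_idx, drop = FALSE], 1L, sd)
    new_flagged <- rowSums(peaks > matrix(k_sd * sds, nrow = n_win,
                                          ncol = length(sds), byrow = TRUE)) > 0
    if (identical(new_flagged, flagged)) break
    flagged <- flagged | new_flagged
  }
  idx <- which(flagged)
  seg <- if (length(idx) == 0L) {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  } else {
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    do.call(rbind, lapply(runs, function(r) {
      c(start = (min(r) - 1L) * w, end = max(r) * w)
    }))
  }
  structure(list(flagged = matrix(as.integer(seg), ncol = 2L,
                                  dimnames = list(NULL, c("start", "end"))),
                 k_sd = k_sd, window_s = window_s),
            class = "segment_mask")
}

#' Apply an artifact mask to a recording
#'
#' Updates `clean_segments` to the intersection of the current clean set with
#' the complement of the flagged intervals; the data array is untouched
#' (phase/amplitude extraction later runs per contiguous clean segment).
#'
#' @param rec A [recording()].
#' @param mask A `segment_mask` from [detect_artifact_segments()].
#' @return The recording with updated `clean_segments`.
#' @export
apply_segments <- function(rec, mask) {
  stopifnot(inherits(rec, "recording"), inherits(mask, "segment_mask"))
  n <- n_samples(rec)
  keep <- complement_segments(mask$flagged, n)
  rec$clean_segments <- intersect_segments(rec$clean_segments, keep)
  rec
}

#' Standard preprocessing pipeline
#'
#' Fixed stage order: high-pass (baseline correction) -> artifact-segment
#' detection and masking -> power-line band-stop -> downsampling (last, for
#' speed). Each stage is the corresponding exported function with its
#' defaults unless overridden.
#'
#' @param rec A [recording()].
#' @param highpass_hz High-pass cutoff (Hz).
#' @param notch_hz,notch_width_hz Band-stop center and total width (Hz); set
#'   `notch_hz = NULL` to skip the notch.
#' @param target_hz Output sampling rate.
#' @param window_s,k_sd Artifact-detection parameters.
#' @return The preprocessed recording; discarded intervals (at the original
#'   sampling rate) are stored in `attr(, "discarded_segments")`.
#' @export
preprocess <- function(rec, highpass_hz = 0.5, notch_hz = 60,
                       notch_width_hz = 1.5, target_hz = 500,
                       window_s = 1, k_sd = 5) {
  rec <- highpass(rec, highpass_hz)
  mask <- detect_artifact_segments(rec, window_s = window_s, k_sd = k_sd)
  rec <- apply_segments(rec, mask)
  if (!is.null(notch_hz)) rec <- bandstop(rec, notch_hz, notch_width_hz)
  rec <- resample_recording(rec, target_hz)
  attr(rec, "discarded_segments") <- mask$flagged
  rec
}
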