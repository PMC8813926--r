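#' Parcel-level recording
#'
#' Container for one participant's parcel-by-sample time-series matrix plus
#' metadata. `clean_segments` is an integer matrix with one row per contiguous
#' artifact-free interval, columns `start`/`end`, using 0-based half-open
#' sample indexing `[start, end)` (the convention used by every interval in
#' this package).
#'
#' @param data Numeric matrix, parcels x samples.
#' @param fs_hz Sampling rate (Hz), positive scalar.
#' @param participant_id Participant identifier string.
#' @param group `"patient"` or `"control"`.
#' @param clean_segments Integer matrix (n x 2) of half-open clean intervals;
#'   defaults to the whole recording.
#' @param parcel_ids Character vector of parcel identifiers (defaults to
#'   `"P001"`, `"P002"`, ...).
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs_hz, participant_id = "S01", group = "patient",
                      clean_segments = NULL, parcel_ids = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric parcels x samples matrix",
          class = "megpac_error_schema")
  }
  if (nrow(data) < 1L) {
    abort("recording must contain at least one parcel",
          class = "megpac_error_schema")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    abort("`fs_hz` must be a positive scalar", class = "megpac_error_schema")
  }
  group <- match.arg(group, c("patient", "control"))
  n <- ncol(data)
  if (is.null(clean_segments)) {
    clean_segments <- matrix(c(0L, n), nrow = 1L)
  }
  clean_segments <- validate_segments(clean_segments, n)
  if (is.null(parcel_ids)) {
    parcel_ids <- sprintf("P%03d", seq_len(nrow(data)))
  }
  if (length(parcel_ids) != nrow(data)) {
    abort("`parcel_ids` length must match the number of parcels",
          class = "megpac_error_schema")
  }
  structure(list(data = data, fs_hz = as.numeric(fs_hz),
                 participant_id = as.character(participant_id),
                 group = group, clean_segments = clean_segments,
                 parcel_ids = as.character(parcel_ids)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (%s): %d parcels x %d samples @ %g Hz, %d clean segment(s), %.1f s clean\n",
              x$participant_id, x$group, nrow(x$data), ncol(x$data), x$fs_hz,
              nrow(x$clean_segments),
              sum(x$clean_segments[, 2] - x$clean_segments[, 1]) / x$fs_hz))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

validate_segments <- function(seg, n_total) {
  seg <- matrix(as.integer(seg), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  if (nrow(seg) == 0L) return(seg)
  if (any(seg[, 1] < 0L) || any(seg[, 2] > n_total) || any(seg[, 1] >= seg[, 2])) {
    abort("segments must be non-empty half-open intervals within [0, n_samples)",
          class = "megpac_error_schema")
  }
  o <- order(seg[, 1])
  seg <- seg[o, , drop = FALSE]
  if (nrow(seg) > 1L && any(seg[-1L, 1] < seg[-nrow(seg), 2])) {
    abort("segments must be pairwise disjoint", class = "megpac_error_schema")
  }
  seg
}

# Complement of a sorted disjoint interval set within [0, n).
complement_segments <- function(seg, n_total) {
  if (nrow(seg) == 0L) return(matrix(c(0L, as.integer(n_total)), ncol = 2L,
                                     dimnames = list(NULL, c("start", "end"))))
  seg <- validate_segments(seg, n_total)
  starts <- c(0L, seg[, 2])
  ends <- c(seg[, 1], as.integer(n_total))
  keep <- starts < ends
  matrix(c(starts[keep], ends[keep]), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

# Intersection of two sorted disjoint interval sets.
intersect_segments <- function(a, b) {
  out <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      s <- max(a[i, 1], b[j, 1]); e <- min(a[i, 2], b[j, 2])
      if (s < e) out <- rbind(out, c(s, e))
    }
  }
  out[order(out[, 1]), , drop = FALSE]
}

# 1-based R sample indices covered by a 0-based half-open segment matrix.
segment_indices <- function(seg) {
  if (nrow(seg) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(seg)), function(i) (seg[i, 1] + 1L):seg[i, 2]))
}
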