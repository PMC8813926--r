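#' Frequency band specification
#'
#' A band is a half-open-by-convention interval `[low_hz, high_hz]` on the
#' frequency axis with an optional label. The canonical resting-state bands
#' used throughout the package are alpha 8-12 Hz, beta 13-25 Hz and gamma
#' 50-100 Hz.
#'
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz`.
#' @param label Band label; one of `"alpha"`, `"beta"`, `"gamma"` or a custom
#'   string (default `"custom"`).
#' @return An object of class `band_spec` (a named list with `low_hz`,
#'   `high_hz`, `label`).
#' @examples
#' band_spec(13, 25, "beta")
#' @export
band_spec <- function(low_hz, high_hz, label = "custom") {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      length(low_hz) != 1L || length(high_hz) != 1L) {
    abort("band edges must be single numbers", class = "megpac_error_band")
  }
  if (!(low_hz > 0 && high_hz > low_hz)) {
    abort(sprintf("invalid band [%g, %g]: need 0 < low < high", low_hz, high_hz),
          class = "megpac_error_band")
  }
  structure(list(low_hz = as.numeric(low_hz), high_hz = as.numeric(high_hz),
                 label = as.character(label)),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$label, x$low_hz, x$high_hz))
  invisible(x)
}

band_center <- function(b) (b$low_hz + b$high_hz) / 2

#' Canonical analysis bands
#'
#' @return A named list of `band_spec`: alpha 8-12 Hz, beta 13-25 Hz,
#'   gamma 50-100 Hz.
#' @export
canonical_bands <- function() {
  list(alpha = band_spec(8, 12, "alpha"),
       beta  = band_spec(13, 25, "beta"),
       gamma = band_spec(50, 100, "gamma"))
}

#' Comodulogram frequency grids
#'
#' The full comodulogram grid pairs nine 4-Hz-wide phase bands (4-8, 6-10,
#' ..., 20-24 Hz; centers 6, 8, ..., 22 Hz) with eight 50-Hz-wide amplitude
#' bands (30-80, 40-90, ..., 100-150 Hz; centers 55, 65, ..., 125 Hz).
#'
#' @return A list of `band_spec` objects.
#' @export
phase_band_grid <- function() {
  lapply(seq(4, 20, by = 2), function(lo) band_spec(lo, lo + 4))
}

#' @rdname phase_band_grid
#' @export
amp_band_grid <- function() {
  lapply(seq(30, 100, by = 10), function(lo) band_spec(lo, lo + 50))
}
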