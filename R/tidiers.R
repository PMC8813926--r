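#' Tidy a surrogate test result
#'
#' @param x A `surrogate_result` from [surrogate_test()].
#' @param ... Unused.
#' @return A one-row tibble: `si`, `surrogate_mean`, `p`, `n_surrogates`,
#'   `n`.
#' @export
tidy.surrogate_result <- function(x, ...) {
  tibble(si = x$si, surrogate_mean = x$surrogate_mean, p = x$p,
         n_surrogates = x$n_surrogates, n = x$n)
}

#' @rdname tidy.surrogate_result
#' @export
glance.surrogate_result <- function(x, ...) tidy.surrogate_result(x)

#' Tidy a correlation result
#'
#' @param x A `correlation_result` from [correlate_metric()].
#' @param ... Unused.
#' @return A one-row tibble with `r`, `p_parametric`, `n` and the confidence
#'   bounds.
#' @export
tidy.correlation_result <- function(x, ...) {
  out <- tibble(r = x$r, p_parametric = x$p_parametric, n = x$n,
                conf_low = x$conf_low, conf_high = x$conf_high)
  if (!is.null(x$p_permutation)) {
    out$p_permutation <- x$p_permutation
    out$n_permutations <- x$n_permutations
  }
  out
}

#' @rdname tidy.correlation_result
#' @export
glance.correlation_result <- function(x, ...) tidy.correlation_result(x)

#' Tidy a permutation correlation test
#'
#' @param x A `perm_cor_test` from [permutation_correlation_test()].
#' @param ... Unused.
#' @return `tidy()`: the per-area tibble; `glance()`: the one-row
#'   family-level tibble.
#' @export
tidy.perm_cor_test <- function(x, ...) x$areas

#' @rdname tidy.perm_cor_test
#' @export
glance.perm_cor_test <- function(x, ...) {
  dplyr::bind_cols(x$family,
                   tibble(n = x$n, n_permutations = x$n_permutations))
}

#' Comodulogram heat map
#'
#' @param object A `comodulogram` tibble from [comodulogram()].
#' @param ... Unused.
#' @return A ggplot object: phase-band center on x, amplitude-band center on
#'   y, tiles filled by SI.
#' @export
autoplot.comodulogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$phase_center),
                                       y = factor(.data$amp_center),
                                       fill = .data$si)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "SI") +
    ggplot2::labs(x = "Frequency for phase (Hz, band center)",
                  y = "Frequency for amplitude (Hz, band center)") +
    ggplot2::theme_minimal()
}

#' Surrogate null distribution plot
#'
#' @param object A `surrogate_result`.
#' @param ... Unused.
#' @return A ggplot: histogram of surrogate SI with the observed SI marked.
#' @export
autoplot.surrogate_result <- function(object, ...) {
  df <- tibble(si = object$surrogate_si)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$si)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$si, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(x = "Synchronization index", y = "Surrogate count",
                  subtitle = sprintf("observed SI = %.3f, p = %.3g",
                                     object$si, object$p)) +
    ggplot2::theme_minimal()
}

#' Parcel statistic map plot
#'
#' Bar chart of a per-parcel statistic table (t or F map), colored by
#' significance — a light-weight stand-in for a cortical surface map.
#'
#' @param stats_tab Tibble with `parcel`, a statistic column and
#'   `significant`.
#' @param statistic Name of the statistic column (default `"t"`).
#' @return A ggplot object.
#' @export
plot_stat_map <- function(stats_tab, statistic = "t") {
  stopifnot(statistic %in% names(stats_tab))
  ggplot2::ggplot(stats_tab,
                  ggplot2::aes(x = .data$parcel,
                               y = .data[[statistic]],
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = "significant") +
    ggplot2::labs(x = "Parcel", y = statistic) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
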