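#' Akinesia score from motor-exam item scores
#'
#' The akinesia score is the sum of MDS-UPDRS part III items 3.4 (finger
#' tapping), 3.5 (hand movements), 3.6 (pronation-supination movements of
#' hands), 3.7 (toe tapping) and 3.8 (leg agility). Items scored per side
#' may appear as e.g. `"3.4L"`/`"3.4R"`; every entry whose name starts with
#' one of the five item families is summed.
#'
#' @param items Named numeric vector (or one-row list) of non-negative
#'   integer sub-scores; names start with `"3.4"` ... `"3.8"`.
#' @return Integer sum.
#' @examples
#' akinesia_score(c(`3.4L` = 2, `3.4R` = 1, `3.5L` = 1, `3.5R` = 1,
#'                  `3.6L` = 0, `3.6R` = 1, `3.7L` = 2, `3.7R` = 1,
#'                  `3.8L` = 1, `3.8R` = 0))
#' @export
akinesia_score <- function(items) {
  items <- unlist(items)
  if (is.null(names(items)) || any(names(items) == "")) {
    abort("`items` must be named by MDS-UPDRS item (3.4 ... 3.8)",
          class = "megpac_error_schema")
  }
  if (any(items < 0) || any(items != round(items))) {
    abort("item scores must be non-negative integers",
          class = "megpac_error_schema")
  }
  fams <- c("3.4", "3.5", "3.6", "3.7", "3.8")
  total <- 0L
  for (f in fams) {
    hit <- startsWith(names(items), f)
    if (!any(hit)) {
      abort(sprintf("missing MDS-UPDRS item %s", f),
            class = "megpac_error_schema")
    }
    total <- total + sum(items[hit])
  }
  as.integer(total)
}

#' Pearson correlation of a parcel metric with clinical scores
#'
#' Pairs a per-patient metric (e.g. area-averaged SI or power Z) with the
#' akinesia score and returns the Pearson r with its two-sided parametric
#' p-value (t transform, via [stats::cor.test()]).
#'
#' @param metric,scores Equal-length numeric vectors paired by participant.
#' @return An object of class `correlation_result`: list with `r`,
#'   `p_parametric`, `n`, `conf_low`, `conf_high` (and `p_permutation`,
#'   `n_permutations`, `seed` when produced by a permutation test). Has
#'   [tidy()]/[glance()] methods.
#' @export
correlate_metric <- function(metric, scores) {
  keep <- complete.cases(metric, scores)
  metric <- metric[keep]; scores <- scores[keep]
  n <- length(metric)
  if (n < 3L) abort("need at least 3 paired observations",
                    class = "megpac_error_schema")
  if (sd(metric) == 0 || sd(scores) == 0) {
    abort("zero variance: correlation undefined", class = "megpac_error_numeric")
  }
  ct <- suppressWarnings(cor.test(metric, scores, method = "pearson"))
  structure(list(r = unname(ct$estimate), p_parametric = ct$p.value,
                 n = n,
                 conf_low = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
                 conf_high = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, n = %d, parametric p = %.4g",
              x$r, x$n, x$p_parametric))
  if (!is.null(x$p_permutation)) {
    cat(sprintf(", permutation p = %.4g (%d permutations)",
                x$p_permutation, x$n_permutations))
  }
  cat("\n")
  invisible(x)
}

#' Permutation test of metric-score correlations across areas
#'
#' For each area (column of `metrics`) the observed Pearson r against
#' `scores` is computed. The null is built by permuting the participant
#' order of the metric rows (scores kept fixed; rows move together so the
#' across-area correlation structure is preserved), `n_perm` times
#' (default 2000). Two results are reported:
#' \itemize{
#'   \item per area: permutation `p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_perm)`;
#'   \item family level: the observed count of areas with parametric
#'     `p < alpha` compared against the permutation null distribution of
#'     that count (are there more significant correlations than chance
#'     would produce?).
#' }
#'
#' @param metrics Patients x areas numeric matrix (or data frame).
#' @param scores Per-patient score vector (length `nrow(metrics)`).
#' @param n_perm Number of permutations (>= 100, default 2000).
#' @param alpha Parametric threshold defining a "significant" correlation in
#'   the family count (default 0.05).
#' @param seed RNG seed.
#' @return A list of class `perm_cor_test`: `areas` (tibble: area, r,
#'   p_parametric, p_permutation), `family` (tibble: n_significant,
#'   expected_null, p), `n_permutations`, `seed`.
#' @export
permutation_correlation_test <- function(metrics, scores, n_perm = 2000,
                                         alpha = 0.05, seed = 1L) {
  metrics <- as_parcel_matrix(metrics)
  if (n_perm < 100) abort("n_perm must be >= 100", class = "megpac_error_config")
  if (length(scores) != nrow(metrics)) {
    abort("scores length must match metric rows", class = "megpac_error_schema")
  }
  keep <- complete.cases(metrics) & !is.na(scores)
  metrics <- metrics[keep, , drop = FALSE]; scores <- scores[keep]
  n <- nrow(metrics)
  if (n < 3L) abort("need at least 3 complete participants",
                    class = "megpac_error_schema")
  areas <- colnames(metrics)
  if (is.null(areas)) areas <- sprintf("A%03d", seq_len(ncol(metrics)))
  r_obs <- as.vector(cor(metrics, scores))
  p_par <- cor_p_two_sided(r_obs, n)
  crit_r <- critical_r(alpha, n)
  perm <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      as.vector(cor(metrics[sample.int(n), , drop = FALSE], scores))
    }, numeric(ncol(metrics)))
  })
  perm <- matrix(perm, nrow = ncol(metrics))  # areas x n_perm
  p_perm <- vapply(seq_len(ncol(metrics)), function(j) {
    (1 + sum(abs(perm[j, ]) >= abs(r_obs[j]))) / (1 + n_perm)
  }, numeric(1))
  n_sig_obs <- sum(abs(r_obs) >= crit_r)
  n_sig_null <- colSums(abs(perm) >= crit_r)
  fam_p <- (1 + sum(n_sig_null >= n_sig_obs)) / (1 + n_perm)
  structure(list(
    areas = tibble(area = areas, r = r_obs, p_parametric = p_par,
                   p_permutation = p_perm),
    family = tibble(n_significant = n_sig_obs,
                    expected_null = mean(n_sig_null), p = fam_p),
    n_permutations = as.integer(n_perm), n = n, seed = seed),
    class = "perm_cor_test")
}

# Two-sided parametric p for Pearson r at sample size n (t transform).
cor_p_two_sided <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

# |r| threshold for two-sided parametric significance at level alpha.
critical_r <- function(alpha, n) {
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' @export
print.perm_cor_test <- function(x, ...) {
  cat(sprintf("<perm_cor_test> %d areas, n = %d, %d permutations\n",
              nrow(x$areas), x$n, x$n_permutations))
  cat(sprintf("  family: %d significant (null mean %.2f), p = %.4g\n",
              x$family$n_significant, x$family$expected_null, x$family$p))
  print(x$areas)
  invisible(x)
}

#' A-priori sample size for a correlation test
#'
#' Fisher-z approximation for detecting a population Pearson correlation
#' `rho` at significance `alpha` with the given power:
#' `n0 = ceil(((z_{1-alpha/tails} + z_{power}) / atanh(rho))^2 + 3)`,
#' inflated for an expected dropout fraction as `ceil(n0 / (1 - dropout))`.
#'
#' @param rho Population correlation to detect, in (0, 1).
#' @param alpha Type-I error probability (default 0.05).
#' @param power Target power (default 0.8).
#' @param tail `"two"` (default) or `"one"`.
#' @param dropout Expected dropout fraction in `[0, 1)` (default 0).
#' @return A list: `n` (inflated), `n0` (before inflation).
#' @examples
#' required_sample_size(0.6, 0.05, 0.8)  # n0 = 20
#' @export
required_sample_size <- function(rho, alpha = 0.05, power = 0.8,
                                 tail = c("two", "one"), dropout = 0) {
  tail <- match.arg(tail)
  if (rho <= 0 || rho >= 1) abort("rho must lie in (0, 1)",
                                  class = "megpac_error_config")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("alpha and power must lie in (0, 1)", class = "megpac_error_config")
  }
  if (dropout < 0 || dropout >= 1) abort("dropout must lie in [0, 1)",
                                         class = "megpac_error_config")
  za <- qnorm(1 - alpha / ifelse(tail == "two", 2, 1))
  zb <- qnorm(power)
  n0 <- ceiling(((za + zb) / atanh(rho))^2 + 3)
  list(n = as.integer(ceiling(n0 / (1 - dropout))), n0 = as.integer(n0))
}
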