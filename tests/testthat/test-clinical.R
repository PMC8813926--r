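test_that("akinesia score sums the five item families and names the missing one", {
  items <- c(`3.4L` = 2, `3.4R` = 1, `3.5L` = 1, `3.5R` = 1, `3.6L` = 0,
             `3.6R` = 1, `3.7L` = 2, `3.7R` = 1, `3.8L` = 1, `3.8R` = 0)
  expect_equal(akinesia_score(items), 10L)
  expect_equal(akinesia_score(c(`3.4` = 0, `3.5` = 0, `3.6` = 0, `3.7` = 0,
                                `3.8` = 0)), 0L)
  # the printed maximum patient score is attainable
  expect_equal(akinesia_score(c(`3.4` = 5, `3.5` = 4, `3.6` = 4, `3.7` = 4,
                                `3.8` = 4)), 21L)
  expect_error(akinesia_score(items[!startsWith(names(items), "3.7")]),
               regexp = "3\\.7", class = "megpac_error_schema")
  expect_error(akinesia_score(c(`3.4` = -1, `3.5` = 0, `3.6` = 0, `3.7` = 0,
                                `3.8` = 0)), class = "megpac_error_schema")
})

test_that("Pearson correlation has the trivial endpoints and affine invariance", {
  s <- c(3, 8, 1, 12, 7, 5, 9)
  expect_equal(correlate_metric(s, s)$r, 1)
  expect_equal(correlate_metric(-s, s)$r, -1)
  # affine invariance (positive slope) on a fixed vector
  set.seed(1); m <- s + rnorm(7)
  expect_equal(correlate_metric(3 * m + 5, s)$r, correlate_metric(m, s)$r,
               tolerance = 1e-12)
  expect_error(correlate_metric(rep(1, 7), s), class = "megpac_error_numeric")
  expect_error(correlate_metric(1:2, 1:2), class = "megpac_error_schema")
})

test_that("permutation p is minimal for a self-correlated single area", {
  s <- rnorm(23)
  out <- permutation_correlation_test(matrix(s, ncol = 1), s, n_perm = 200,
                                      seed = 1)
  expect_equal(out$areas$p_permutation, 1 / 201)
  expect_equal(out$areas$r, 1)
})

test_that("permutation and parametric p-values rank areas the same way", {
  set.seed(11)
  n <- 23; n_areas <- 25
  scores <- rnorm(n)
  metrics <- sapply(seq_len(n_areas), function(j) {
    w <- (j - 1) / (n_areas - 1)
    w * scores + sqrt(1 - w^2) * rnorm(n)
  })
  out <- permutation_correlation_test(metrics, scores, n_perm = 500, seed = 2)
  expect_gte(cor(out$areas$p_parametric, out$areas$p_permutation,
                 method = "spearman"), 0.9)
})

test_that("the family count test detects an excess of linked areas", {
  # Note the count statistic is inherently weak for a single linked area
  # (under the null, P(at least one of six areas is significant) is about
  # 0.26), so power is tested with several linked areas among nulls, and
  # the per-area permutation p is checked for the single-area case.
  hits <- vapply(1:10, function(s) {
    set.seed(600 + s)
    n <- 23
    scores <- rnorm(n)
    metrics <- cbind(sapply(1:4, function(j)
      0.8 * scores + sqrt(1 - 0.8^2) * rnorm(n)),
      matrix(rnorm(n * 6), n, 6))
    out <- permutation_correlation_test(metrics, scores, n_perm = 300,
                                        seed = s)
    out$family$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # a single strongly linked area is caught by its per-area permutation p
  per_area <- vapply(1:10, function(s) {
    set.seed(700 + s)
    n <- 23
    scores <- rnorm(n)
    metrics <- cbind(0.85 * scores + sqrt(1 - 0.85^2) * rnorm(n),
                     matrix(rnorm(n * 5), n, 5))
    out <- permutation_correlation_test(metrics, scores, n_perm = 300,
                                        seed = s)
    out$areas$p_permutation[1] < 0.05
  }, logical(1))
  expect_gte(mean(per_area), 0.9)
})

test_that("required sample size matches the Fisher-z closed form", {
  res <- required_sample_size(0.6, 0.05, 0.8, tail = "two", dropout = 0)
  expect_equal(res$n0, 20L)
  expect_equal(res$n, 20L)
  # dropout inflation
  expect_equal(required_sample_size(0.6, dropout = 0.5)$n, 40L)
  expect_equal(required_sample_size(0.6, dropout = 0.3)$n, 29L)
  # monotone in power
  ns <- vapply(c(0.8, 0.9, 0.99), function(p)
    required_sample_size(0.6, power = p)$n0, integer(1))
  expect_true(all(diff(ns) > 0))
  expect_error(required_sample_size(0), class = "megpac_error_config")
})

test_that("the Fisher-z n delivers its nominal power (Monte-Carlo oracle)", {
  # exact-power check by simulation at n0 = 20, rho = 0.6
  set.seed(12)
  n <- 20
  rej <- vapply(1:2000, function(i) {
    x <- rnorm(n)
    y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
    cor.test(x, y)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.75)
})
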