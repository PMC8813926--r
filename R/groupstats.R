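#' Parcel adjacency graph
#'
#' Undirected parcel adjacency used to define clusters in
#' [cluster_permutation_F()]. Built from an edge table; validated to be
#' symmetric with no self-loops.
#'
#' @param parcel_ids Character vector of parcel identifiers.
#' @param edges Two-column data frame or matrix of parcel-ID pairs.
#' @return An object of class `parcel_graph` wrapping an igraph graph.
#' @export
parcel_graph <- function(parcel_ids, edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) abort("`edges` must have two columns",
                               class = "megpac_error_schema")
  if (any(edges[, 1] == edges[, 2])) {
    abort("self-loops are not allowed", class = "megpac_error_schema")
  }
  if (!all(edges %in% parcel_ids)) {
    abort("edge references unknown parcel", class = "megpac_error_schema")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = parcel_ids))
  g <- igraph::simplify(g)
  structure(list(graph = g, parcel_ids = as.character(parcel_ids)),
            class = "parcel_graph")
}

#' Grid-shaped synthetic parcellation
#'
#' A rows x cols lattice of parcels with 4-neighbor adjacency — the default
#' synthetic stand-in for a cortical parcellation (use 18 x 20 for a
#' 360-area scheme).
#'
#' @param rows,cols Lattice dimensions.
#' @return A list with `parcel_ids` and a `parcel_graph` in `$graph`.
#' @export
grid_parcellation <- function(rows = 6, cols = 10) {
  n <- rows * cols
  ids <- sprintf("P%03d", seq_len(n))
  idx <- function(r, c) (r - 1L) * cols + c
  e <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) e[[length(e) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
    if (r < rows) e[[length(e) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
  }
  em <- do.call(rbind, e)
  pg <- parcel_graph(ids, cbind(ids[em[, 1]], ids[em[, 2]]))
  list(parcel_ids = ids, graph = pg)
}

as_parcel_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.matrix(x), is.numeric(x))
  x
}

#' Paired t map: SI versus surrogate-mean SI
#'
#' For each parcel, a paired t statistic on the per-participant differences
#' `d_i = si_i - surrogate_mean_i` (`t = mean(d) / (sd(d)/sqrt(n))`,
#' `df = n - 1`), testing whether observed coupling exceeds its surrogate
#' null within a group.
#'
#' @param si,surr_mean Participants x parcels numeric matrices (equal
#'   dimensions, parcels in columns).
#' @return A tibble: `parcel`, `t`, `df`, `p_uncorrected` (two-sided
#'   parametric), `degenerate` (TRUE where `sd(d) == 0`, t is `NA` there).
#' @export
paired_t_vs_surrogate <- function(si, surr_mean) {
  si <- as_parcel_matrix(si); surr_mean <- as_parcel_matrix(surr_mean)
  if (!all(dim(si) == dim(surr_mean))) {
    abort("si and surr_mean dimensions differ", class = "megpac_error_schema")
  }
  if (nrow(si) < 2L) abort("need at least 2 participants",
                           class = "megpac_error_schema")
  d <- si - surr_mean
  tt <- t_map(d)
  parcels <- colnames(si)
  if (is.null(parcels)) parcels <- sprintf("P%03d", seq_len(ncol(si)))
  tibble(parcel = parcels, t = tt, df = nrow(d) - 1,
         p_uncorrected = 2 * pt(-abs(tt), df = nrow(d) - 1),
         degenerate = !is.finite(tt))
}

# Column-wise one-sample t statistics of a participants x parcels matrix.
t_map <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2, m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0] <- NA_real_
  t
}

#' Permutation-FDR correction of a paired t map
#'
#' Builds the permutation null by randomly sign-flipping each participant's
#' difference vector (`n_perm` times), recomputing the parcel t map each
#' time. Per-parcel permutation p-values compare `|t_obs|` with the null
#' `|t|` values — pooled across parcels and permutations by default (set
#' `pool = FALSE` for per-parcel nulls) — and Benjamini-Hochberg correction
#' is applied across parcels (and any band combinations included as columns).
#'
#' @param d Participants x parcels matrix of differences
#'   (si - surrogate_mean).
#' @param n_perm Number of sign-flip permutations (>= 100, default 1000).
#' @param seed RNG seed.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param pool Pool null t values across parcels (default TRUE).
#' @return A tibble: `parcel`, `t`, `p_uncorrected` (permutation p),
#'   `p_corrected` (BH), `significant`.
#' @export
permutation_fdr <- function(d, n_perm = 1000, seed = 1L, alpha = 0.05,
                            pool = TRUE) {
  d <- as_parcel_matrix(d)
  if (nrow(d) < 2L) abort("need at least 2 participants",
                          class = "megpac_error_schema")
  if (n_perm < 100) abort("n_perm must be >= 100", class = "megpac_error_config")
  n <- nrow(d); np <- ncol(d)
  t_obs <- t_map(d)
  t_null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      t_map(d * signs)
    }, numeric(np))
  })
  t_null <- matrix(t_null, nrow = np)  # parcels x n_perm
  abs_obs <- abs(t_obs)
  if (pool) {
    pooled <- abs(as.vector(t_null))
    pooled <- pooled[is.finite(pooled)]
    p_unc <- vapply(abs_obs, function(a) {
      (1 + sum(pooled >= a)) / (1 + length(pooled))
    }, numeric(1))
  } else {
    p_unc <- vapply(seq_len(np), function(j) {
      nullj <- abs(t_null[j, ]); nullj <- nullj[is.finite(nullj)]
      (1 + sum(nullj >= abs_obs[j])) / (1 + length(nullj))
    }, numeric(1))
  }
  p_unc[!is.finite(t_obs)] <- NA_real_
  p_corr <- p.adjust(p_unc, method = "BH")
  parcels <- colnames(d)
  if (is.null(parcels)) parcels <- sprintf("P%03d", seq_len(np))
  tibble(parcel = parcels, t = t_obs, p_uncorrected = p_unc,
         p_corrected = p_corr,
         significant = !is.na(p_corr) & p_corr < alpha)
}

# Per-parcel one-way F statistics for two groups (columns = parcels).
f_map <- function(a, b) {
  na <- nrow(a); nb <- nrow(b); n <- na + nb
  ma <- colMeans(a); mb <- colMeans(b)
  gm <- (na * ma + nb * mb) / n
  ssb <- na * (ma - gm)^2 + nb * (mb - gm)^2
  ssw <- colSums(sweep(a, 2, ma)^2) + colSums(sweep(b, 2, mb)^2)
  (ssb / 1) / (ssw / (n - 2))
}

#' Cluster-based permutation F test between groups
#'
#' Per parcel, a one-way F statistic (two groups) is computed; parcels with
#' parametric `p < cluster_alpha` are joined into connected components on
#' the parcel adjacency graph; each cluster's mass is the sum of its F
#' values. The null distribution of the maximum cluster mass is built by
#' permuting group labels `n_perm` times, and each observed cluster gets
#' `p = (1 + #\{max null mass >= mass\}) / (1 + n_perm)` (two-group F is
#' direction-free, so the test is inherently two-sided).
#'
#' @param group_a,group_b Subjects x parcels matrices (same columns).
#' @param graph A [parcel_graph()] covering all columns.
#' @param n_perm Label permutations (default 1000).
#' @param cluster_alpha Cluster-forming (parcel-level parametric) threshold
#'   (default 0.05).
#' @param alpha Cluster-level significance threshold (default 0.05).
#' @param seed RNG seed.
#' @return A tibble with one row per parcel: `parcel`, `F`, `p_parametric`,
#'   `cluster_id` (`NA` outside clusters), `cluster_mass`, `cluster_p`,
#'   `significant`. Cluster-level summary in `attr(, "clusters")`.
#' @export
cluster_permutation_F <- function(group_a, group_b, graph, n_perm = 1000,
                                  cluster_alpha = 0.05, alpha = 0.05,
                                  seed = 1L) {
  a <- as_parcel_matrix(group_a); b <- as_parcel_matrix(group_b)
  if (ncol(a) != ncol(b)) abort("groups have different parcel sets",
                                class = "megpac_error_schema")
  if (nrow(a) < 2L || nrow(b) < 2L) {
    abort("both groups need >= 2 subjects", class = "megpac_error_schema")
  }
  stopifnot(inherits(graph, "parcel_graph"))
  parcels <- colnames(a)
  if (is.null(parcels)) parcels <- sprintf("P%03d", seq_len(ncol(a)))
  if (!all(parcels %in% graph$parcel_ids)) {
    abort("graph does not cover all parcels", class = "megpac_error_schema")
  }
  na <- nrow(a); nb <- nrow(b)
  pooled <- rbind(a, b)
  df2 <- na + nb - 2
  f_thresh <- stats::qf(1 - cluster_alpha, 1, df2)

  clusters_of <- function(fv) {
    supra <- which(fv > f_thresh)
    if (length(supra) == 0L) return(list())
    sub <- igraph::induced_subgraph(graph$graph, parcels[supra])
    comp <- igraph::components(sub)
    lapply(seq_len(comp$no), function(k) {
      members <- names(comp$membership)[comp$membership == k]
      j <- match(members, parcels)
      list(members = members, idx = j, mass = sum(fv[j]))
    })
  }

  f_obs <- f_map(a, b)
  obs_clusters <- clusters_of(f_obs)
  null_max <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(na + nb, na)
      fv <- f_map(pooled[ia, , drop = FALSE], pooled[-ia, , drop = FALSE])
      cl <- clusters_of(fv)
      if (length(cl) == 0L) 0 else max(vapply(cl, `[[`, numeric(1), "mass"))
    }, numeric(1))
  })
  cluster_id <- rep(NA_integer_, length(parcels))
  cluster_mass <- rep(NA_real_, length(parcels))
  cluster_p <- rep(NA_real_, length(parcels))
  cl_summary <- tibble(cluster_id = integer(0), n_parcels = integer(0),
                       mass = numeric(0), p = numeric(0))
  if (length(obs_clusters) > 0L) {
    ord <- order(vapply(obs_clusters, `[[`, numeric(1), "mass"),
                 decreasing = TRUE)
    for (k in seq_along(ord)) {
      cl <- obs_clusters[[ord[k]]]
      pk <- (1 + sum(null_max >= cl$mass)) / (1 + n_perm)
      cluster_id[cl$idx] <- k
      cluster_mass[cl$idx] <- cl$mass
      cluster_p[cl$idx] <- pk
      cl_summary <- bind_rows(cl_summary,
                              tibble(cluster_id = k,
                                     n_parcels = length(cl$idx),
                                     mass = cl$mass, p = pk))
    }
  }
  out <- tibble(parcel = parcels, F = f_obs,
                p_parametric = stats::pf(f_obs, 1, df2, lower.tail = FALSE),
                cluster_id = cluster_id, cluster_mass = cluster_mass,
                cluster_p = cluster_p,
                significant = !is.na(cluster_p) & cluster_p < alpha)
  attr(out, "clusters") <- cl_summary
  attr(out, "null_max_mass") <- null_max
  out
}
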