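#' Read / write a recording HDF5 container
#'
#' Layout: dataset `/data` (parcels x samples, float) with attributes
#' `fs_hz`, `participant_id`, `group`; dataset `/clean_segments` (n x 2
#' integer, 0-based half-open sample intervals); dataset `/parcels`
#' (character parcel IDs). The round trip is lossless. Requires the
#' suggested package `rhdf5`.
#'
#' @param rec A [recording()].
#' @param path File path.
#' @return `read_recording()` returns a [recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  require_rhdf5()
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$data, path, "data")
  rhdf5::h5write(rec$clean_segments, path, "clean_segments")
  rhdf5::h5write(rec$parcel_ids, path, "parcels")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "data")
  rhdf5::h5writeAttribute(rec$fs_hz, did, "fs_hz")
  rhdf5::h5writeAttribute(rec$participant_id, did, "participant_id")
  rhdf5::h5writeAttribute(rec$group, did, "group")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  require_rhdf5()
  if (!file.exists(path)) abort(sprintf("no such file: %s", path),
                                class = "megpac_error_schema")
  contents <- rhdf5::h5ls(path)$name
  for (need in c("data", "clean_segments", "parcels")) {
    if (!need %in% contents) {
      abort(sprintf("recording container missing dataset '%s'", need),
            class = "megpac_error_schema")
    }
  }
  dat <- rhdf5::h5read(path, "data")
  at <- rhdf5::h5readAttributes(path, "data")
  for (need in c("fs_hz", "participant_id", "group")) {
    if (is.null(at[[need]])) {
      abort(sprintf("recording container missing attribute '%s'", need),
            class = "megpac_error_schema")
    }
  }
  seg <- rhdf5::h5read(path, "clean_segments")
  recording(matrix(as.numeric(dat), nrow = nrow(dat)),
            fs_hz = as.numeric(at$fs_hz),
            participant_id = as.character(at$participant_id),
            group = as.character(at$group),
            clean_segments = matrix(as.integer(seg), ncol = 2L),
            parcel_ids = as.character(rhdf5::h5read(path, "parcels")))
}

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    abort("package 'rhdf5' is required for HDF5 recording containers",
          class = "megpac_error_schema")
  }
}

#' Read a cohort table CSV
#'
#' Expected columns: `id`, `sex` (M/F or Male/Female), `age_years`,
#' `affected_side` (Left/Right), `akinesia_score`, `state` (On/Off),
#' `ledd_mg`, `duration_years`, optional `group` (patient/control; defaults
#' to patient). Validated: unique ids, known sex/state tokens, positive
#' ages, non-negative akinesia scores.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("id", "sex", "age_years", "affected_side", "akinesia_score",
            "state", "ledd_mg", "duration_years")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort table missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "megpac_error_schema")
  }
  if (anyDuplicated(tab$id)) {
    abort("duplicate participant ID in cohort table",
          class = "megpac_error_schema")
  }
  sex_map <- c(M = "M", Male = "M", F = "F", Female = "F")
  if (!all(tab$sex %in% names(sex_map))) {
    abort("unknown sex token (expected M/F/Male/Female)",
          class = "megpac_error_schema")
  }
  tab$sex <- unname(sex_map[tab$sex])
  if (!all(tab$state %in% c("On", "Off"))) {
    abort("unknown medication-state token (expected On/Off)",
          class = "megpac_error_schema")
  }
  if (any(tab$age_years <= 0)) abort("ages must be positive",
                                     class = "megpac_error_schema")
  if (any(tab$akinesia_score < 0, na.rm = TRUE)) {
    abort("akinesia scores must be >= 0", class = "megpac_error_schema")
  }
  if (!"group" %in% names(tab)) tab$group <- "patient"
  if (!all(tab$group %in% c("patient", "control"))) {
    abort("group must be patient or control", class = "megpac_error_schema")
  }
  tab$id <- as.character(tab$id)
  as_tibble(tab)
}

#' Read a parcel table with adjacency
#'
#' TSV with columns `parcel_id`, optional `name` and `hemisphere`, and
#' `neighbors` (comma-separated parcel IDs; empty for isolated parcels).
#' Adjacency must be symmetric and self-loop-free.
#'
#' @param path TSV file path.
#' @return A list: `parcels` (tibble) and `graph` (a [parcel_graph()]).
#' @export
read_parcels <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("parcel_id", "neighbors") %in% names(tab))) {
    abort("parcel table needs columns parcel_id and neighbors",
          class = "megpac_error_schema")
  }
  if (anyDuplicated(tab$parcel_id)) {
    abort("duplicate parcel_id", class = "megpac_error_schema")
  }
  adj <- lapply(tab$neighbors, function(s) {
    if (is.na(s) || s == "") character(0)
    else trimws(strsplit(s, ",")[[1]])
  })
  names(adj) <- tab$parcel_id
  edges <- list()
  for (p in names(adj)) {
    for (q in adj[[p]]) {
      if (!q %in% tab$parcel_id) {
        abort(sprintf("neighbor '%s' of '%s' is not a parcel", q, p),
              class = "megpac_error_schema")
      }
      if (!p %in% adj[[q]]) {
        abort(sprintf("asymmetric adjacency: %s lists %s but not vice versa",
                      p, q),
              class = "megpac_error_schema")
      }
      edges[[length(edges) + 1L]] <- c(p, q)
    }
  }
  g <- parcel_graph(tab$parcel_id,
                    if (length(edges) > 0) do.call(rbind, edges)
                    else matrix(character(0), ncol = 2L))
  list(parcels = as_tibble(tab), graph = g)
}

#' Run the full resting-state PAC pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> preprocess -> band power -> PAC (SI +
#' surrogates) -> group statistics (within-group permutation FDR on the
#' patient SI map; between-group cluster permutation F) -> clinical
#' correlation (area-averaged SI versus akinesia, permutation-tested), and
#' returns a machine-readable report. Every random draw derives from
#' `seed`; rerunning with the same configuration reproduces the report
#' exactly.
#'
#' @param spec A [cohort_spec()].
#' @param sim A [sim_config()].
#' @param n_surr Surrogates per SI value (default 1000).
#' @param n_perm Permutations for group and correlation tests (default
#'   2000 for the correlation test, and also used for the FDR/cluster
#'   permutations).
#' @param seed Master seed (overrides the seeds in `spec`/`sim`).
#' @param out Optional path for a JSON report.
#' @return The report (a nested list), invisibly written to `out` as JSON if
#'   given.
#' @export
run_pipeline <- function(spec = cohort_spec(), sim = sim_config(),
                         n_surr = 1000, n_perm = 2000, seed = 1L,
                         out = NULL) {
  seeds <- derive_seeds(seed, 5L)
  spec$seed <- seeds[1]
  cohort_data <- simulate_cohort(spec, sim)
  report <- list(config = list(
    seed = seed, n_surrogates = n_surr, n_permutations = n_perm,
    n_patients = spec$n_patients, n_controls = spec$n_controls,
    fs_hz = sim$fs_hz, duration_s = sim$duration_s,
    n_parcels = sim$n_parcels,
    phase_band = c(sim$phase_band$low_hz, sim$phase_band$high_hz),
    amp_band = c(sim$amp_band$low_hz, sim$amp_band$high_hz)))
  report$simulate <- list(
    n_recordings = length(cohort_data$recordings),
    coupled_parcels = sim$coupled_parcels,
    mean_patient_depth = mean(cohort_data$cohort$coupling_depth[
      cohort_data$cohort$group == "patient"]))

  recs <- lapply(cohort_data$recordings, preprocess,
                 target_hz = min(500, sim$fs_hz))
  report$preprocess <- list(
    discarded_windows = sum(vapply(recs, function(r)
      nrow(attr(r, "discarded_segments")), numeric(1))),
    clean_seconds = vapply(recs, function(r)
      sum(r$clean_segments[, 2] - r$clean_segments[, 1]) / r$fs_hz,
      numeric(1)))

  bands <- canonical_bands()
  power_tabs <- lapply(recs, function(r) {
    bind_rows(lapply(bands, function(b) band_power(r, b))) |> zscore_parcels()
  })
  power_tab <- bind_rows(power_tabs)
  report$power <- list(n_rows = nrow(power_tab),
                       bands = names(bands))

  pac_seeds <- derive_seeds(seeds[2], length(recs))
  pac_tab <- bind_rows(lapply(seq_along(recs), function(i) {
    pac_parcels(recs[[i]], sim$phase_band, sim$amp_band,
                n_surr = n_surr, seed = pac_seeds[i])
  }))
  report$pac <- list(n_rows = nrow(pac_tab),
                     mean_si = mean(pac_tab$si))

  groups <- cohort_data$cohort$group[match(unique(pac_tab$participant),
                                           cohort_data$cohort$id)]
  si_mat <- metric_matrix(pac_tab, "si")
  surr_mat <- metric_matrix(pac_tab, "surrogate_mean")
  pat <- groups == "patient"
  fdr <- permutation_fdr(si_mat[pat, , drop = FALSE] -
                           surr_mat[pat, , drop = FALSE],
                         n_perm = max(100, n_perm), seed = seeds[3])
  pg <- grid_parcellation(1, sim$n_parcels)
  colnames(si_mat) <- pg$parcel_ids[seq_len(ncol(si_mat))]
  clus <- cluster_permutation_F(si_mat[pat, , drop = FALSE],
                                si_mat[!pat, , drop = FALSE],
                                pg$graph, n_perm = max(100, n_perm),
                                seed = seeds[4])
  report$groupstats <- list(
    n_significant_parcels = sum(fdr$significant),
    significant_parcels = fdr$parcel[fdr$significant],
    n_clusters = nrow(attr(clus, "clusters")),
    min_cluster_p = if (nrow(attr(clus, "clusters")) > 0)
      min(attr(clus, "clusters")$p) else NA)

  sig_idx <- which(fdr$significant)
  if (length(sig_idx) == 0) sig_idx <- sim$coupled_parcels
  pat_si <- si_mat[pat, , drop = FALSE]
  metric <- rowMeans(pat_si[, sig_idx, drop = FALSE])
  scores <- cohort_data$cohort$akinesia_score[match(rownames(si_mat)[pat],
                                                    cohort_data$cohort$id)]
  cr <- correlate_metric(metric, scores)
  pt_ <- permutation_correlation_test(pat_si, scores, n_perm = n_perm,
                                      seed = seeds[5])
  report$correlate <- list(
    area_averaged = list(r = cr$r, p_parametric = cr$p_parametric, n = cr$n),
    family = as.list(pt_$family),
    areas_used = length(sig_idx))

  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}

# participants x parcels matrix from a long PAC table.
metric_matrix <- function(tab, col) {
  wide <- tab |>
    select("participant", "parcel", dplyr::all_of(col)) |>
    tidyr::pivot_wider(names_from = "parcel", values_from = dplyr::all_of(col))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$participant
  m
}
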