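#' Simulate all raw inputs for one synthetic patient
#'
#' Runs the full generator chain: electrode geometry, boundary mask, contact
#' areas, planted truth networks, streamline counts consistent with the
#' structural truth, and a SPES recording consistent with the effective
#' truth.
#'
#' @param config A [sim_config()].
#' @param fp_rate False-positive rate for the streamline counts.
#' @return A list of class `synthetic_patient`: `config`, `electrodes`,
#'   `mask`, `areas`, `truth`, `counts`, `recording`.
#' @export
simulate_patient <- function(config, fp_rate = 0) {
  electrodes <- simulate_electrodes(config)
  mask <- simulate_boundary_mask(electrodes, config)
  areas <- build_contact_areas(electrodes, mask)
  truth <- simulate_truth_networks(config, electrodes)
  counts <- simulate_streamline_counts(truth, areas, fp_rate = fp_rate,
                                       seed = config$seed + 4L)
  recording <- simulate_spes_recording(truth, electrodes, config)
  structure(list(config = config, electrodes = electrodes, mask = mask,
                 areas = areas, truth = truth, counts = counts,
                 recording = recording),
            class = "synthetic_patient")
}

subset_network <- function(net, labels) {
  binary_network(unclass(net)[labels, labels, drop = FALSE])
}

#' Run the full single-patient analysis pipeline
#'
#' Contact areas on the boundary mask, streamline-density structural
#' network, CCEP-derived effective network, inter-modal similarity, and the
#' per-node metric table. Both networks are restricted to the common node
#' set (included contacts with a non-empty contact area). Intermediate
#' artifacts can be written to `out_dir` together with a provenance record
#' carrying the parameter hash.
#'
#' @param electrodes Electrode tibble (`label`, `x`, `y`, `z`, `included`,
#'   `soz`).
#' @param mask A [voxel_mask()].
#' @param recording A `spes_recording`.
#' @param counts Streamline count matrix; alternatively pass `streamlines`.
#' @param streamlines Optional list of streamline coordinate matrices,
#'   counted against the contact areas when `counts` is NULL.
#' @param patient Patient identifier.
#' @param density_threshold Streamline-density cutoff (0.1).
#' @param denominator VEA normalization for the density ([streamline_density()]).
#' @param B Permutations for the Jaccard significance test.
#' @param seed Integer seed (permutation test).
#' @param out_dir Optional output directory for intermediate artifacts.
#' @return A list of class `patient_result`: `areas`, `sc`, `ec`,
#'   `detections`, `similarity`, `nodes`.
#' @export
run_patient_pipeline <- function(electrodes, mask, recording,
                                 counts = NULL, streamlines = NULL,
                                 patient = "p01",
                                 density_threshold = 0.1,
                                 denominator = "sum",
                                 B = 10000, seed = 1L, out_dir = NULL) {
  areas <- build_contact_areas(electrodes, mask)
  if (is.null(counts)) {
    if (is.null(streamlines)) {
      stop("Provide either `counts` or `streamlines`.", call. = FALSE)
    }
    counts <- count_streamlines(streamlines, areas)
  }
  dens <- streamline_density(counts, areas, denominator = denominator)
  sc <- binarize_structural(dens, threshold = density_threshold)

  epochs <- epoch_trials(recording)
  epochs <- rereference_epochs(epochs)
  erps <- average_erp(epochs)
  detections <- detect_ccep(erps)
  included <- electrodes$label[electrodes$included]
  ec <- build_effective_network(detections, included)

  common <- intersect(rownames(sc), rownames(ec))
  if (length(common) < nrow(sc) || length(common) < nrow(ec)) {
    message(sprintf("Restricting to %d common nodes.", length(common)))
  }
  sc <- subset_network(sc, common)
  ec <- subset_network(ec, common)
  similarity <- compare_networks(sc, ec, B = B, seed = seed)
  nodes <- node_metrics(sc, ec, electrodes, areas = areas, patient = patient)

  res <- structure(list(patient = patient, areas = areas, sc = sc, ec = ec,
                        detections = detections, similarity = similarity,
                        nodes = nodes),
                   class = "patient_result")
  if (!is.null(out_dir)) write_patient_outputs(res, out_dir, list(
    patient = patient, density_threshold = density_threshold,
    denominator = denominator, B = B, seed = seed))
  res
}

write_patient_outputs <- function(res, out_dir, params) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    areas = file.path(out_dir, "contact_areas.tsv"),
    sc = file.path(out_dir, "structural_adjacency.tsv"),
    ec = file.path(out_dir, "effective_adjacency.tsv"),
    detections = file.path(out_dir, "ccep_detections.tsv"),
    similarity = file.path(out_dir, "similarity.json"),
    nodes = file.path(out_dir, "node_metrics.tsv")
  )
  write_tsv_lf(tibble::as_tibble(res$areas), files["areas"])
  write_adjacency_tsv(res$sc, files["sc"])
  write_adjacency_tsv(res$ec, files["ec"])
  write_tsv_lf(res$detections, files["detections"])
  write_similarity_json(res$similarity, files["similarity"])
  write_tsv_lf(res$nodes, files["nodes"])
  prov <- list(params = params, config_hash = rlang::hash(params),
               files = as.list(files))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Run a multi-patient synthetic study end-to-end
#'
#' Simulates a cohort of synthetic patients (a mix of ECoG grids and sEEG
#' shaft implants in roughly the 5:8 ratio of typical surgical cohorts),
#' runs each through the full pipeline, and fits the group-level models:
#' per-patient Spearman correlations with FDR correction, the intercept-only
#' multilevel model (ICC), and backward elimination over the candidate
#' predictors.
#'
#' @param config Template [sim_config()]; per-patient seeds and modalities
#'   are derived from it.
#' @param n_patients Number of synthetic patients.
#' @param B Permutations per patient for the Jaccard test.
#' @param fp_rate Streamline false-positive rate.
#' @return A list of class `study_result`: `patients` (per-patient
#'   `patient_result`s), `similarity` (one glance row per patient),
#'   `node_table`, `correlations`, `icc_fit`, `model`.
#' @export
run_synthetic_study <- function(config, n_patients = 13, B = 2000, fp_rate = 0) {
  n_ecog <- round(5 / 13 * n_patients)
  results <- purrr::map(seq_len(n_patients), function(p) {
    cfg <- config
    cfg$modality <- if (p <= n_ecog) "ECoG" else "sEEG"
    cfg$seed <- config$seed + 97L * p
    pat <- simulate_patient(cfg, fp_rate = fp_rate)
    run_patient_pipeline(pat$electrodes, pat$mask, pat$recording,
                         counts = pat$counts,
                         patient = sprintf("pt%02d", p),
                         B = B, seed = cfg$seed + 5L)
  })
  node_table <- dplyr::bind_rows(purrr::map(results, "nodes"))
  correlations <- correlate_by_patient(node_table)
  icc_fit <- fit_intercept_only(node_table)
  model <- backward_eliminate(node_table)
  structure(list(
    patients = results,
    similarity = dplyr::bind_rows(
      purrr::map(results, ~ dplyr::mutate(glance(.x$similarity),
                                          patient = .x$patient, .before = 1))),
    node_table = node_table,
    correlations = correlations,
    icc_fit = icc_fit,
    model = model
  ), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d patients\n", nrow(x$similarity)))
  cat(sprintf("  median JI %.3f (expected %.3f); %d/%d significant degree correlations\n",
              stats::median(x$similarity$ji), stats::median(x$similarity$ji_expected),
              sum(x$correlations$significant), nrow(x$correlations)))
  cat(sprintf("  ICC %.3f; final model: %s\n", x$icc_fit$icc,
              paste(x$model$retained, collapse = " + ")))
  invisible(x)
}
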