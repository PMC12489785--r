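#' Node degree of a binary network
#'
#' Row sums of the symmetric adjacency matrix.
#'
#' @param net A [binary_network()].
#' @return A tibble with `label` and `degree`.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  tibble::tibble(label = rownames(net), degree = as.integer(rowSums(net)))
}

#' Betweenness centrality of a binary network
#'
#' Unnormalized betweenness over unordered node pairs: for node v, the sum
#' over pairs s != t != v of the fraction of shortest s-t paths passing
#' through v (unweighted shortest paths; disconnected pairs contribute 0).
#'
#' @param net A [binary_network()].
#' @return A tibble with `label` and `betweenness`.
#' @export
node_betweenness <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  g <- igraph::graph_from_adjacency_matrix(as.matrix(net), mode = "undirected")
  bc <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
  tibble::tibble(label = rownames(net), betweenness = unname(bc))
}

#' Assemble the per-node metric table for one patient
#'
#' Joins per-node degree and betweenness of the structural and effective
#' networks with node proximity, contact-area volume (VEA) and SOZ flags —
#' the long-format rows the group-level multilevel model consumes.
#'
#' @param sc,ec [binary_network()]s on identical node sets.
#' @param electrodes Electrode tibble (coordinates, `soz`, `included`).
#' @param areas Optional `contact_area_set` supplying `vea_mm3`.
#' @param patient Patient identifier stamped on every row.
#' @return A tibble with one row per node: `patient`, `label`, `sc_degree`,
#'   `ec_degree`, `sc_betweenness`, `ec_betweenness`, `proximity_mm`,
#'   `vea_mm3`, `soz`.
#' @export
node_metrics <- function(sc, ec, electrodes, areas = NULL, patient = "p01") {
  assert_same_nodes(sc, ec)
  labels <- rownames(sc)
  deg_sc <- node_degree(sc); deg_ec <- node_degree(ec)
  bc_sc <- node_betweenness(sc); bc_ec <- node_betweenness(ec)
  prox <- node_proximity(electrodes[electrodes$label %in% labels, , drop = FALSE])
  out <- tibble::tibble(patient = patient, label = labels) |>
    dplyr::left_join(dplyr::rename(deg_sc, sc_degree = "degree"), by = "label") |>
    dplyr::left_join(dplyr::rename(deg_ec, ec_degree = "degree"), by = "label") |>
    dplyr::left_join(dplyr::rename(bc_sc, sc_betweenness = "betweenness"), by = "label") |>
    dplyr::left_join(dplyr::rename(bc_ec, ec_betweenness = "betweenness"), by = "label") |>
    dplyr::left_join(prox, by = "label")
  out$vea_mm3 <- if (!is.null(areas)) {
    areas$vea_mm3[match(labels, areas$label)]
  } else NA_real_
  out$soz <- electrodes$soz[match(labels, electrodes$label)]
  out
}

#' Per-patient rank correlation with FDR correction
#'
#' Spearman rank correlation between two node metrics within each patient
#' (average ranks for ties, asymptotic p-values), with Benjamini-Hochberg
#' correction of the per-patient p-values across the cohort at level `q`.
#' Patients with a constant metric get NA correlation and are flagged.
#'
#' @param node_table Long node table ([node_metrics()] rows, or
#'   [simulate_cohort()]).
#' @param x,y Column names of the two metrics (defaults: effective vs
#'   structural degree).
#' @param q FDR level (default 0.05).
#' @return A tibble per patient: `patient`, `n`, `rho`, `p_value`, `p_adj`,
#'   `significant`, `degenerate`.
#' @export
correlate_by_patient <- function(node_table, x = "ec_degree", y = "sc_degree",
                                 q = 0.05) {
  stopifnot(all(c("patient", x, y) %in% names(node_table)))
  res <- node_table |>
    dplyr::group_by(.data$patient) |>
    dplyr::group_modify(function(df, key) {
      xv <- df[[x]]; yv <- df[[y]]
      if (length(xv) < 4) {
        stop("Spearman correlation requires at least 4 nodes per patient.", call. = FALSE)
      }
      if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
        return(tibble::tibble(n = length(xv), rho = NA_real_,
                              p_value = NA_real_, degenerate = TRUE))
      }
      ct <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman",
                                             exact = FALSE))
      tibble::tibble(n = length(xv), rho = unname(ct$estimate),
                     p_value = ct$p.value, degenerate = FALSE)
    }) |>
    dplyr::ungroup()
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < q
  res[, c("patient", "n", "rho", "p_value", "p_adj", "significant", "degenerate")]
}
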