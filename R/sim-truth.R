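#' Plant a pair of binary networks with exact edge-set overlap
#'
#' Places `n_shared` shared edges, `n_sc - n_shared` structural-only edges
#' and `n_ec - n_shared` effective-only edges uniformly at random over the
#' unordered node pairs, so the Jaccard index of the pair equals
#' `n_shared / (n_sc + n_ec - n_shared)` exactly.
#'
#' @param labels Character vector of node labels (or a single node count).
#' @param n_sc,n_ec Edge counts of the two networks.
#' @param n_shared Number of shared edges.
#' @param seed Integer seed.
#' @return A list with `sc`, `ec` ([binary_network()]s) and `ji`, the planted
#'   Jaccard index.
#' @examples
#' tr <- plant_binary_networks(20, n_sc = 30, n_ec = 30, n_shared = 12, seed = 1)
#' tr$ji  # 12 / 48 = 0.25
#' @export
plant_binary_networks <- function(labels, n_sc, n_ec, n_shared, seed = 1L) {
  if (length(labels) == 1 && is.numeric(labels)) {
    labels <- sprintf("n%02d", seq_len(labels))
  }
  n <- length(labels)
  pairs <- all_pairs(labels)
  p <- nrow(pairs)
  if (n_shared > min(n_sc, n_ec)) {
    stop("Infeasible: shared edges exceed an edge count.", call. = FALSE)
  }
  if (n_sc + n_ec - n_shared > p) {
    stop("Infeasible: union exceeds the number of node pairs.", call. = FALSE)
  }
  sel <- withr::with_seed(seed, {
    u <- sample.int(p, n_sc + n_ec - n_shared)
    list(shared = u[seq_len(n_shared)],
         sc_only = u[n_shared + seq_len(n_sc - n_shared)],
         ec_only = u[n_sc + seq_len(n_ec - n_shared)])
  })
  edge_df <- function(i) tibble::tibble(from = pairs[i, 1], to = pairs[i, 2])
  sc <- network_from_edges(edge_df(c(sel$shared, sel$sc_only)), labels)
  ec <- network_from_edges(edge_df(c(sel$shared, sel$ec_only)), labels)
  ji <- if (n_sc + n_ec - n_shared == 0) NA_real_ else n_shared / (n_sc + n_ec - n_shared)
  list(sc = sc, ec = ec, ji = ji)
}

#' Simulate ground-truth structural and effective networks
#'
#' Plants two symmetric zero-diagonal binary networks over the included
#' contacts whose edge counts match the configured densities (rounded to the
#' nearest feasible integers) and whose Jaccard index is exact by
#' construction.
#'
#' The effective network is built as the lift of a quotient graph over the
#' disjoint stimulation pairs: a quotient edge between pairs \{a,b\} and
#' \{c,d\} contributes all four contact edges a-c, a-d, b-c, b-d. Lifted
#' networks are exactly the networks the bi-directional construction rule
#' (edges from both stimulated contacts to a responding channel) can
#' produce, so the noiseless generator-to-detector round trip recovers the
#' truth edge-for-edge. Effective edge counts are therefore multiples of
#' four. Structural edges are free: the configured shared count is drawn
#' from the effective edges and the remainder from pairs outside them.
#'
#' @param config A [sim_config()].
#' @param electrodes Electrode tibble; defaults to
#'   [simulate_electrodes()] on `config`.
#' @return A list of class `synthetic_truth`: `sc_true`, `ec_true`
#'   ([binary_network()]s), `ji` (planted Jaccard index), `pairs`
#'   (stimulation pairs), `degrees` (per-node planted degrees).
#' @export
simulate_truth_networks <- function(config, electrodes = simulate_electrodes(config)) {
  labels <- electrodes$label[electrodes$included]
  n <- length(labels)
  if (n < 2) stop("Need at least 2 included contacts.", call. = FALSE)
  pairs <- stim_pairs(electrodes[electrodes$included, ])
  np <- nrow(pairs)
  p_all <- n * (n - 1) / 2

  # effective: quotient graph over stimulation pairs, 4 contact edges each
  q_max <- np * (np - 1) / 2
  q <- round(round(config$d_ec * p_all) / 4)
  q <- min(max(q, if (config$d_ec > 0) 1 else 0), q_max)
  e_ec <- 4 * q

  e_sc <- round(config$d_sc * p_all)
  n_shared <- round(config$overlap * min(e_sc, e_ec))
  if (e_sc - n_shared > p_all - e_ec) {
    stop("Infeasible (d_sc, d_ec, overlap) triple: structural-only edges do not fit.",
         call. = FALSE)
  }

  res <- withr::with_seed(config$seed + 1L, {
    qpairs <- all_pairs(pairs$site)
    qsel <- sample.int(nrow(qpairs), q)
    pair_members <- stats::setNames(
      purrr::map(seq_len(np), ~ c(pairs$anode[.x], pairs$cathode[.x])), pairs$site)
    ec_edges <- purrr::map_dfr(qsel, function(k) {
      a <- pair_members[[qpairs[k, 1]]]
      b <- pair_members[[qpairs[k, 2]]]
      tidyr::expand_grid(from = a, to = b)
    })
    ec <- network_from_edges(ec_edges, labels)
    # lifted edges are distinct across quotient edges (disjoint pairs)
    stopifnot(sum(ec) / 2 == e_ec)

    apairs <- all_pairs(labels)
    in_ec <- unclass(ec)[cbind(apairs[, 1], apairs[, 2])]
    ec_idx <- which(in_ec); non_ec_idx <- which(!in_ec)
    shared_idx <- ec_idx[sample.int(length(ec_idx), n_shared)]
    sc_only_idx <- non_ec_idx[sample.int(length(non_ec_idx), e_sc - n_shared)]
    sc <- network_from_edges(
      tibble::tibble(from = apairs[c(shared_idx, sc_only_idx), 1],
                     to = apairs[c(shared_idx, sc_only_idx), 2]),
      labels)
    list(sc = sc, ec = ec)
  })

  union_n <- e_sc + e_ec - n_shared
  structure(list(
    sc_true = res$sc,
    ec_true = res$ec,
    ji = if (union_n == 0) NA_real_ else n_shared / union_n,
    n_shared = n_shared,
    pairs = pairs,
    degrees = tibble::tibble(
      label = labels,
      sc_degree = rowSums(unclass(res$sc)),
      ec_degree = rowSums(unclass(res$ec))
    )
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d nodes; SC %d edges, EC %d edges, shared %d, planted JI %.3f\n",
              nrow(x$degrees), sum(x$sc_true) / 2, sum(x$ec_true) / 2,
              x$n_shared, x$ji))
  invisible(x)
}
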