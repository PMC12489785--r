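#' Density of a binary network
#'
#' Sum of the (symmetric) adjacency matrix over N(N-1), i.e. 2E / (N(N-1))
#' for E undirected edges.
#'
#' @param net A [binary_network()].
#' @return Density in \[0, 1\].
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- nrow(net)
  if (n < 2) stop("Density requires at least 2 nodes.", call. = FALSE)
  sum(net) / (n * (n - 1))
}

#' Jaccard index of two binary networks
#'
#' Size of the intersection of the two edge sets divided by the size of
#' their union, over unordered node pairs. Both networks must share the same
#' node set and ordering. When both networks are empty the index is 0, with
#' a warning (no overlap is measurable).
#'
#' @param sc,ec [binary_network()]s on identical node sets.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard_index <- function(sc, ec) {
  stopifnot(inherits(sc, "binary_network"), inherits(ec, "binary_network"))
  assert_same_nodes(sc, ec)
  up <- upper.tri(sc)
  inter <- sum(sc[up] & ec[up])
  union <- sum(sc[up] | ec[up])
  if (union == 0) {
    warning("Both networks are empty; Jaccard index reported as 0.", call. = FALSE)
    return(0)
  }
  inter / union
}

#' Expected Jaccard index under density-matched chance
#'
#' The Jaccard index obtained when the connections of both networks are
#' placed at random positions: `d1*d2 / (d1 + d2 - d1*d2)`.
#'
#' @param d_sc,d_ec Network densities in \[0, 1\], not both zero.
#' @return Expected Jaccard index.
#' @examples
#' expected_jaccard(0.20, 0.23)  # ~0.12
#' @export
expected_jaccard <- function(d_sc, d_ec) {
  stopifnot(all(d_sc >= 0 & d_sc <= 1), all(d_ec >= 0 & d_ec <= 1))
  if (any(d_sc == 0 & d_ec == 0)) {
    stop("Expected Jaccard index is undefined when both densities are 0.", call. = FALSE)
  }
  d_sc * d_ec / (d_sc + d_ec - d_sc * d_ec)
}

#' Permutation test for Jaccard similarity of two binary networks
#'
#' Tests whether the observed Jaccard index exceeds what density-matched
#' chance produces: each permutation places the two networks' edge counts
#' independently and uniformly over the unordered node pairs and records the
#' permuted Jaccard index. The p-value is `(1 + #(JI_perm >= JI_obs)) /
#' (B + 1)`. The mean of the permuted indices estimates the closed-form
#' expected Jaccard index, which serves as a cross-check of the null.
#'
#' @param sc,ec Non-empty [binary_network()]s on identical node sets.
#' @param B Number of permutations (default 10000; fewer than 100 warns).
#' @param seed Integer seed for the permutation RNG.
#' @return List with `p_value`, `ji_obs`, `ji_null_mean`, `ji_null` (the B
#'   permuted indices) and `B`.
#' @export
jaccard_significance <- function(sc, ec, B = 10000, seed = 1L) {
  stopifnot(inherits(sc, "binary_network"), inherits(ec, "binary_network"))
  assert_same_nodes(sc, ec)
  if (B < 100) warning("Fewer than 100 permutations gives a coarse p-value.", call. = FALSE)
  up <- which(upper.tri(sc))
  e1 <- sum(sc[up]); e2 <- sum(ec[up])
  if (e1 == 0 || e2 == 0) {
    stop("Permutation test requires both networks to be non-empty.", call. = FALSE)
  }
  ji_obs <- jaccard_index(sc, ec)
  p <- length(up)
  ji_null <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      a <- sample.int(p, e1)
      bb <- sample.int(p, e2)
      inter <- length(intersect(a, bb))
      inter / (e1 + e2 - inter)
    }, numeric(1))
  })
  list(
    p_value = (1 + sum(ji_null >= ji_obs)) / (B + 1),
    ji_obs = ji_obs,
    ji_null_mean = mean(ji_null),
    ji_null = ji_null,
    B = B
  )
}

#' Symmetric-difference log-ratio of structural vs effective connections
#'
#' `log10(|SC-only| / |EC-only|)` over the set of symmetric-difference
#' connections: 0 when both modalities contribute equally, -1 when there are
#' ten times more effective-only than structural-only connections, and
#' +/-Inf when one side is empty. When the symmetric difference itself is
#' empty the ratio is undefined (NaN, with a warning).
#'
#' @param sc,ec [binary_network()]s on identical node sets.
#' @return Log10 ratio (possibly +/-Inf or NaN).
#' @export
symmetric_difference_ratio <- function(sc, ec) {
  stopifnot(inherits(sc, "binary_network"), inherits(ec, "binary_network"))
  assert_same_nodes(sc, ec)
  up <- upper.tri(sc)
  sc_only <- sum(sc[up] & !ec[up])
  ec_only <- sum(ec[up] & !sc[up])
  if (sc_only == 0 && ec_only == 0) {
    warning("Empty symmetric difference; ratio is undefined (NaN).", call. = FALSE)
    return(NaN)
  }
  if (ec_only == 0) return(Inf)
  if (sc_only == 0) return(-Inf)
  log10(sc_only / ec_only)
}

#' Inter-modal similarity between structural and effective networks
#'
#' Computes the full similarity panel of the two binary networks: Jaccard
#' index, expected Jaccard under density-matched chance, both densities, the
#' symmetric-difference log-ratio, edge-count breakdown, and the permutation
#' p-value for the Jaccard index being higher than chance.
#'
#' @param sc,ec [binary_network()]s on identical node sets (structural and
#'   effective).
#' @param B Permutations for the significance test (default 10000).
#' @param seed Integer seed.
#' @return An object of class `network_similarity`.
#' @export
compare_networks <- function(sc, ec, B = 10000, seed = 1L) {
  stopifnot(inherits(sc, "binary_network"), inherits(ec, "binary_network"))
  assert_same_nodes(sc, ec)
  up <- upper.tri(sc)
  inter <- sum(sc[up] & ec[up])
  sc_only <- sum(sc[up] & !ec[up])
  ec_only <- sum(ec[up] & !sc[up])
  d_sc <- network_density(sc)
  d_ec <- network_density(ec)
  test <- if (sum(sc[up]) > 0 && sum(ec[up]) > 0) {
    jaccard_significance(sc, ec, B = B, seed = seed)
  } else NULL
  structure(list(
    n_nodes = nrow(sc),
    ji = if (inter + sc_only + ec_only == 0) 0 else inter / (inter + sc_only + ec_only),
    ji_expected = if (d_sc == 0 && d_ec == 0) NA_real_ else expected_jaccard(d_sc, d_ec),
    d_sc = d_sc,
    d_ec = d_ec,
    ratio_sc_delta_ec = if (sc_only == 0 && ec_only == 0) NaN
                        else if (ec_only == 0) Inf
                        else if (sc_only == 0) -Inf
                        else log10(sc_only / ec_only),
    n_intersection = inter,
    n_union = inter + sc_only + ec_only,
    n_sc_only = sc_only,
    n_ec_only = ec_only,
    p_value = if (is.null(test)) NA_real_ else test$p_value,
    ji_null_mean = if (is.null(test)) NA_real_ else test$ji_null_mean,
    B = B
  ), class = "network_similarity")
}

#' @export
print.network_similarity <- function(x, ...) {
  cat(sprintf(paste0(
    "<network_similarity> %d nodes\n",
    "  JI %.3f (expected %.3f), p %s\n",
    "  densities: SC %.3f, EC %.3f\n",
    "  edges: %d shared, %d SC-only, %d EC-only; log10 ratio %.3g\n"),
    x$n_nodes, x$ji, x$ji_expected,
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3, eps = 1e-4),
    x$d_sc, x$d_ec, x$n_intersection, x$n_sc_only, x$n_ec_only,
    x$ratio_sc_delta_ec))
  invisible(x)
}

#' @rdname compare_networks
#' @param x A `network_similarity` object.
#' @param ... Unused.
#' @export
glance.network_similarity <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes, ji = x$ji, ji_expected = x$ji_expected,
    d_sc = x$d_sc, d_ec = x$d_ec, ratio_sc_delta_ec = x$ratio_sc_delta_ec,
    p_value = x$p_value
  )
}

#' @rdname compare_networks
#' @export
tidy.network_similarity <- function(x, ...) {
  tibble::tibble(
    component = c("intersection", "sc_only", "ec_only", "union"),
    n_edges = c(x$n_intersection, x$n_sc_only, x$n_ec_only, x$n_union)
  )
}

#' @rdname compare_networks
#' @param object A `network_similarity` object.
#' @export
autoplot.network_similarity <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$component != "union", , drop = FALSE]
  df$component <- factor(df$component, c("sc_only", "intersection", "ec_only"),
                         c("structural only", "both", "effective only"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$n_edges,
                                   fill = .data$component)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("#2166ac", "#e08214", "#1b7837")) +
    ggplot2::labs(
      x = NULL, y = "connections",
      title = sprintf("JI %.2f (expected %.2f), log10 SC/EC ratio %.2f",
                      object$ji, object$ji_expected, object$ratio_sc_delta_ec)
    ) +
    ggplot2::theme_minimal()
}
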