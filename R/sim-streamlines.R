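#' Simulate streamline endpoint counts from a planted structural network
#'
#' Draws a symmetric integer count matrix over contact-area pairs that, once
#' normalized by the contact-area volumes and thresholded at the configured
#' streamline-density cutoff, recovers the planted structural network: true
#' edges get counts whose density exceeds the threshold, non-edges get
#' sub-threshold counts except for a Bernoulli(`fp_rate`) fraction of
#' spurious supra-threshold pairs (mimicking false-positive streamlines from
#' probabilistic tractography).
#'
#' @param truth A `synthetic_truth` ([simulate_truth_networks()]), or any
#'   [binary_network()] used as the structural truth.
#' @param areas A `contact_area_set` ([build_contact_areas()]) covering the
#'   truth's nodes.
#' @param fp_rate Per-pair probability of a spurious supra-threshold count.
#' @param seed Integer seed.
#' @param threshold Streamline-density threshold the downstream binarization
#'   will use (default 0.1).
#' @param denominator Volume normalization the downstream density step will
#'   use; `"sum"` of the two VEAs by default.
#' @return Symmetric integer count matrix with contact labels.
#' @export
simulate_streamline_counts <- function(truth, areas, fp_rate = 0, seed = 1L,
                                       threshold = 0.1,
                                       denominator = c("sum", "mean", "product")) {
  denominator <- match.arg(denominator)
  sc <- if (inherits(truth, "synthetic_truth")) truth$sc_true else truth
  stopifnot(inherits(sc, "binary_network"), fp_rate >= 0, fp_rate <= 1)
  labels <- network_labels(sc)
  if (!all(labels %in% areas$label)) {
    stop("Contact areas missing for some network nodes.", call. = FALSE)
  }
  vea <- stats::setNames(areas$vea_mm3, areas$label)[labels]
  if (any(vea[labels] <= 0)) {
    stop("All network nodes must have non-empty contact areas.", call. = FALSE)
  }
  pairs <- all_pairs(labels)
  vol <- switch(denominator,
    sum = vea[pairs[, 1]] + vea[pairs[, 2]],
    mean = (vea[pairs[, 1]] + vea[pairs[, 2]]) / 2,
    product = vea[pairs[, 1]] * vea[pairs[, 2]]
  )
  is_edge <- unclass(sc)[cbind(pairs[, 1], pairs[, 2])]
  counts <- withr::with_seed(seed, {
    cnt <- integer(nrow(pairs))
    # true edges: density drawn in (1.2, 5) x threshold, strictly above cutoff
    dens_true <- stats::runif(sum(is_edge), 1.2 * threshold, 5 * threshold)
    cnt[is_edge] <- pmax(ceiling(dens_true * vol[is_edge]),
                         floor(threshold * vol[is_edge]) + 1L)
    # non-edges: mostly sub-threshold, a Bernoulli(fp_rate) fraction spurious
    n_non <- sum(!is_edge)
    spurious <- stats::runif(n_non) < fp_rate
    dens_null <- stats::runif(n_non, 0, 0.8 * threshold)
    sub <- pmin(floor(dens_null * vol[!is_edge]), floor(threshold * vol[!is_edge]))
    dens_fp <- stats::runif(n_non, 1.2 * threshold, 2 * threshold)
    sup <- pmax(ceiling(dens_fp * vol[!is_edge]),
                floor(threshold * vol[!is_edge]) + 1L)
    cnt[!is_edge] <- ifelse(spurious, sup, sub)
    cnt
  })
  m <- matrix(0L, length(labels), length(labels), dimnames = list(labels, labels))
  m[cbind(pairs[, 1], pairs[, 2])] <- as.integer(counts)
  m[cbind(pairs[, 2], pairs[, 1])] <- as.integer(counts)
  m
}

#' Simulate streamlines realizing a count matrix
#'
#' Emits, for every contact pair, the counted number of three-point
#' polylines running from a voxel centre of one contact area to a voxel
#' centre of the other (plus a midpoint), in the mask's mm space. Feeding
#' the result to [count_streamlines()] reproduces the count matrix exactly;
#' the streamlines also exercise the TCK writer/reader.
#'
#' @param counts Symmetric integer count matrix (contact labels as dimnames).
#' @param areas A `contact_area_set`.
#' @param seed Integer seed for endpoint voxel choice.
#' @return List of n x 3 coordinate matrices (class `streamline_set`).
#' @export
simulate_streamlines <- function(counts, areas, seed = 1L) {
  labels <- rownames(counts)
  vox <- area_voxels(areas)
  affine <- attr(areas, "affine")
  mask_stub <- list(affine = affine)
  pairs <- all_pairs(labels)
  lines <- withr::with_seed(seed, {
    out <- list()
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      nk <- counts[i, j]
      if (nk == 0) next
      vi <- vox[[i]]; vj <- vox[[j]]
      for (s in seq_len(nk)) {
        a <- vi[sample.int(nrow(vi), 1), , drop = FALSE]
        b <- vj[sample.int(nrow(vj), 1), , drop = FALSE]
        pa <- voxel_centres(mask_stub, a)
        pb <- voxel_centres(mask_stub, b)
        out[[length(out) + 1]] <- rbind(pa, (pa + pb) / 2, pb)
      }
    }
    out
  })
  structure(lines, class = "streamline_set")
}
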