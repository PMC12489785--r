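#' Count streamlines connecting contact areas
#'
#' A streamline contributes to the count of the unordered pair (i, j) when
#' its first point lies in a voxel of contact area i and its last point in a
#' voxel of a different contact area j. Streamlines starting and ending in
#' the same area, or with an endpoint outside every area, are ignored;
#' streamlines with fewer than two points are skipped and the skip count is
#' reported as an attribute.
#'
#' @param streamlines List of n x 3 mm coordinate matrices (e.g. from
#'   [read_tck()] or [simulate_streamlines()]).
#' @param areas A `contact_area_set` ([build_contact_areas()]); endpoint
#'   membership is resolved through the mask affine stored in the set.
#' @return Symmetric integer count matrix over the non-empty contact areas,
#'   with attribute `n_skipped`.
#' @export
count_streamlines <- function(streamlines, areas) {
  vox <- area_voxels(areas)
  labels <- areas$label[!areas$empty]
  affine <- attr(areas, "affine")
  # hash voxel index -> owning area
  keys <- purrr::imap(vox[labels], function(v, lab) {
    if (nrow(v) == 0) return(character())
    stats::setNames(rep(lab, nrow(v)), apply(v, 1, paste, collapse = ","))
  })
  lookup <- unlist(unname(keys))
  m <- matrix(0L, length(labels), length(labels), dimnames = list(labels, labels))
  mask_stub <- list(affine = affine)
  n_skipped <- 0L
  for (s in streamlines) {
    s <- coord_matrix(s)
    if (nrow(s) < 2) { n_skipped <- n_skipped + 1L; next }
    ends <- world_to_voxel(mask_stub, s[c(1, nrow(s)), , drop = FALSE])
    k <- apply(ends, 1, paste, collapse = ",")
    a <- lookup[k[1]]; b <- lookup[k[2]]
    if (is.na(a) || is.na(b) || a == b) next
    m[a, b] <- m[a, b] + 1L
    m[b, a] <- m[b, a] + 1L
  }
  if (n_skipped > 0) {
    message(sprintf("Skipped %d streamline(s) with fewer than 2 points.", n_skipped))
  }
  attr(m, "n_skipped") <- n_skipped
  m
}

#' Streamline density between contact areas
#'
#' The streamline count of each pair divided by the volume of the two
#' involved electrode contact areas. The default normalization is the sum of
#' the two VEAs, which is symmetric and keeps the usual 0.1 threshold on a
#' per-mm^3 scale; the mean and product are available as alternatives.
#'
#' @param counts Symmetric non-negative integer count matrix with contact
#'   labels as dimnames.
#' @param areas A `contact_area_set` covering the count-matrix labels.
#' @param denominator `"sum"` (default), `"mean"`, or `"product"` of the two
#'   VEAs.
#' @return Symmetric numeric density matrix.
#' @export
streamline_density <- function(counts, areas,
                               denominator = c("sum", "mean", "product")) {
  denominator <- match.arg(denominator)
  labels <- rownames(counts)
  stopifnot(!is.null(labels), identical(labels, colnames(counts)))
  if (any(counts < 0)) stop("Counts must be non-negative.", call. = FALSE)
  if (!isTRUE(all(counts == t(counts)))) stop("Counts must be symmetric.", call. = FALSE)
  vea <- stats::setNames(areas$vea_mm3, areas$label)
  if (!all(labels %in% names(vea))) {
    stop("Contact areas missing for some count-matrix labels.", call. = FALSE)
  }
  v <- vea[labels]
  if (any(counts > 0 & (v[row(counts)] == 0 | v[col(counts)] == 0))) {
    stop("Nonzero streamline count for a contact with an empty area.", call. = FALSE)
  }
  denom <- switch(denominator,
    sum = outer(v, v, "+"),
    mean = outer(v, v, "+") / 2,
    product = outer(v, v, "*")
  )
  d <- counts / denom
  d[!is.finite(d)] <- 0
  diag(d) <- 0
  d
}

#' Binarize a streamline-density matrix into a structural network
#'
#' A structural connection is formed when the streamline density strictly
#' exceeds the threshold (default 0.1); a density exactly at the threshold
#' forms no edge.
#'
#' @param density Symmetric non-negative density matrix with contact labels.
#' @param threshold Density cutoff (default 0.1).
#' @return A [binary_network()].
#' @export
binarize_structural <- function(density, threshold = 0.1) {
  stopifnot(is.matrix(density))
  if (any(density < 0)) stop("Densities must be non-negative.", call. = FALSE)
  if (!isTRUE(all(abs(density - t(density)) < 1e-12))) {
    stop("Density matrix must be symmetric.", call. = FALSE)
  }
  a <- density > threshold
  diag(a) <- FALSE
  binary_network(a)
}
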