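#' Apply a 4x4 affine transform to millimetre coordinates
#'
#' Used to move electrode contact coordinates between co-registered spaces
#' (e.g. CT-extracted coordinates into the diffusion-image space); the
#' transform itself is an input, never estimated here.
#'
#' @param coords n x 3 matrix, data frame with `x`,`y`,`z`, or length-3 vector.
#' @param transform 4x4 affine matrix.
#' @return Transformed coordinates in the same shape as the input.
#' @examples
#' tr <- diag(4); tr[1, 4] <- 5
#' apply_affine(c(1, 2, 3), tr)
#' @export
apply_affine <- function(coords, transform) {
  transform <- as.matrix(transform)
  stopifnot(identical(dim(transform), c(4L, 4L)))
  if (abs(det(transform)) < .Machine$double.eps^0.5) {
    stop("Affine transform is singular.", call. = FALSE)
  }
  was_vector <- is.numeric(coords) && is.null(dim(coords))
  was_df <- is.data.frame(coords)
  m <- coord_matrix(coords)
  out <- t(transform %*% t(cbind(m, 1)))[, 1:3, drop = FALSE]
  if (was_vector && nrow(out) == 1) return(drop(out))
  if (was_df) {
    coords$x <- out[, 1]; coords$y <- out[, 2]; coords$z <- out[, 3]
    return(coords)
  }
  out
}

#' Build electrode contact areas on the grey-white matter boundary
#'
#' Projects each included contact onto the boundary mask by claiming its
#' nearest boundary voxels (Euclidean distance from the contact coordinate
#' to voxel centres), up to `max_voxels` per contact and within
#' `search_radius_mm`. Voxels claimed by several contacts, or strictly
#' nearer to another contact, are kept only by the globally nearest contact
#' (ties broken by ascending contact index); areas are never refilled after
#' losing voxels, so closely spaced contacts end up with volumes below the
#' cap. The volume of the electrode contact area (VEA) is the voxel count
#' times the voxel volume, at most 64 mm^3 at 1 mm isotropic voxels.
#'
#' @param electrodes Electrode tibble with `label`, `x`, `y`, `z`,
#'   `included`.
#' @param mask A [voxel_mask()].
#' @param max_voxels Cap on voxels per contact area (64).
#' @param search_radius_mm Maximum projection distance; contacts with no
#'   boundary voxel within it get an empty, flagged area.
#' @return An object of class `contact_area_set`: a tibble (`label`,
#'   `n_voxels`, `vea_mm3`, `empty`) with the voxel index sets, mask affine
#'   and voxel volume attached as attributes.
#' @export
build_contact_areas <- function(electrodes, mask, max_voxels = 64,
                                search_radius_mm = 20) {
  stopifnot(inherits(mask, "voxel_mask"), max_voxels >= 1)
  el <- electrodes[electrodes$included, , drop = FALSE]
  if (nrow(el) == 0) stop("No included contacts.", call. = FALSE)
  true_idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(true_idx) == 0) stop("Mask contains no true voxels.", call. = FALSE)
  centres <- voxel_centres(mask, true_idx)
  coords <- coord_matrix(el)
  d <- cross_dist(centres, coords)  # voxels x contacts

  # globally nearest contact per voxel; ties to the lower contact index
  nearest <- max.col(-d, ties.method = "first")

  claims <- purrr::map(seq_len(nrow(el)), function(i) {
    cand <- which(d[, i] <= search_radius_mm)
    cand[order(d[cand, i], cand)][seq_len(min(max_voxels, length(cand)))]
  })
  kept <- purrr::map(seq_len(nrow(el)), function(i) {
    claims[[i]][nearest[claims[[i]]] == i]
  })

  n_vox <- lengths(kept)
  if (any(n_vox == 0)) {
    warning(sprintf("%d contact(s) received an empty area and carry no structural node: %s",
                    sum(n_vox == 0), paste(el$label[n_vox == 0], collapse = ", ")),
            call. = FALSE)
  }
  areas <- tibble::tibble(
    label = el$label,
    n_voxels = n_vox,
    vea_mm3 = n_vox * mask$voxel_volume,
    empty = n_vox == 0
  )
  voxels <- purrr::map(kept, function(k) true_idx[k, , drop = FALSE])
  names(voxels) <- el$label
  structure(areas,
            voxels = voxels,
            affine = mask$affine,
            voxel_volume = mask$voxel_volume,
            class = c("contact_area_set", class(areas)))
}

#' Voxel index sets of a contact area set
#'
#' @param areas A `contact_area_set`.
#' @return Named list of 1-based voxel index matrices (n x 3), one per contact.
#' @export
area_voxels <- function(areas) attr(areas, "voxels")

#' Median inter-contact distance (node proximity)
#'
#' For every included contact, the median Euclidean distance to all other
#' included contacts, in mm. Low values mark densely sampled regions;
#' proximity enters the multilevel model to absorb irregular spatial
#' sampling of the brain.
#'
#' @param electrodes Electrode tibble with `label`, `x`, `y`, `z`,
#'   `included` (or any data frame with those coordinate columns).
#' @return A tibble with `label` and `proximity_mm`.
#' @examples
#' el <- tibble::tibble(label = c("a", "b", "c"),
#'                      x = c(0, 10, 20), y = 0, z = 0, included = TRUE)
#' node_proximity(el)  # 15, 10, 15
#' @export
node_proximity <- function(electrodes) {
  el <- if ("included" %in% names(electrodes)) {
    electrodes[electrodes$included, , drop = FALSE]
  } else electrodes
  if (nrow(el) < 2) {
    stop("Node proximity requires at least 2 included contacts.", call. = FALSE)
  }
  coords <- coord_matrix(el)
  d <- cross_dist(coords, coords)
  prox <- vapply(seq_len(nrow(d)), function(i) stats::median(d[i, -i]), numeric(1))
  tibble::tibble(label = el$label, proximity_mm = prox)
}
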