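#' Voxel mask with world-coordinate affine
#'
#' A binary 3-D mask marking grey-white matter boundary voxels, together
#' with the affine mapping 0-based voxel indices to scanner millimetre
#' coordinates (NIfTI convention) and the voxel volume.
#'
#' @param data Logical (or 0/1) 3-D array.
#' @param affine 4x4 voxel-to-world transform (0-based indices).
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(data, affine = diag(4)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (is.numeric(data)) {
    stopifnot(all(data %in% c(0, 1)))
    storage.mode(data) <- "logical"
  }
  stopifnot(is.logical(data))
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps^0.5) {
    stop("Mask affine must be invertible.", call. = FALSE)
  }
  vol <- abs(det(affine[1:3, 1:3]))
  structure(list(data = data, affine = affine, voxel_volume = vol),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels, %d true, voxel volume %.3g mm^3\n",
              paste(dim(x$data), collapse = "x"), sum(x$data), x$voxel_volume))
  invisible(x)
}

# World-space centre coordinates (n x 3, mm) of 1-based voxel indices (n x 3).
voxel_centres <- function(mask, idx1) {
  idx0 <- cbind(idx1 - 1, 1)
  t(mask$affine %*% t(idx0))[, 1:3, drop = FALSE]
}

# 1-based voxel index of world-space mm coordinates; no bounds check.
world_to_voxel <- function(mask, coords) {
  coords <- coord_matrix(coords)
  inv <- solve(mask$affine)
  idx0 <- t(inv %*% t(cbind(coords, 1)))[, 1:3, drop = FALSE]
  round(idx0) + 1
}

#' Simulate a grey-white matter boundary mask around electrode contacts
#'
#' Marks as boundary every voxel within `radius_mm` of any contact, so that
#' each contact can claim a full-size contact area (a 4 mm ball at 1 mm
#' voxels holds ~250 voxels, comfortably above the 64-voxel cap), while
#' closely spaced contacts compete for shared voxels and end up with areas
#' below the cap, as happens on real boundary masks.
#'
#' @param electrodes Electrode tibble ([simulate_electrodes()]).
#' @param config A [sim_config()] (voxel size).
#' @param radius_mm Boundary thickness around each contact, mm.
#' @param margin_mm Padding between the outermost contact and the volume edge.
#' @return A [voxel_mask()] whose affine places the volume around the
#'   contacts in scanner mm space.
#' @export
simulate_boundary_mask <- function(electrodes, config, radius_mm = 4, margin_mm = 8) {
  stopifnot(radius_mm > 0)
  coords <- coord_matrix(electrodes)
  vs <- config$voxel_size_mm
  lo <- floor(apply(coords, 2, min) - margin_mm)
  hi <- ceiling(apply(coords, 2, max) + margin_mm)
  dims <- pmax(ceiling((hi - lo) / vs) + 1, 2)
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- lo
  arr <- array(FALSE, dim = dims)
  idx <- which(!arr, arr.ind = TRUE)  # all voxels
  centres <- t(affine %*% t(cbind(idx - 1, 1)))[, 1:3, drop = FALSE]
  d <- cross_dist(centres, coords)
  arr[idx[apply(d, 1, min) <= radius_mm, , drop = FALSE]] <- TRUE
  voxel_mask(arr, affine)
}
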