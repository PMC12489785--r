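test_that("apply_affine handles identity, translation, and composition", {
  pts <- matrix(c(1, 2, 3, -4, 0, 2.5), ncol = 3, byrow = TRUE)
  expect_equal(apply_affine(pts, diag(4)), pts)
  tr <- diag(4); tr[1, 4] <- 5
  expect_equal(apply_affine(c(1, 2, 3), tr), c(6, 2, 3))
  # composition equals the matrix product applied once
  a <- diag(4); a[1:3, 1:3] <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3); a[1:3, 4] <- c(1, 2, 3)
  b <- diag(c(2, 2, 2, 1)); b[2, 4] <- -7
  expect_equal(apply_affine(apply_affine(pts, a), b), apply_affine(pts, b %*% a))
  sing <- diag(4); sing[1, 1] <- 0
  expect_error(apply_affine(pts, sing), "singular")
})

test_that("an isolated contact on a saturated mask gets exactly 64 voxels (VEA 64 mm^3)", {
  mask <- voxel_mask(array(TRUE, dim = c(20, 20, 20)))
  el <- tibble::tibble(label = "c1", x = 10, y = 10, z = 10, included = TRUE)
  areas <- build_contact_areas(el, mask)
  expect_equal(areas$n_voxels, 64)
  expect_equal(areas$vea_mm3, 64)
  expect_false(areas$empty)
})

test_that("a constrained mask limits the area to the available voxels", {
  arr <- array(FALSE, dim = c(30, 30, 30))
  idx <- which(!arr, arr.ind = TRUE)
  keep <- idx[order(sqrt(rowSums((idx - 15)^2)))[1:40], ]
  arr[keep] <- TRUE
  mask <- voxel_mask(arr)
  el <- tibble::tibble(label = "c1", x = 14, y = 14, z = 14, included = TRUE)
  areas <- build_contact_areas(el, mask)
  expect_equal(areas$n_voxels, 40)
})

test_that("empty masks error and unreachable contacts get flagged empty areas", {
  expect_error(
    build_contact_areas(
      tibble::tibble(label = "c1", x = 1, y = 1, z = 1, included = TRUE),
      voxel_mask(array(FALSE, dim = c(4, 4, 4)))),
    "no true voxels")
  arr <- array(FALSE, dim = c(40, 10, 10)); arr[1:2, , ] <- TRUE
  el <- tibble::tibble(label = c("near", "far"), x = c(2, 35), y = 5, z = 5,
                       included = TRUE)
  expect_warning(areas <- build_contact_areas(el, voxel_mask(arr)), "empty area")
  expect_false(areas$empty[areas$label == "near"])
  expect_true(areas$empty[areas$label == "far"])
})

test_that("contested voxels go to the nearest contact, ties to the lower index", {
  # two contacts symmetric about x = 5.5 on a single-voxel-thick line
  arr <- array(FALSE, dim = c(10, 1, 1)); arr[, 1, 1] <- TRUE
  el <- tibble::tibble(label = c("a", "b"), x = c(4, 7), y = 0, z = 0,
                       included = TRUE)
  areas <- build_contact_areas(el, voxel_mask(arr))
  vox <- area_voxels(areas)
  # voxel centres are x = 0..9; x = 5.5 is equidistant -> none; x = 5 nearer a
  expect_true(all(vox[["a"]][, 1] <= 6))   # 1-based index 6 = centre x 5
  expect_true(all(vox[["b"]][, 1] >= 7))
  # exact tie: contacts equidistant from every voxel -> all go to "a"
  el2 <- tibble::tibble(label = c("a", "b"), x = 4.5, y = c(1, -1), z = 0,
                        included = TRUE)
  a2 <- suppressWarnings(build_contact_areas(el2, voxel_mask(arr)))
  expect_equal(a2$n_voxels[a2$label == "a"], 10)
  expect_equal(a2$n_voxels[a2$label == "b"], 0)
})

test_that("area assignment matches the brute-force nearest-contact oracle", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      arr <- array(stats::runif(16 * 16 * 8) < 0.35, dim = c(16, 16, 8))
      mask <- voxel_mask(arr)
      el <- tibble::tibble(label = sprintf("c%d", 1:4),
                           x = stats::runif(4, 2, 13),
                           y = stats::runif(4, 2, 13),
                           z = stats::runif(4, 1, 6),
                           included = TRUE)
      areas <- suppressWarnings(build_contact_areas(el, mask))
      vox <- area_voxels(areas)
      coords <- cbind(el$x, el$y, el$z)
      seen <- character(0)
      for (i in seq_len(nrow(el))) {
        v <- vox[[el$label[i]]]
        expect_lte(nrow(v), 64)
        if (nrow(v) == 0) next
        keys <- apply(v, 1, paste, collapse = ",")
        expect_false(any(keys %in% seen))  # disjoint
        seen <- c(seen, keys)
        centres <- v - 1  # identity affine: centre = 0-based index
        for (k in seq_len(nrow(v))) {
          dd <- sqrt(colSums((t(coords) - centres[k, ])^2))
          expect_lte(dd[i], 20)                      # radius cap
          expect_true(all(dd[i] < dd[-i] + 1e-12))   # no strictly nearer contact
        }
      }
      # total assigned voxels cannot exceed the true-voxel count
      expect_lte(length(seen), sum(arr))
    }
  })
})

test_that("node proximity is the median inter-contact distance", {
  el <- tibble::tibble(label = c("a", "b", "c"), x = c(0, 10, 20), y = 0, z = 0,
                       included = TRUE)
  expect_equal(node_proximity(el)$proximity_mm, c(15, 10, 15))
  el2 <- tibble::tibble(label = c("a", "b"), x = c(0, 7), y = 0, z = 0,
                        included = TRUE)
  expect_equal(node_proximity(el2)$proximity_mm, c(7, 7))
  # invariance under rigid motion (translation + rotation about z)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  m <- coordRot <- cbind(el$x, el$y, el$z) %*% t(R)
  el3 <- tibble::tibble(label = el$label, x = m[, 1] + 5, y = m[, 2] - 3,
                        z = m[, 3] + 11, included = TRUE)
  expect_equal(node_proximity(el3)$proximity_mm, c(15, 10, 15))
  expect_error(node_proximity(el[1, ]), "at least 2")
})
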