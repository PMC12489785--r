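make_two_areas <- function() {
  # two contacts far apart on a saturated mask: full 64-voxel areas
  mask <- voxel_mask(array(TRUE, dim = c(40, 12, 12)))
  el <- tibble::tibble(label = c("A", "B"), x = c(5, 30), y = 5, z = 5,
                       included = TRUE)
  build_contact_areas(el, mask)
}

test_that("streamlines are counted by endpoint-area membership", {
  areas <- make_two_areas()
  vox <- area_voxels(areas)
  a1 <- vox[["A"]][1, ] - 1  # identity affine: centre = 0-based index
  b1 <- vox[["B"]][1, ] - 1
  sl <- c(
    replicate(5, rbind(a1, (a1 + b1) / 2, b1), simplify = FALSE),
    list(rbind(a1, a1 + c(0.2, 0, 0))),           # same area: ignored
    list(rbind(c(200, 200, 200), b1)),            # start outside: ignored
    list(matrix(a1, ncol = 3))                    # single point: skipped
  )
  counts <- suppressMessages(count_streamlines(sl, areas))
  expect_equal(counts["A", "B"], 5L)
  expect_equal(counts["B", "A"], 5L)
  expect_equal(attr(counts, "n_skipped"), 1L)
})

test_that("streamline density follows count / (VEA_i + VEA_j)", {
  areas <- make_two_areas()
  counts <- matrix(c(0L, 13L, 13L, 0L), 2, dimnames = list(c("A", "B"), c("A", "B")))
  d <- streamline_density(counts, areas)
  expect_equal(d["A", "B"], 13 / 128)
  expect_gt(d["A", "B"], 0.1)
  expect_equal(d["B", "A"], d["A", "B"])
  # zero counts give zero density; halving under doubled volumes
  counts0 <- counts; counts0[] <- 0L
  expect_true(all(streamline_density(counts0, areas) == 0))
  areas2 <- areas; areas2$vea_mm3 <- areas$vea_mm3 * 2
  expect_equal(streamline_density(counts, areas2)["A", "B"], d["A", "B"] / 2)
  # alternative denominators
  expect_equal(streamline_density(counts, areas, "mean")["A", "B"], 13 / 64)
  expect_equal(streamline_density(counts, areas, "product")["A", "B"], 13 / 64^2)
})

test_that("a nonzero count on an empty-area contact is rejected", {
  areas <- make_two_areas()
  areas$vea_mm3[2] <- 0
  counts <- matrix(c(0L, 2L, 2L, 0L), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(streamline_density(counts, areas), "empty area")
})

test_that("binarization uses a strict threshold and yields a clean network", {
  d <- matrix(c(0, 0.1, 0.2, 0.1, 0, 0.100001, 0.2, 0.100001, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net <- binarize_structural(d)
  expect_false(net["a", "b"])       # exactly at threshold: no edge
  expect_true(net["a", "c"])
  expect_true(net["b", "c"])
  expect_true(all(diag(unclass(net)) == FALSE))
  # all-zero densities: empty network with density 0
  net0 <- binarize_structural(matrix(0, 3, 3, dimnames = dimnames(d)))
  expect_equal(network_density(net0), 0)
})

test_that("binarization is monotone in counts and matches per-pair recomputation", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- sample(4:10, 1)
      labels <- sprintf("c%d", 1:n)
      vea <- stats::setNames(sample(30:64, n, replace = TRUE), labels)
      areas <- tibble::tibble(label = labels, n_voxels = vea, vea_mm3 = vea,
                              empty = FALSE)
      counts <- matrix(0L, n, n, dimnames = list(labels, labels))
      up <- which(upper.tri(counts), arr.ind = TRUE)
      vals <- sample(0:20, nrow(up), replace = TRUE)
      counts[up] <- vals; counts[up[, 2:1]] <- vals
      net <- binarize_structural(streamline_density(counts, areas))
      # per-pair oracle
      for (k in seq_len(nrow(up))) {
        i <- up[k, 1]; j <- up[k, 2]
        expect_equal(unclass(net)[i, j],
                     unname(counts[i, j] / (vea[i] + vea[j]) > 0.1))
      }
      # raising one count never removes an edge
      counts2 <- counts
      counts2[up[1, 1], up[1, 2]] <- counts2[up[1, 1], up[1, 2]] + 50L
      counts2[up[1, 2], up[1, 1]] <- counts2[up[1, 1], up[1, 2]]
      net2 <- binarize_structural(streamline_density(counts2, areas))
      expect_true(all(unclass(net2)[unclass(net)] ))
    }
  })
})

test_that("simulated counts recover the planted structural network", {
  cfg <- sim_config("sEEG", n_shafts = 2, contacts_per_shaft = 8, seed = 31)
  el <- simulate_electrodes(cfg)
  mask <- simulate_boundary_mask(el, cfg)
  areas <- build_contact_areas(el, mask)
  tr <- simulate_truth_networks(cfg, el)
  counts <- simulate_streamline_counts(tr, areas, fp_rate = 0, seed = 8)
  net <- binarize_structural(streamline_density(counts, areas))
  expect_identical(unclass(net), unclass(tr$sc_true))
  # streamline-level round trip: counting simulated streamlines reproduces counts
  sl <- simulate_streamlines(counts, areas, seed = 9)
  counts2 <- count_streamlines(sl, areas)
  expect_equal(unclass(counts2), unclass(counts), ignore_attr = TRUE)
})

test_that("false-positive streamline counts add roughly fp_rate spurious edges", {
  cfg <- sim_config("sEEG", n_shafts = 2, contacts_per_shaft = 8,
                    d_sc = 0.15, seed = 55)
  el <- simulate_electrodes(cfg)
  areas <- build_contact_areas(el, simulate_boundary_mask(el, cfg))
  tr <- simulate_truth_networks(cfg, el)
  n_non_edges <- choose(16, 2) - sum(tr$sc_true) / 2
  counts <- simulate_streamline_counts(tr, areas, fp_rate = 0.05, seed = 77)
  net <- binarize_structural(streamline_density(counts, areas))
  spurious <- (sum(net) - sum(tr$sc_true)) / 2
  expect_true(all(unclass(net)[unclass(tr$sc_true)]))  # no true edge lost
  # binomial(n_non_edges, 0.05): expect ~5, allow a wide deterministic band
  expect_gte(spurious, 1)
  expect_lte(spurious, qbinom(0.9999, n_non_edges, 0.05))
})
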