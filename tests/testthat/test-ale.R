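test_that("ma_map matches direct kernel evaluation at the peak", {
  g <- cube_grid(31, 2)
  fwhm <- 8
  m <- ma_map(matrix(c(0, 0, 0), 1), g, fwhm)

  # brute-force oracle: normalized Gaussian over the full voxel lattice
  sigma <- fwhm / sqrt(8 * log(2))
  xyz <- voxel_centers(g)
  k <- exp(-rowSums(xyz^2) / (2 * sigma^2))
  expect_equal(max(m), max(k) / sum(k), tolerance = 1e-6)
  peak_vox <- world_to_voxel(g, c(0, 0, 0)) + 1
  expect_equal(m[peak_vox[1], peak_vox[2], peak_vox[3]], max(m))

  # truncation keeps at least 1 - 1e-10 of the discretized mass
  expect_gt(sum(m[m > 0]), (1 - 1e-10) * 1)

  # far voxels are numerically zero
  far <- voxel_centers(g)[, 1] < -28
  expect_true(all(m[array(far, dim = g$shape)] < 1e-12))
})

test_that("ma_map takes the max over foci and respects the mask", {
  g <- cube_grid(25, 2)
  one <- ma_map(matrix(c(0, 0, 0), 1), g, 8)
  dup <- ma_map(rbind(c(0, 0, 0), c(0, 0, 0)), g, 8)
  expect_equal(dup, one)

  g2 <- g
  g2$mask[1:12, , ] <- FALSE
  clipped <- ma_map(matrix(c(0, 0, 0), 1), g2, 8)
  expect_true(all(clipped[1:12, , ] == 0))
  expect_equal(clipped[13:25, , ], one[13:25, , ])

  expect_warning(ma_map(matrix(c(500, 0, 0), 1), g, 8), "outside the grid")
})

test_that("ale_union is the complement-product and is monotone", {
  expect_equal(ale_union(list(array(0.5, c(2, 2, 2)))), array(0.5, c(2, 2, 2)))
  expect_equal(ale_union(list(array(0.5, c(1, 1, 1)), array(0.5, c(1, 1, 1))))[1],
               0.75)
  expect_equal(ale_union(list(array(0.1, c(1, 1, 1)), array(0.2, c(1, 1, 1)),
                              array(0.3, c(1, 1, 1))))[1],
               1 - 0.9 * 0.8 * 0.7)
  expect_error(ale_union(list()), "empty")

  # properties on random maps: range, order invariance, monotonicity
  set.seed(7)
  maps <- lapply(1:4, function(i) array(stats::runif(27, 0, 0.5), c(3, 3, 3)))
  a <- ale_union(maps)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(ale_union(rev(maps)), a)
  expect_true(all(ale_union(maps[1:3]) <= a + 1e-12))
})

test_that("find_clusters agrees with a flood-fill oracle", {
  # corner-touching voxels: one 26-component, two 6-components
  v <- array(FALSE, c(3, 3, 3))
  v[1, 1, 1] <- TRUE; v[2, 2, 2] <- TRUE
  expect_length(find_clusters(v, 26), 1L)
  expect_length(find_clusters(v, 6), 2L)
  expect_length(find_clusters(array(FALSE, c(4, 4, 4))), 0L)

  set.seed(11)
  for (conn in c(26, 6)) {
    vol <- array(stats::runif(512) < 0.35, c(8, 8, 8))
    got <- canonical_components(attr(find_clusters(vol, conn), "labels"))
    want <- canonical_components(flood_fill_labels(vol, conn))
    expect_identical(got, want)
  }
})

test_that("voxel_null matches enumeration on a two-voxel mask", {
  # two-voxel mask: relocation can only put the focus on voxel 1 or voxel 2,
  # each with probability 1/2; enumerating both placements gives p = 1 at the
  # off-peak voxel and p -> 1/2 at the peak voxel
  g <- cube_grid(2, 2)
  g$mask[] <- FALSE
  g$mask[1, 1, 1] <- TRUE
  g$mask[2, 1, 1] <- TRUE
  tab <- parse_foci_table(data.frame(
    study_id = "s", task = "t", n_subjects = 10, space = "MNI",
    x = voxel_to_world(g, c(0, 0, 0))[1], y = voxel_to_world(g, c(0, 0, 0))[2],
    z = voxel_to_world(g, c(0, 0, 0))[3]))
  res <- voxel_null(tab, g, kernel_fwhm = 4, n_perm = 400, seed = 5)
  expect_equal(res$p[2, 1, 1], 1)           # off-peak: every placement >= tail value
  expect_equal(res$p[1, 1, 1], 0.5, tolerance = 0.08)  # peak: about half
  # plus-one estimator lower bound
  expect_true(all(res$p >= 1 / 401))
  # ALE = 0 voxels have p exactly 1
  expect_true(all(res$p[res$ale == 0] == 1))
})

test_that("voxel_null p decreases with observed ALE and respects the bound", {
  g <- cube_grid(21, 2)
  tab <- gen_foci(loci = rbind(c(0, 0, 0)), n_studies = 6, jitter_sigma = 2,
                  grid = g, seed = 3)
  res <- voxel_null(tab, g, kernel_fwhm = 6, n_perm = 150, seed = 9)
  o <- order(res$ale[res$ale > 0])
  p <- res$p[res$ale > 0][o]
  # monotone trend up to Monte-Carlo granularity: p at high ALE never exceeds
  # p at low ALE by more than the estimator step
  expect_true(all(p[length(p)] <= p + 1e-12))
  expect_equal(min(res$p), 1 / 151, tolerance = 1e-12)
})

test_that("cluster_inference recovers planted structure and is deterministic", {
  g <- mni_grid(spacing = 4)
  tab <- gen_foci(loci = rbind(c(-30, 20, 0), c(10, -40, 30)), n_studies = 20,
                  jitter_sigma = 4, grid = g, seed = 2)
  params <- list(n_perm = 150, voxel_p_threshold = 0.001, kernel_fwhm = 8,
                 rng_seed = 3)
  res <- cluster_inference(tab, g, params)
  expect_identical(nrow(res$clusters), 2L)
  peaks <- as.matrix(res$clusters[, c("peak_x", "peak_y", "peak_z")])
  d1 <- sqrt(rowSums(sweep(peaks, 2, c(-30, 20, 0))^2))
  d2 <- sqrt(rowSums(sweep(peaks, 2, c(10, -40, 30))^2))
  expect_true(all(pmin(d1, d2) <= 6))

  # bit-identical rerun under the same seed
  res2 <- cluster_inference(tab, g, params)
  expect_identical(res$ale, res2$ale)
  expect_identical(res$clusters, res2$clusters)
  expect_identical(res$null_max_size, res2$null_max_size)

  # every cluster voxel sits at or above the pooled cluster-forming cutoff
  expect_true(all(res$ale[res$labels > 0] >= res$forming_cutoff))

  # an extreme one-locus table yields exactly one significant cluster there
  tab1 <- gen_foci(loci = rbind(c(-30, 20, 0)), n_studies = 20,
                   jitter_sigma = 1, grid = g, seed = 4)
  res1 <- cluster_inference(tab1, g, params)
  expect_identical(nrow(res1$clusters), 1L)
  expect_lt(sqrt(sum((unlist(res1$clusters[1, c("peak_x", "peak_y", "peak_z")]) -
                        c(-30, 20, 0))^2)), 6)
})

test_that("cluster_inference validates its parameters", {
  g <- cube_grid(9, 2)
  tab <- gen_foci(loci = rbind(c(0, 0, 0)), n_studies = 2, grid = g, seed = 1)
  expect_error(cluster_inference(tab, g, list(voxel_p_threshold = 0)), "voxel_p")
  expect_error(cluster_inference(tab, g, list(n_perm = 0)), "n_perm")
  expect_error(voxel_null(tab, g, kernel_fwhm = 6, n_perm = 0), "n_perm")
})

test_that("per-study kernel widths shrink with sample size", {
  fw <- fwhm_from_sample_size(c(10, 20, 100))
  expect_true(all(diff(fw) < 0))
  expect_true(all(fw > 8 & fw < 13))
})

test_that("ALE and p maps round-trip through NIfTI output", {
  g <- cube_grid(15, 2)
  tab <- gen_foci(loci = rbind(c(0, 0, 0)), n_studies = 4, jitter_sigma = 2,
                  grid = g, seed = 6)
  res <- cluster_inference(tab, g, list(n_perm = 60, voxel_p_threshold = 0.01,
                                        kernel_fwhm = 8, rng_seed = 1))
  dir <- tempfile()
  write_ale_result(res, dir)
  back <- read_nifti(file.path(dir, "ale.nii.gz"))
  expect_equal(array(back$data, dim = g$shape), res$ale, tolerance = 1e-6)
  expect_equal(back$affine, g$affine, tolerance = 1e-5)
  expect_true(file.exists(file.path(dir, "clusters.csv")))
})
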