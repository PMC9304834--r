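test_that("gen_foci plants loci with controlled jitter, deterministically", {
  g <- mni_grid(spacing = 4)
  loci <- rbind(c(-20, 10, 0), c(20, -30, 20))
  tab <- gen_foci(loci, n_studies = 10, jitter_sigma = 0,
                  foci_per_study_per_locus = 1, grid = g, seed = 3)
  expect_identical(n_studies(tab), 10L)
  expect_identical(nrow(tab), 20L)
  # zero jitter: planted foci sit exactly on the loci
  expect_true(all(tab[seq(1, 20, 2), c("x", "y", "z")] ==
                    matrix(loci[1, ], 10, 3, byrow = TRUE)))

  # determinism / seed sensitivity
  expect_identical(gen_foci(loci, n_studies = 10, grid = g, seed = 3)$x,
                   gen_foci(loci, n_studies = 10, grid = g, seed = 3)$x)
  expect_false(identical(gen_foci(loci, n_studies = 10, grid = g, seed = 4)$x,
                         gen_foci(loci, n_studies = 10, grid = g, seed = 3)$x))

  # law of large numbers: per-locus sample means approach the loci
  big <- gen_foci(loci, n_studies = 35, jitter_sigma = 4,
                  foci_per_study_per_locus = 4, grid = g, seed = 5)
  l1 <- big[rep(rep(c(TRUE, FALSE), each = 4), 35), c("x", "y", "z")]
  expect_lt(sqrt(sum((colMeans(l1) - loci[1, ])^2)), 1.5)

  # subject counts land in the requested range
  expect_true(all(big$n_subjects >= 14 & big$n_subjects <= 255))
})

test_that("gen_parcellation builds mirrored disjoint spheres with exact volumes", {
  g <- cube_grid(61, 2)
  parc <- gen_parcellation(g, salience_regions(), radius = 3)
  expect_identical(nrow(parc$regions), 18L)
  expect_identical(sort(unique(as.vector(parc$labels[parc$labels > 0]))), 1:18)

  # parcel volumes equal brute-force lattice counts around each center
  centers <- rbind(as.matrix(salience_regions()[, c("x", "y", "z")]),
                   as.matrix(salience_regions()[, c("x", "y", "z")]) %*%
                     diag(c(-1, 1, 1)))
  xyz <- voxel_centers(g)
  for (l in c(1, 5, 9, 10, 18)) {
    want <- sum(rowSums(sweep(xyz, 2, centers[l, ])^2) <= 9)
    expect_identical(sum(parc$labels == l), want)
  }

  # mirrored pairs have identical volumes
  for (k in 1:9) {
    expect_identical(sum(parc$labels == k), sum(parc$labels == k + 9L))
  }

  # overlapping parcels are rejected with the offending pair named
  bad <- data.frame(region = c("P", "Q"), cluster = "dlpfc",
                    x = c(-10, -12), y = 0, z = 0)
  expect_error(gen_parcellation(g, bad, radius = 4), "overlap.*P.*Q")

  # region table round-trips through JSON
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(parc$regions, js, dataframe = "rows")
  back <- as.data.frame(jsonlite::read_json(js, simplifyVector = TRUE))
  expect_equal(back$region, parc$regions$region)
  expect_equal(back$label, parc$regions$label)
})

test_that("bundle centerlines are trackable and tubes stay within radius", {
  p <- c(-20, -10, 0); q <- c(-20, 14, 6)
  for (kind in c("straight", "arc", "u_shape")) {
    cl <- bundle_centerline(kind, p, q, bulge_mm = 8, bulge_dir = c(0, 0, 1))
    # unit tangents
    expect_equal(rowSums(cl$tangents^2), rep(1, nrow(cl$tangents)),
                 tolerance = 1e-9)
    # endpoints at the requested points
    expect_equal(cl$points[1, ], p, tolerance = 0.3)
    expect_equal(cl$points[nrow(cl$points), ], q, tolerance = 0.3)
    # max direction change over a 1.5 mm step stays under 45 degrees when the
    # curvature radius is at least 3 steps
    r_curv <- salnet:::bundle_curvature_radius(kind, p, q, 8)
    expect_gte(r_curv, 3 * 1.5)
    expect_lt(1.5 / r_curv, 45 * pi / 180)  # per-step turn at tracking scale
  }

  g <- cube_grid(61, 1)
  cl <- bundle_centerline("u_shape", p, q, 8, c(0, 0, 1))
  rast <- salnet:::rasterize_tube(g, cl$points, cl$tangents, 3)
  xyz <- voxel_centers(g)[rast$voxel, , drop = FALSE]
  d <- vapply(seq_len(nrow(xyz)), function(i) {
    min(sqrt(colSums((t(cl$points) - xyz[i, ])^2)))
  }, numeric(1))
  expect_true(all(d <= 3 + 1e-9))
  expect_equal(rowSums(rast$tangent^2), rep(1, nrow(rast$tangent)),
               tolerance = 1e-9)
})

test_that("gen_cohort presence plan follows its probabilities and seeds", {
  g <- cube_grid(61, 1)
  specs <- data.frame(region = c("A", "B"), cluster = "insular_opercular",
                      x = c(-20, -20), y = c(-12, 12), z = 0)
  parc <- gen_parcellation(g, specs, radius = 5)
  always <- bundle_spec("straight", "A", "B", presence_prob = 1)
  never <- bundle_spec("straight", "A", "B", presence_prob = 0)

  co1 <- gen_cohort(list(always), parc, n_subjects = 6, seed = 2)
  expect_true(all(co1$truth$present))
  co0 <- gen_cohort(list(never), parc, n_subjects = 6, seed = 2)
  expect_false(any(co0$truth$present))

  expect_identical(gen_cohort(list(always), parc, 4, seed = 7)$plan,
                   gen_cohort(list(always), parc, 4, seed = 7)$plan)
  expect_error(gen_cohort(list(bundle_spec("straight", "A", "nope")), parc, 2),
               "not in parcellation")

  # a bundle whose tube leaves the grid is refused
  edge_specs <- data.frame(region = c("E", "F"), cluster = "dlpfc",
                           x = c(-29, -29), y = c(-25, 25), z = 0)
  parc_edge <- gen_parcellation(g, edge_specs, radius = 2)
  co <- gen_cohort(list(bundle_spec("straight", "E", "F", tube_radius_mm = 6)),
                   parc_edge, n_subjects = 1, seed = 1)
  expect_error(cohort_field(co, 1), "exits the grid")
})

test_that("an absent bundle produces an empty field; a present one a tube", {
  g <- cube_grid(41, 1)
  specs <- data.frame(region = c("A", "B"), cluster = "middle_cingulate",
                      x = c(-12, -12), y = c(-8, 8), z = 0)
  parc <- gen_parcellation(g, specs, radius = 4)
  co0 <- gen_cohort(list(bundle_spec("straight", "A", "B", presence_prob = 0)),
                    parc, 1, seed = 1)
  f0 <- cohort_field(co0, 1)
  expect_identical(sum(f0$n_peaks), 0L)

  co1 <- gen_cohort(list(bundle_spec("straight", "A", "B", presence_prob = 1)),
                    parc, 1, seed = 1)
  f1 <- cohort_field(co1, 1)
  expect_gt(sum(f1$n_peaks > 0), 100)
  # tangents along a straight A-B bundle point along +y
  got <- f1$peaks[, 1, 9, 21, 21]    # voxel at (-12, 0, 0)
  expect_equal(abs(got), c(0, 1, 0), tolerance = 1e-9)
})
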