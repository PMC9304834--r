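test_that("mean_present and mean_all follow their definitions", {
  expect_equal(mean_present(c(0, 0, 0)), list(n_present = 0L, mean = NA_real_),
               ignore_attr = TRUE)
  expect_equal(mean_present(c(50, 60, 70, 0, 0)),
               list(n_present = 3L, mean = 60), ignore_attr = TRUE)

  # random vectors vs a brute-force filter-and-average oracle
  set.seed(21)
  for (i in 1:20) {
    v <- stats::rpois(12, 2)
    mp <- mean_present(v)
    expect_identical(mp$n_present, sum(v > 0))
    if (mp$n_present > 0) expect_equal(mp$mean, sum(v) / sum(v > 0))
  }

  expect_equal(mean_all(56.67, 3, 25), 6.8004)
  expect_equal(round(mean_all(1614.92, 24, 25), 2), 1550.32)
  expect_equal(mean_all(123.4, 25, 25), 123.4)
  expect_equal(mean_all(NA_real_ * 0, 0, 25), 0)
  expect_error(mean_all(5, 3, 0), "positive")
})

test_that("laterality_index matches the published rows and is antisymmetric", {
  expect_equal(round(laterality_index(1246.72, 1216), 2), -0.01)
  expect_equal(laterality_index(2, 0), -1)
  expect_equal(laterality_index(7, 7), 0)
  expect_true(is.na(laterality_index(0, 0)))
  expect_error(laterality_index(-1, 2), "nonnegative")
  set.seed(4)
  l <- stats::runif(10, 0, 100); r <- stats::runif(10, 0, 100)
  expect_equal(laterality_index(l, r), -laterality_index(r, l))
  expect_true(all(abs(laterality_index(l, r)) <= 1))
})

test_that("rank_sum_p: exact enumeration and approximation agree with oracles", {
  expect_equal(rank_sum_p(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_warning(p1 <- rank_sum_p(c(2, 2), c(2, 2)), "tied")
  expect_equal(p1, 1)

  # identical samples -> no evidence either way
  expect_equal(rank_sum_p(1:3, 1:3), 1)

  # small-n exact route vs wilcox.test's exact p (no ties)
  set.seed(31)
  for (i in 1:20) {
    a <- sample(1:100, 5); b <- sample(101:200, 6) - sample(0:120, 6)
    if (length(unique(c(a, b))) < 11) next
    want <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(rank_sum_p(a, b), want, tolerance = 1e-12)
  }

  # large-n tie-corrected normal route vs wilcox.test (continuity off)
  for (i in 1:10) {
    a <- stats::rpois(15, 4); b <- stats::rpois(18, 5)
    want <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(rank_sum_p(a, b), want, tolerance = 1e-9)
  }

  # at n = 8 per group the approximate route tracks full enumeration closely
  enum_p <- function(a, b) {
    r <- rank(c(a, b)); m <- length(a)
    mu <- m * (length(b) + m + 1) / 2
    w <- sum(r[seq_len(m)])
    ws <- colSums(matrix(r[utils::combn(length(r), m)], nrow = m))
    mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  }
  for (i in 1:5) {
    a <- stats::runif(8); b <- stats::runif(8) + 0.2
    expect_lt(abs(rank_sum_p(a, b) - enum_p(a, b)), 0.02)
  }
  expect_error(rank_sum_p(numeric(0), 1:3), "non-empty")
})

test_that("classify_edge reproduces the fiber-type taxonomy", {
  cmap <- stats::setNames(salience_regions()$cluster, salience_regions()$region)
  expect_identical(classify_edge("FOP4", "SCEF", cmap), "FAT")
  expect_identical(classify_edge("AVI", "MI", cmap), "U_fiber")
  expect_identical(classify_edge("a24pr", "46", cmap), "Other")
  expect_error(classify_edge("AVI", "nope", cmap), "unknown cluster")

  # all 36 pairs of the 9-region model: 16 FAT, 12 U-fiber, 8 Other
  pairs <- utils::combn(salience_regions()$region, 2)
  types <- apply(pairs, 2, function(p) classify_edge(p[1], p[2], cmap))
  expect_equal(as.integer(table(types)[c("FAT", "U_fiber", "Other")]),
               c(16L, 12L, 8L))

  # and the packaged strength table prints the identical column
  edges <- salience_edge_table()
  got <- mapply(classify_edge, edges$region_a, edges$region_b,
                MoreArgs = list(cluster_map = cmap))
  expect_identical(unname(got), edges$fiber_type)
})

test_that("the packaged strength table is internally consistent", {
  edges <- salience_edge_table()
  expect_identical(nrow(edges), 36L)

  # the one row whose printed left mean_all contradicts its presence count
  bad <- edges$region_a == "a32pr" & edges$region_b == "p32pr"

  # mean_all recomputed from (mean_present, n_present, N = 25) matches print
  for (h in c("left", "right")) {
    mp <- edges[[paste0(h, "_mean_present")]]
    np <- edges[[paste0(h, "_n_present")]]
    ma <- edges[[paste0(h, "_mean_all")]]
    rows <- if (h == "left") !bad else rep(TRUE, nrow(edges))
    expect_equal(round(mean_all(mp[rows], np[rows], 25), 2), round(ma[rows], 2),
                 tolerance = 1e-8)
  }

  # laterality index recomputed from the printed mean_all pair matches print
  li <- laterality_index(edges$left_mean_all, edges$right_mean_all)
  expect_equal(round(li, 2), edges$li, tolerance = 1e-8)
})

test_that("edge_stats aggregates a toy cohort correctly", {
  cmap <- c(A = "insular_opercular", B = "middle_cingulate", C = "insular_opercular")
  counts <- expand.grid(subject = paste0("s", 1:4),
                        region_a = "A", region_b = c("B", "C"),
                        hemisphere = c("L", "R"), stringsAsFactors = FALSE)
  counts$count <- 0L
  pick <- function(b, h) counts$region_b == b & counts$hemisphere == h
  counts$count[pick("B", "L")] <- c(10L, 0L, 20L, 0L)
  counts$count[pick("B", "R")] <- c(30L, 30L, 0L, 0L)
  es <- edge_stats(counts, cmap, n_total = 4)
  ab <- es[es$region_b == "B", ]
  expect_equal(ab$left_n_present, 2L)
  expect_equal(ab$left_mean_present, 15)
  expect_equal(ab$left_mean_all, 7.5)
  expect_equal(ab$right_mean_all, 15)
  expect_equal(ab$li, laterality_index(7.5, 15))
  expect_identical(ab$fiber_type, "FAT")
  # invariant: mean_all = mean_present * n_present / N
  expect_equal(ab$left_mean_all, ab$left_mean_present * ab$left_n_present / 4,
               tolerance = 1e-9)
  ac <- es[es$region_b == "C", ]
  expect_true(is.na(ac$li) && is.na(ac$p_value))
  expect_identical(ac$fiber_type, "U_fiber")
})

test_that("build_network applies the minimum-strength filter", {
  cmap <- stats::setNames(salience_regions()$cluster, salience_regions()$region)
  edges <- salience_edge_table()
  es <- structure(edges, class = c("edge_stats", "data.frame"))
  net <- build_network(es, 10)
  # the weak pair from the discussion (left 3.76, right 0.16) is dropped
  expect_false(any(net$edges$region_a == "MI" & net$edges$region_b == "p32pr"))
  # threshold 0 retains everything
  expect_identical(nrow(build_network(es, 0)$edges), nrow(edges))
  # brute-force filter oracle
  keep <- edges$left_mean_all >= 10 | edges$right_mean_all >= 10
  expect_identical(nrow(net$edges), sum(keep))
  expect_error(build_network(es, -1))
})

test_that("report formatting rounds half-up and renders undefined LI as '-'", {
  es <- data.frame(region_a = "A", region_b = "B", fiber_type = "FAT",
                   left_n_present = 1L, left_mean_present = 2.005,
                   left_mean_all = 0.125, right_n_present = 0L,
                   right_mean_present = NA_real_, right_mean_all = 0,
                   li = NA_real_, p_value = NA_real_)
  out <- format_edge_stats(es)
  expect_equal(out$left_mean_all, 0.13)   # half-up, not banker's rounding
  expect_identical(out$li, "-")
})

test_that("a network model exports to GraphML", {
  edges <- salience_edge_table()
  es <- structure(edges, class = c("edge_stats", "data.frame"))
  net <- build_network(es, 10)
  path <- tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(g), 9)
  expect_equal(igraph::gsize(g), nrow(net$edges))
})

test_that("fixture_tables verifies checksums and returns both tables", {
  fx <- fixture_tables()
  expect_identical(n_studies(fx$foci), 35L)
  expect_identical(nrow(fx$edges), 36L)
  row <- fx$edges[fx$edges$region_a == "a24pr" & fx$edges$region_b == "a32pr", ]
  expect_equal(row$left_mean_all, 1246.72)
})
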