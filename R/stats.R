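#' Mean tract count over subjects showing a connection
#'
#' @param counts integer vector of per-subject tract counts.
#' @return list `n_present` (subjects with count > 0) and `mean` (average over
#'   those subjects; `NA` when none show the connection).
#' @export
mean_present <- function(counts) {
  stopifnot(length(counts) >= 1)
  present <- counts > 0
  n <- sum(present)
  list(n_present = n, mean = if (n == 0) NA_real_ else mean(counts[present]))
}

#' Mean tract count over all subjects
#'
#' Recovers the all-subjects average from the when-present average and the
#' presence count: `mean_present * n_present / N` (0 when never present).
#'
#' @param mean_present_value average over subjects showing the connection.
#' @param n_present number of those subjects.
#' @param n_total cohort size N (> 0).
#' @export
mean_all <- function(mean_present_value, n_present, n_total) {
  if (any(n_total <= 0)) stop("cohort size N must be positive")
  stopifnot(all(n_present >= 0), all(n_present <= n_total))
  out <- ifelse(n_present == 0, 0, mean_present_value * n_present / n_total)
  as.numeric(out)
}

#' Laterality index
#'
#' `(right - left) / (right + left)` of mean tract counts: -1 purely left
#' lateralized, +1 purely right, 0 symmetric; undefined (NA) when both are 0.
#'
#' @param left_mean_all,right_mean_all nonnegative mean counts.
#' @export
laterality_index <- function(left_mean_all, right_mean_all) {
  if (any(left_mean_all < 0) || any(right_mean_all < 0)) {
    stop("mean tract counts must be nonnegative")
  }
  s <- left_mean_all + right_mean_all
  ifelse(s == 0, NA_real_, (right_mean_all - left_mean_all) / s)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact p by full enumeration of rank splits when the combined sample size
#' is at most 12; otherwise the normal approximation with tie and continuity
#' corrections. No multiplicity adjustment is applied. Degenerate all-tied
#' samples return p = 1 with a warning.
#'
#' @param left_counts,right_counts non-empty numeric samples.
#' @export
rank_sum_p <- function(left_counts, right_counts) {
  m <- length(left_counts); n <- length(right_counts)
  if (m == 0 || n == 0) stop("both samples must be non-empty")
  pooled <- c(left_counts, right_counts)
  if (length(unique(pooled)) == 1) {
    warning("all observations tied; rank-sum p set to 1")
    return(1)
  }
  r <- rank(pooled)
  w <- sum(r[seq_len(m)])
  mu <- m * (n + m + 1) / 2
  if (m + n <= 12) {
    splits <- utils::combn(m + n, m)
    ws <- colSums(matrix(r[splits], nrow = m))
    mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  } else {
    ties <- table(pooled)
    N <- m + n
    sigma2 <- m * n * (N + 1) / 12 -
      m * n * sum(ties^3 - ties) / (12 * N * (N - 1))
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Fiber-type taxonomy of a region pair
#'
#' Classifies an edge by the anatomical clusters of its two regions: any pair
#' touching the dorsolateral prefrontal cluster is "Other"; a within-cluster
#' pair is a short association "U_fiber"; an insular-opercular to
#' middle-cingulate pair is carried by the frontal aslant tract ("FAT").
#'
#' @param region_a,region_b region names.
#' @param cluster_map named character vector region -> cluster; clusters must
#'   be named `insular_opercular`, `middle_cingulate`, `dlpfc`.
#' @return one of "FAT", "U_fiber", "Other".
#' @export
classify_edge <- function(region_a, region_b, cluster_map) {
  ca <- unname(cluster_map[region_a])
  cb <- unname(cluster_map[region_b])
  if (length(ca) != 1 || is.na(ca)) stop("unknown cluster for region ", region_a)
  if (length(cb) != 1 || is.na(cb)) stop("unknown cluster for region ", region_b)
  known <- c("insular_opercular", "middle_cingulate", "dlpfc")
  if (!ca %in% known || !cb %in% known) {
    stop("unknown cluster name: ", paste(setdiff(c(ca, cb), known), collapse = ", "))
  }
  if (ca == "dlpfc" || cb == "dlpfc") return("Other")
  if (ca == cb) return("U_fiber")
  "FAT"
}

#' The nine-region salience network model
#'
#' Region table of the network: four anterior insular/frontal-opercular
#' areas (AVI, MI, FOP4, FOP5), four middle-cingulate areas (a24pr, a32pr,
#' p32pr, SCEF), and dorsolateral prefrontal area 46, with representative
#' left-hemisphere MNI centers.
#'
#' @return data.frame with `region`, `cluster`, `x`, `y`, `z`.
#' @export
salience_regions <- function() {
  data.frame(
    region = c("AVI", "MI", "FOP4", "FOP5", "a24pr", "a32pr", "p32pr", "SCEF", "46"),
    cluster = c(rep("insular_opercular", 4), rep("middle_cingulate", 4), "dlpfc"),
    x = c(-33, -39, -40, -39, -6, -6, -7, -6, -33),
    y = c(22, 7, 13, 22, 10, 27, 16, 9, 34),
    z = c(-1, -3, 5, 6, 36, 34, 39, 51, 34),
    stringsAsFactors = FALSE
  )
}

#' Edge statistics over a cohort of subject connectomes
#'
#' Aggregates per-subject tract counts into one row per region pair:
#' per-hemisphere presence count, when-present and all-subjects averages,
#' the laterality index from the all-subjects averages, an uncorrected
#' two-sided rank-sum p comparing the per-subject left and right counts
#' (zeros included), and the fiber-type class.
#'
#' @param counts data.frame with columns `subject`, `region_a`, `region_b`,
#'   `hemisphere`, `count` (e.g. rbind of [subject_connectome()] results with
#'   a subject column), or a list of `subject_connectome`s.
#' @param cluster_map named vector region -> cluster for [classify_edge()].
#' @param n_total cohort size N; defaults to the number of distinct subjects.
#' @return An `edge_stats` data.frame.
#' @export
edge_stats <- function(counts, cluster_map, n_total = NULL) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- do.call(rbind, lapply(counts, function(sc) {
      cbind(subject = attr(sc, "subject_id"), as.data.frame(sc))
    }))
  }
  stopifnot(all(c("subject", "region_a", "region_b", "hemisphere", "count")
                %in% names(counts)))
  subjects <- unique(counts$subject)
  if (is.null(n_total)) n_total <- length(subjects)
  pairs <- unique(counts[, c("region_a", "region_b")])
  pairs <- pairs[order(pairs$region_a, pairs$region_b), , drop = FALSE]

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$region_a[i]; b <- pairs$region_b[i]
    per_h <- lapply(c("L", "R"), function(h) {
      sub <- counts[counts$region_a == a & counts$region_b == b &
                      counts$hemisphere == h, ]
      cnt <- sub$count[match(subjects, sub$subject)]
      cnt[is.na(cnt)] <- 0
      mp <- mean_present(cnt)
      list(counts = cnt, n = mp$n_present, mean_present = mp$mean,
           mean_all = mean_all(ifelse(is.na(mp$mean), 0, mp$mean),
                               mp$n_present, n_total))
    })
    L <- per_h[[1]]; R <- per_h[[2]]
    p <- if (all(c(L$counts, R$counts) == 0)) NA_real_ else
      suppressWarnings(rank_sum_p(L$counts, R$counts))
    data.frame(
      region_a = a, region_b = b,
      fiber_type = classify_edge(a, b, cluster_map),
      left_n_present = L$n, left_mean_present = L$mean_present,
      left_mean_all = L$mean_all,
      right_n_present = R$n, right_mean_present = R$mean_present,
      right_mean_all = R$mean_all,
      li = laterality_index(L$mean_all, R$mean_all),
      p_value = p,
      stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("edge_stats", "data.frame"),
            n_total = n_total)
}

#' Build the network model from edge statistics
#'
#' Retains edges whose all-subjects average reaches `min_edge_strength`
#' tracts in at least one hemisphere (pairs with fewer connections are left
#' out of the schematic model).
#'
#' @param stats an `edge_stats` data.frame.
#' @param min_edge_strength minimum mean tract count (default 10).
#' @return A `network_model`: list with `edges` (retained rows) and
#'   `regions`.
#' @export
build_network <- function(stats, min_edge_strength = 10) {
  stopifnot(min_edge_strength >= 0)
  keep <- stats$left_mean_all >= min_edge_strength |
    stats$right_mean_all >= min_edge_strength
  structure(list(
    edges = stats[keep, , drop = FALSE],
    regions = sort(unique(c(stats$region_a, stats$region_b))),
    min_edge_strength = min_edge_strength
  ), class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d regions, %d edges (min strength %.3g)\n",
              length(x$regions), nrow(x$edges), x$min_edge_strength))
  invisible(x)
}

#' Format an edge-stats table for reporting
#'
#' Rounds to 2 decimals (half-up, matching conventional table formatting)
#' and renders undefined laterality indices as "-".
#'
#' @param stats an `edge_stats` data.frame.
#' @export
format_edge_stats <- function(stats) {
  half_up <- function(x, d = 2) ifelse(is.na(x), NA, trunc(abs(x) * 10^d + 0.5) / 10^d * sign(x))
  out <- as.data.frame(stats)
  for (col in c("left_mean_present", "left_mean_all", "right_mean_present",
                "right_mean_all", "li", "p_value")) {
    out[[col]] <- half_up(out[[col]])
  }
  out$li <- ifelse(is.na(out$li), "-", sprintf("%.2f", out$li))
  out
}

#' Export a network model as GraphML
#'
#' Node list plus weighted edge list (per-hemisphere mean strengths as edge
#' attributes) for downstream schematic rendering.
#'
#' @param model a [build_network()] result.
#' @param path output `.graphml` file.
#' @export
write_network_graphml <- function(model, path) {
  e <- model$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$region_a, to = e$region_b,
               fiber_type = e$fiber_type,
               weight = pmax(e$left_mean_all, e$right_mean_all),
               left_mean_all = e$left_mean_all,
               right_mean_all = e$right_mean_all),
    directed = FALSE,
    vertices = data.frame(name = model$regions))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Packaged connection-strength fixture
#'
#' The 36-row transcription of the salience-network connection table shipped
#' with the package (per-hemisphere presence counts, when-present and
#' all-subjects averages for a 25-subject cohort, laterality index, and
#' rank-sum p-value).
#'
#' @return data.frame of 36 edges.
#' @export
salience_edge_table <- function() {
  utils::read.delim(system.file("extdata", "salience_edges_table2.tsv",
                                package = "salnet", mustWork = TRUE),
                    sep = "\t", stringsAsFactors = FALSE)
}

#' Packaged fixtures: foci table and edge table
#'
#' Returns both package fixtures after verifying their checksums, so tests
#' fail loudly if the packaged transcriptions are altered.
#'
#' @return list with `foci` (a `foci_table`) and `edges` (data.frame).
#' @export
fixture_tables <- function() {
  paths <- c(
    foci = system.file("extdata", "salience_foci_table1.tsv", package = "salnet",
                       mustWork = TRUE),
    edges = system.file("extdata", "salience_edges_table2.tsv", package = "salnet",
                        mustWork = TRUE))
  sums <- stats::setNames(unname(tools::md5sum(paths)), names(paths))
  expected <- c(foci = "8293f7b9b0c91d383b05839cc8127d24", edges = "3a20b61d2c7f4c80e28d220aaca61ed6")
  for (k in names(expected)) {
    if (!identical(unname(sums[[k]]), unname(expected[[k]]))) {
      stop("fixture checksum mismatch for ", k, " table")
    }
  }
  list(foci = parse_foci_table(paths[["foci"]]), edges = salience_edge_table())
}
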