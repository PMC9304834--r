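#' Orientation field
#'
#' Per-voxel fiber peak directions (up to 3 unit vectors per voxel) plus a
#' brain mask on a [voxel_grid()]. This is the reconstruction-level input the
#' tracker consumes; raw diffusion reconstruction is out of scope.
#'
#' @param grid a [voxel_grid()].
#' @param peaks numeric array with dim `c(3, max_peaks, shape)`; columns need
#'   not be normalized, zero columns mean "no peak".
#' @param mask optional logical array (defaults to the grid mask).
#' @export
orientation_field <- function(grid, peaks, mask = NULL) {
  dp <- dim(peaks)
  stopifnot(length(dp) == 5L, dp[1] == 3L, identical(dp[3:5], grid$shape))
  if (is.null(mask)) mask <- grid$mask
  mask <- array(as.logical(mask), dim = grid$shape)
  maxp <- dp[2]
  nv <- prod(grid$shape)
  pm <- matrix(peaks, nrow = 3L * maxp)
  norms <- sqrt(matrix(colSums(matrix(pm^2, nrow = 3L)), nrow = maxp))
  npk <- colSums(norms > 1e-9)
  # normalize nonzero peaks to unit length
  scale <- ifelse(norms > 1e-9, 1 / norms, 0)
  pm <- pm * scale[rep(seq_len(maxp), each = 3L), , drop = FALSE]
  npk[!as.vector(mask)] <- 0L
  structure(list(grid = grid, peaks = array(pm, dim = dp),
                 n_peaks = array(as.integer(npk), dim = grid$shape),
                 max_peaks = as.integer(maxp), mask = mask),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %s grid, %d voxels with peaks (max %d per voxel)\n",
              paste(x$grid$shape, collapse = "x"), sum(x$n_peaks > 0), x$max_peaks))
  invisible(x)
}

#' Tracking parameters
#'
#' Deterministic-tracker settings. Defaults follow common fiber-tracking
#' practice for this kind of study: 45 degree angular threshold, 1.5 mm step,
#' 800 mm maximum length, streamlines shorter than 1 mm discarded, and
#' whole-brain random seeding (the full-fidelity seed count is 1e6; tests use
#' smaller counts, which scales tract counts proportionally).
#'
#' @param angular_threshold_deg halt when the direction change exceeds this.
#' @param step_mm propagation step.
#' @param max_len_mm total length budget per streamline.
#' @param min_len_mm streamlines shorter than this are excluded.
#' @param n_seeds random whole-brain seed count.
#' @param rng_seed seed for the seed draw.
#' @export
tracking_params <- function(angular_threshold_deg = 45, step_mm = 1.5,
                            max_len_mm = 800, min_len_mm = 1,
                            n_seeds = 1e6, rng_seed = 1) {
  stopifnot(step_mm > 0, angular_threshold_deg > 0, angular_threshold_deg < 90,
            min_len_mm < max_len_mm, max_len_mm > 0)
  structure(list(angular_threshold_deg = angular_threshold_deg,
                 step_mm = step_mm, max_len_mm = max_len_mm,
                 min_len_mm = min_len_mm, n_seeds = as.integer(n_seeds),
                 rng_seed = rng_seed),
            class = "tracking_params")
}

track_cpp_call <- function(field, seeds, params) {
  res <- cpp_track(field$peaks, field$n_peaks, field$mask, field$grid$shape,
                   field$max_peaks, solve(field$grid$affine),
                   matrix(seeds, ncol = 3), params$step_mm,
                   params$angular_threshold_deg, params$max_len_mm,
                   params$min_len_mm)
  res[!vapply(res, is.null, logical(1))]
}

#' Track a single streamline
#'
#' Bidirectional deterministic propagation from one seed point: the first
#' step follows the seed voxel's first peak in both senses; at each position
#' the peak minimizing the angle to the incoming direction is chosen (sign
#' disambiguated), and propagation halts on mask exit, a peak-free voxel, a
#' direction change above the angular threshold, or the length budget.
#'
#' @param field an [orientation_field()].
#' @param seed_point mm coordinate.
#' @param params a [tracking_params()].
#' @return n x 3 matrix of points (consecutive spacing `step_mm`), or `NULL`
#'   when the seed is invalid or the streamline is shorter than `min_len_mm`.
#' @export
track_one <- function(field, seed_point, params = tracking_params()) {
  res <- track_cpp_call(field, matrix(seed_point, ncol = 3), params)
  if (length(res) == 0) NULL else res[[1]]
}

#' Whole-brain deterministic tractography
#'
#' Draws `n_seeds` seed points uniformly at random inside mask voxels
#' (uniform voxel, then uniform position within the voxel) and tracks one
#' streamline per seed. Deterministic given `rng_seed`.
#'
#' @param field an [orientation_field()].
#' @param params a [tracking_params()].
#' @return list of streamline point matrices (seeds that produced no
#'   retainable streamline are dropped).
#' @export
whole_brain_track <- function(field, params = tracking_params()) {
  if (params$n_seeds < 1) stop("n_seeds must be >= 1")
  idx <- which(field$mask)
  if (length(idx) == 0) stop("empty mask")
  with_seed(params$rng_seed, {
    pick <- idx[sample.int(length(idx), params$n_seeds, replace = TRUE)]
    ijk <- arrayInd(pick, field$grid$shape) - 1L
    frac <- matrix(stats::runif(3 * params$n_seeds, -0.5, 0.5), ncol = 3)
    seeds <- voxel_to_world(field$grid, ijk + frac)
    track_cpp_call(field, seeds, params)
  })
}

streamline_length <- function(s) {
  if (is.null(s) || nrow(s) < 2) return(0)
  sum(sqrt(rowSums(diff(s)^2)))
}

# label of the voxel containing each row of a point matrix (0 outside grid)
points_to_labels <- function(points, parc) {
  ijk <- world_to_voxel(parc$grid, points)
  ok <- in_bounds(parc$grid, ijk)
  lab <- integer(nrow(ijk))
  lab[ok] <- parc$labels[linear_index(parc$grid, ijk[ok, , drop = FALSE])]
  lab
}

#' Two-ROI streamline filter
#'
#' Counts streamlines with one endpoint in `roi_a` and the other in `roi_b`
#' (the two-ROI approach for isolating a tract); streamlines that intersect
#' any exclusion ROI are removed first.
#'
#' @param streamlines list of point matrices.
#' @param roi_a,roi_b logical arrays on `grid`; must not overlap.
#' @param grid the [voxel_grid()] the ROIs live on.
#' @param exclusions optional logical array of exclusion voxels.
#' @return integer count.
#' @export
two_roi_filter <- function(streamlines, roi_a, roi_b, grid, exclusions = NULL) {
  if (any(roi_a & roi_b)) stop("roi_a and roi_b overlap")
  lab <- array(0L, dim = grid$shape)
  lab[roi_a] <- 1L
  lab[roi_b] <- 2L
  parc <- list(grid = grid, labels = lab)
  n <- 0L
  for (s in streamlines) {
    if (is.null(s) || nrow(s) < 2) next
    if (!is.null(exclusions)) {
      ijk <- world_to_voxel(grid, s)
      ok <- in_bounds(grid, ijk)
      if (any(exclusions[linear_index(grid, ijk[ok, , drop = FALSE])])) next
    }
    ends <- points_to_labels(s[c(1, nrow(s)), , drop = FALSE], parc)
    if (all(sort(ends) == c(1L, 2L))) n <- n + 1L
  }
  n
}

#' Per-subject connectome from one whole-brain pass
#'
#' Tracks once over the whole brain, then counts streamlines connecting every
#' unordered region pair within each hemisphere (endpoint membership by
#' voxel label). Cross-hemispheric endpoints are not counted; the model
#' treats hemispheres as separate networks.
#'
#' @param field an [orientation_field()].
#' @param parc a [parcellation()] on the field grid.
#' @param params a [tracking_params()].
#' @param subject_id optional identifier carried into the result.
#' @return A `subject_connectome`: data.frame `region_a`, `region_b`,
#'   `hemisphere`, `count` covering all pairs (zeros included), with the
#'   subject id and number of retained streamlines as attributes.
#' @export
subject_connectome <- function(field, parc, params = tracking_params(),
                               subject_id = "subj") {
  regs <- parc$regions
  if (length(unique(regs$region)) < 2) stop("need at least two regions")
  streamlines <- whole_brain_track(field, params)
  ends <- vapply(streamlines, function(s) {
    points_to_labels(s[c(1, nrow(s)), , drop = FALSE], parc)
  }, integer(2))

  base <- sort(unique(regs$region))
  pairs <- utils::combn(base, 2)
  out <- do.call(rbind, lapply(c("L", "R"), function(h) {
    data.frame(region_a = pairs[1, ], region_b = pairs[2, ],
               hemisphere = h, count = 0L)
  }))
  if (length(streamlines) > 0) {
    lab2 <- regs[match(ends, regs$label), c("region", "hemisphere")]
    e1 <- lab2[seq(1, nrow(lab2), by = 2), ]
    e2 <- lab2[seq(2, nrow(lab2), by = 2), ]
    valid <- !is.na(e1$region) & !is.na(e2$region) &
      e1$hemisphere == e2$hemisphere & e1$region != e2$region
    if (any(valid)) {
      a <- pmin(e1$region[valid], e2$region[valid])
      b <- pmax(e1$region[valid], e2$region[valid])
      key <- paste(a, b, e1$hemisphere[valid], sep = "\r")
      tab <- table(key)
      okey <- paste(out$region_a, out$region_b, out$hemisphere, sep = "\r")
      hit <- match(names(tab), okey)
      out$count[hit] <- as.integer(tab)
    }
  }
  structure(out, class = c("subject_connectome", "data.frame"),
            subject_id = subject_id, n_streamlines = length(streamlines))
}

#' @export
print.subject_connectome <- function(x, ...) {
  cat(sprintf("<subject_connectome> %s: %d streamlines, %d nonzero pair counts\n",
              attr(x, "subject_id"), attr(x, "n_streamlines"), sum(x$count > 0)))
  invisible(x)
}

#' Export streamlines as a long CSV
#' @param streamlines list of point matrices.
#' @param path output file.
#' @export
write_streamlines_csv <- function(streamlines, path) {
  rows <- lapply(seq_along(streamlines), function(i) {
    s <- streamlines[[i]]
    data.frame(streamline = i, point = seq_len(nrow(s)),
               x = s[, 1], y = s[, 2], z = s[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
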