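#' Kernel width from sample size
#'
#' Between-subject spatial uncertainty of a reported peak shrinks with the
#' study's sample size. The default kernel FWHM follows the widely used
#' empirical two-component model: a template-registration component of
#' 5.7 mm ED and a between-subject component of 11.6 mm ED scaled by
#' `1/sqrt(n)`, both converted from mean Euclidean displacement to Gaussian
#' FWHM.
#'
#' @param n_subjects positive integer vector.
#' @return FWHM in mm, one per element of `n_subjects`.
#' @export
fwhm_from_sample_size <- function(n_subjects) {
  stopifnot(all(n_subjects >= 1))
  ed_to_fwhm <- sqrt(8 * log(2)) / (2 * sqrt(2 / pi))
  u_template <- 5.7 * ed_to_fwhm
  u_subject <- 11.6 * ed_to_fwhm / sqrt(n_subjects)
  sqrt(u_template^2 + u_subject^2)
}

# Discretized, mass-normalized Gaussian kernel stamp on the grid's voxel
# lattice. Truncated at the radius where the omitted 1-D tail mass is below
# `mass_tol` (default keeps truncation error under 1e-10 of total mass).
ale_kernel_stamp <- function(grid, fwhm, mass_tol = 1e-10) {
  stopifnot(fwhm > 0)
  sigma <- fwhm / sqrt(8 * log(2))
  cutoff <- stats::qnorm(1 - mass_tol / 6) * sigma
  sp <- voxel_spacing(grid)
  nv <- ceiling(cutoff / sp)
  off <- as.matrix(expand.grid(dx = -nv[1]:nv[1], dy = -nv[2]:nv[2], dz = -nv[3]:nv[3]))
  mm <- off %*% t(grid$affine[1:3, 1:3])
  d2 <- rowSums(mm^2)
  keep <- d2 <= cutoff^2
  off <- off[keep, , drop = FALSE]
  val <- exp(-d2[keep] / (2 * sigma^2))
  list(offsets = matrix(as.integer(off), ncol = 3), values = val / sum(val))
}

# Snap mm foci to 0-based linear voxel indices; out-of-grid foci are dropped
# with a warning (their kernel contribution is truncated entirely).
foci_to_linear <- function(grid, xyz) {
  ijk <- world_to_voxel(grid, xyz)
  ok <- in_bounds(grid, ijk)
  if (!all(ok)) {
    warning(sum(!ok), " focus/foci outside the grid bounding box; contribution truncated")
  }
  ijk <- ijk[ok, , drop = FALSE]
  as.integer(linear_index(grid, ijk) - 1L)
}

#' Modeled-activation map of one study
#'
#' Places a mass-normalized 3-D Gaussian at every focus of a study and takes
#' the voxelwise maximum over foci (so duplicated peaks do not inflate the
#' map), clipped to the grid mask.
#'
#' @param foci matrix/data.frame with MNI mm columns x,y,z.
#' @param grid a [voxel_grid()].
#' @param kernel_fwhm Gaussian FWHM in mm.
#' @return numeric array over the grid, values in `[0, 1]`.
#' @export
ma_map <- function(foci, grid, kernel_fwhm) {
  if (is.data.frame(foci)) {
    if ("space" %in% names(foci) && any(foci$space != "MNI")) {
      stop("ma_map requires MNI-space foci; run tal_to_mni() first")
    }
    foci <- as.matrix(foci[, c("x", "y", "z")])
  }
  stamp <- ale_kernel_stamp(grid, kernel_fwhm)
  lin <- foci_to_linear(grid, foci)
  v <- cpp_ma_map(lin, grid$shape, grid$mask, stamp)
  array(v, dim = grid$shape)
}

#' ALE union of modeled-activation maps
#'
#' `ALE(v) = 1 - prod_i (1 - MA_i(v))`: the probability that at least one
#' study's true activation lies at the voxel, under independence.
#'
#' @param maps non-empty list of arrays on one grid.
#' @return numeric array.
#' @export
ale_union <- function(maps) {
  if (length(maps) == 0) stop("empty list of modeled-activation maps")
  p <- 1 - maps[[1]]
  for (m in maps[-1]) {
    if (!identical(dim(m), dim(p))) stop("maps do not share one grid")
    p <- p * (1 - m)
  }
  1 - p
}

# Shared setup for the permutation engine: per-study linear foci and stamps
# (one stamp per distinct kernel width).
engine_inputs <- function(table, grid, kernel_fwhm) {
  stopifnot(inherits(table, "foci_table") || is.data.frame(table))
  if (any(table$space != "MNI")) stop("foci must be in MNI space; run tal_to_mni() first")
  sidx <- if ("study" %in% names(table)) table$study else rep(1L, nrow(table))
  studies <- split(seq_len(nrow(table)), sidx)
  study_foci <- lapply(studies, function(rows) {
    foci_to_linear(grid, as.matrix(table[rows, c("x", "y", "z")]))
  })
  if (is.null(kernel_fwhm)) {
    fw <- vapply(studies, function(rows) {
      fwhm_from_sample_size(table$n_subjects[rows[1]])
    }, numeric(1))
  } else {
    fw <- rep(kernel_fwhm, length(studies))
  }
  ufw <- unique(fw)
  stamps <- lapply(ufw, function(f) ale_kernel_stamp(grid, f))
  list(study_foci = unname(study_foci),
       stamp_id = as.integer(match(fw, ufw) - 1L),
       stamps = stamps)
}

#' Voxelwise Monte-Carlo null for an observed ALE map
#'
#' Relocates every focus uniformly at random over mask voxels `n_perm` times,
#' recomputes the ALE map per permutation, and estimates per-voxel p-values
#' with the plus-one estimator `p(v) = (1 + #[ALE_perm(v) >= ALE_obs(v)]) /
#' (n_perm + 1)` (so the smallest attainable p is `1/(n_perm+1)`).
#'
#' @param table a `foci_table` in MNI space.
#' @param grid a [voxel_grid()].
#' @param kernel_fwhm fixed Gaussian FWHM in mm, or `NULL` for the per-study
#'   sample-size-dependent width of [fwhm_from_sample_size()].
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return list with arrays `ale` and `p`.
#' @export
voxel_null <- function(table, grid, kernel_fwhm = NULL, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  inp <- engine_inputs(table, grid, kernel_fwhm)
  mask_idx <- as.integer(which(grid$mask) - 1L)
  res <- with_seed(seed, cpp_ale_perm_engine(
    grid$shape, grid$mask, mask_idx, inp$study_foci, inp$stamp_id, inp$stamps,
    as.integer(n_perm), 0.001, 26L, FALSE))
  ale <- array(res$obs_ale, dim = grid$shape)
  p <- array(1, dim = grid$shape)
  pos <- ale > 0
  p[pos] <- (1 + res$count_ge[pos]) / (n_perm + 1)
  list(ale = ale, p = p)
}

#' Connected components of a binary volume
#'
#' @param vol logical array.
#' @param connectivity 26 (default, faces+edges+corners) or 6 (faces only).
#' @return list of clusters, each an integer vector of (1-based) linear voxel
#'   indices; attribute `labels` holds the full integer label array.
#' @export
find_clusters <- function(vol, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26), length(dim(vol)) == 3)
  lab <- cpp_label_components(as.logical(vol), dim(vol), as.integer(connectivity))
  lab <- array(lab, dim = dim(vol))
  k <- max(lab)
  sets <- if (k == 0) list() else split(which(lab > 0), lab[lab > 0])
  structure(unname(sets), labels = lab)
}

#' ALE cluster-level inference
#'
#' Full permutation-based cluster-extent inference. The cluster-forming
#' threshold is the ALE value at the `1 - voxel_p_threshold` quantile of the
#' pooled relocation-null histogram (every mask voxel of every permutation,
#' zeros included) - the Monte-Carlo counterpart of the analytic null
#' histogram used by the established meta-analysis software. Voxels at or
#' above the cutoff are grouped into connected components, and a component is
#' significant when its size is in the top `cluster_alpha` tail of the
#' permutation distribution of the maximum suprathreshold cluster size (the
#' observed map is pooled into that null, keeping the procedure exchangeable
#' and hence calibrated up to size ties). The returned `voxel_p` array is the
#' uncorrected per-voxel Monte-Carlo p of [voxel_null()].
#'
#' @param table a `foci_table` in MNI space.
#' @param grid a [voxel_grid()].
#' @param params list; recognised entries `cluster_alpha` (0.05),
#'   `voxel_p_threshold` (.001), `n_perm` (1000), `kernel_fwhm` (NULL: per
#'   study from sample size), `connectivity` (26), `rng_seed` (1).
#' @return An `ale_result`: arrays `ale` and `voxel_p`, `clusters`
#'   (significant clusters: id, n_voxels, peak mm coordinates, p), plus
#'   `all_clusters`, the label array, and the resolved `params`.
#' @export
cluster_inference <- function(table, grid, params = list()) {
  p <- utils::modifyList(list(
    cluster_alpha = 0.05, voxel_p_threshold = 0.001, n_perm = 1000,
    kernel_fwhm = NULL, connectivity = 26, rng_seed = 1), params)
  if (p$n_perm < 1) stop("n_perm must be >= 1")
  if (p$voxel_p_threshold <= 0 || p$voxel_p_threshold >= 1) {
    stop("voxel_p_threshold must be in (0, 1)")
  }
  inp <- engine_inputs(table, grid, p$kernel_fwhm)
  mask_idx <- as.integer(which(grid$mask) - 1L)
  res <- with_seed(p$rng_seed, cpp_ale_perm_engine(
    grid$shape, grid$mask, mask_idx, inp$study_foci, inp$stamp_id, inp$stamps,
    as.integer(p$n_perm), p$voxel_p_threshold, as.integer(p$connectivity), TRUE))

  ale <- array(res$obs_ale, dim = grid$shape)
  voxel_p <- array(1, dim = grid$shape)
  pos <- ale > 0
  voxel_p[pos] <- (1 + res$count_ge[pos]) / (p$n_perm + 1)
  labels <- array(res$labels, dim = grid$shape)

  k <- max(labels)
  if (k > 0) {
    sizes <- tabulate(labels[labels > 0], nbins = k)
    peak_idx <- vapply(seq_len(k), function(ci) {
      idx <- which(labels == ci)
      idx[which.max(ale[idx])]
    }, integer(1))
    ijk <- arrayInd(peak_idx, grid$shape) - 1L
    peaks <- voxel_to_world(grid, ijk)
    pc <- vapply(sizes, function(s) sum(res$max_size >= s) / (p$n_perm + 1), numeric(1))
    all_clusters <- data.frame(
      cluster = seq_len(k), n_voxels = sizes,
      peak_x = peaks[, 1], peak_y = peaks[, 2], peak_z = peaks[, 3],
      p = pc)
    all_clusters <- all_clusters[order(-all_clusters$n_voxels), ]
    rownames(all_clusters) <- NULL
  } else {
    all_clusters <- data.frame(cluster = integer(), n_voxels = integer(),
                               peak_x = numeric(), peak_y = numeric(),
                               peak_z = numeric(), p = numeric())
  }
  structure(list(
    ale = ale, voxel_p = voxel_p, labels = labels,
    clusters = all_clusters[all_clusters$p < p$cluster_alpha, , drop = FALSE],
    all_clusters = all_clusters,
    null_max_size = res$max_size,
    forming_cutoff = res$cutoff,
    grid = grid, params = p
  ), class = "ale_result")
}

#' @export
print.ale_result <- function(x, ...) {
  cat(sprintf("<ale_result> %d significant cluster(s) (alpha %.3g, %d permutations)\n",
              nrow(x$clusters), x$params$cluster_alpha, x$params$n_perm))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' Write ALE outputs
#'
#' Writes the ALE statistic and voxelwise p maps as float32 NIfTI-1 volumes
#' and the significant-cluster table as CSV.
#'
#' @param result an `ale_result`.
#' @param dir output directory (created if needed).
#' @export
write_ale_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti(result$ale, result$grid$affine, file.path(dir, "ale.nii.gz"))
  write_nifti(result$voxel_p, result$grid$affine, file.path(dir, "voxel_p.nii.gz"))
  utils::write.csv(result$clusters, file.path(dir, "clusters.csv"), row.names = FALSE)
  invisible(dir)
}

# Evaluate a thunk under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
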