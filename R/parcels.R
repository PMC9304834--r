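#' Parcellation volume
#'
#' Integer label image plus a region table. Labels are positive integers
#' (0 = background); each label maps to a region name, a hemisphere, and an
#' anatomical cluster used by the fiber-type taxonomy. Hemispheres are
#' distinct regions throughout: overlap scoring and tract counting are done
#' per hemisphere.
#'
#' @param grid a [voxel_grid()].
#' @param labels integer array over the grid.
#' @param regions data.frame with columns `label`, `region`, `hemisphere`
#'   ("L"/"R"), `cluster`.
#' @export
parcellation <- function(grid, labels, regions) {
  labels <- array(as.integer(labels), dim = grid$shape)
  stopifnot(all(c("label", "region", "hemisphere", "cluster") %in% names(regions)))
  present <- setdiff(unique(as.vector(labels)), 0L)
  unnamed <- setdiff(present, regions$label)
  if (length(unnamed) > 0) {
    stop("labels without a region entry: ", paste(unnamed, collapse = ", "))
  }
  structure(list(grid = grid, labels = labels, regions = regions),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d regions in %d cluster(s) on a %s grid\n",
              nrow(x$regions), length(unique(x$regions$cluster)),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Read / write a parcellation as NIfTI + JSON
#'
#' The label image is stored as an int32 NIfTI volume and the region table as
#' a JSON array of `{label, region, hemisphere, cluster}` records.
#'
#' @param parc a [parcellation()].
#' @param nii_path,json_path file paths.
#' @name parcellation_io
#' @export
write_parcellation <- function(parc, nii_path, json_path) {
  write_nifti(parc$labels, parc$grid$affine, nii_path, datatype = "int32")
  jsonlite::write_json(parc$regions, json_path, dataframe = "rows")
  invisible(nii_path)
}

#' @rdname parcellation_io
#' @param mask optional logical array for the grid (defaults to all-true).
#' @export
read_parcellation <- function(nii_path, json_path, mask = NULL) {
  img <- read_nifti(nii_path)
  grid <- voxel_grid(dim(img$data), img$affine, mask)
  regions <- as.data.frame(jsonlite::read_json(json_path, simplifyVector = TRUE))
  parcellation(grid, img$data, regions)
}

#' Union-of-spheres mask
#'
#' Marks every voxel whose center lies within radius `r` (Euclidean, mm) of
#' any peak. Peaks outside the grid produce a warning and a clipped sphere.
#'
#' @param peaks n x 3 matrix of mm coordinates.
#' @param radii scalar or per-peak radii (> 0).
#' @param grid a [voxel_grid()].
#' @return logical array over the grid.
#' @export
sphere_union_mask <- function(peaks, radii, grid) {
  peaks <- matrix(peaks, ncol = 3)
  radii <- rep_len(radii, nrow(peaks))
  stopifnot(all(radii > 0))
  out <- array(FALSE, dim = grid$shape)
  inv <- solve(grid$affine)
  sp <- voxel_spacing(grid)
  for (i in seq_len(nrow(peaks))) {
    ctr <- (inv %*% c(peaks[i, ], 1))[1:3]  # 0-based fractional voxel coords
    nv <- ceiling(radii[i] / sp)
    lo <- floor(ctr) - nv
    hi <- ceiling(ctr) + nv
    if (any(hi < 0) || any(lo > grid$shape - 1)) {
      warning("sphere peak outside the grid; sphere clipped away")
      next
    }
    clo <- pmax(lo, 0)
    chi <- pmin(hi, grid$shape - 1)
    if (any(clo > lo) || any(chi < hi)) warning("sphere clipped at grid boundary")
    box <- as.matrix(expand.grid(i = clo[1]:chi[1], j = clo[2]:chi[2], k = clo[3]:chi[3]))
    mm <- voxel_to_world(grid, box)
    d2 <- rowSums(sweep(mm, 2, peaks[i, ])^2)
    keep <- box[d2 <= radii[i]^2, , drop = FALSE]
    if (nrow(keep) > 0) out[linear_index(grid, keep)] <- TRUE
  }
  out
}

#' Overlap fraction of one region with a mask
#'
#' `|region voxels inside mask| / |region voxels|`, both counted on the
#' parcellation's grid.
#'
#' @param label integer region label.
#' @param parc a [parcellation()].
#' @param mask logical array on the parcellation grid.
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(label, parc, mask) {
  stopifnot(identical(dim(mask), dim(parc$labels)))
  sel <- parc$labels == label
  n <- sum(sel)
  if (n == 0) stop("region label ", label, " is empty")
  sum(mask[sel]) / n
}

# Nearest-neighbour resampling of a logical volume onto another grid.
resample_mask_nn <- function(mask, from, to) {
  if (grids_match(from, to)) return(mask)
  ijk_to <- arrayInd(seq_len(prod(to$shape)), to$shape) - 1L
  mm <- voxel_to_world(to, ijk_to)
  ijk_from <- world_to_voxel(from, mm)
  ok <- in_bounds(from, ijk_from)
  out <- rep(FALSE, prod(to$shape))
  out[ok] <- mask[linear_index(from, ijk_from[ok, , drop = FALSE])]
  array(out, dim = to$shape)
}

#' Select parcels overlapping an ALE result
#'
#' Scores every region by its percentage overlap with an ALE-derived mask and
#' includes regions whose fraction strictly exceeds the threshold ("more than
#' 10%" by default). The mask is either the union of spheres placed at the
#' significant-cluster peaks (default, radius from [sphere_radius()]) or the
#' significant-cluster voxels themselves; it is resampled nearest-neighbour
#' onto the parcellation grid when the grids differ.
#'
#' @param parc a [parcellation()].
#' @param ale_result an `ale_result` from [cluster_inference()], or a logical
#'   mask array already on the parcellation grid.
#' @param mask_source "spheres" (default) or "clusters".
#' @param threshold inclusion threshold, strict, in (0, 1); default 0.10.
#' @param sphere_r sphere radius in mm for the "spheres" source.
#' @return A `parcel_selection`: data.frame with `label`, `region`,
#'   `hemisphere`, `cluster`, `fraction`, `included`; attribute `threshold`.
#' @export
select_parcels <- function(parc, ale_result, mask_source = c("spheres", "clusters"),
                           threshold = 0.10, sphere_r = sphere_radius()) {
  mask_source <- match.arg(mask_source)
  stopifnot(threshold > 0, threshold < 1)
  if (is.array(ale_result) && is.logical(ale_result)) {
    mask <- ale_result
  } else {
    stopifnot(inherits(ale_result, "ale_result"))
    if (mask_source == "spheres") {
      if (nrow(ale_result$clusters) == 0) {
        mask <- array(FALSE, dim = ale_result$grid$shape)
      } else {
        peaks <- as.matrix(ale_result$clusters[, c("peak_x", "peak_y", "peak_z")])
        mask <- sphere_union_mask(peaks, sphere_r, ale_result$grid)
      }
    } else {
      sig <- ale_result$clusters$cluster
      mask <- array(ale_result$labels %in% sig & ale_result$labels > 0,
                    dim = ale_result$grid$shape)
    }
    mask <- resample_mask_nn(mask, ale_result$grid, parc$grid)
  }
  fr <- vapply(parc$regions$label, function(l) overlap_fraction(l, parc, mask),
               numeric(1))
  out <- parc$regions
  out$fraction <- fr
  out$included <- fr > threshold
  structure(out, class = c("parcel_selection", "data.frame"), threshold = threshold)
}

#' @export
print.parcel_selection <- function(x, ...) {
  cat(sprintf("<parcel_selection> %d/%d regions above %.3g\n",
              sum(x$included), nrow(x), attr(x, "threshold")))
  print(as.data.frame(x))
  invisible(x)
}
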