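#' Voxel grid
#'
#' A `voxel_grid` couples an array shape with a 4x4 voxel-to-world affine
#' (NIfTI convention: the affine maps 0-based voxel indices to world
#' millimetres, RAS+) and a logical analysis mask. All world coordinates in
#' the package are millimetres; voxelization happens only through the affine.
#'
#' @param shape integer vector of 3 positive extents.
#' @param affine 4x4 numeric voxel-to-world map; must be invertible.
#' @param mask logical array with `dim == shape`, or `NULL` for all-true.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, affine, mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L))
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  if (is.null(mask)) {
    mask <- array(TRUE, dim = shape)
  } else {
    mask <- array(as.logical(mask), dim = shape)
  }
  if (!any(mask)) stop("mask is empty")
  structure(
    list(shape = shape, affine = affine, mask = mask),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  sp <- voxel_spacing(x)
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %.3g x %.3g x %.3g mm, %d mask voxels\n",
              x$shape[1], x$shape[2], x$shape[3], sp[1], sp[2], sp[3], sum(x$mask)))
  invisible(x)
}

#' Default MNI-space analysis grid
#'
#' Isotropic grid covering the usual MNI bounding box (x -90..90, y -126..90,
#' z -72..108 mm) with an ellipsoidal brain-envelope mask. A template mask
#' image can be substituted by constructing a [voxel_grid()] directly.
#'
#' @param spacing isotropic voxel size in mm (default 2).
#' @param mask one of "ellipsoid" (default) or "box".
#' @export
mni_grid <- function(spacing = 2, mask = c("ellipsoid", "box")) {
  mask <- match.arg(mask)
  lo <- c(-90, -126, -72)
  hi <- c(90, 90, 108)
  shape <- floor((hi - lo) / spacing) + 1L
  affine <- diag(c(rep(spacing, 3), 1))
  affine[1:3, 4] <- lo
  g <- voxel_grid(shape, affine)
  if (mask == "ellipsoid") {
    g$mask <- ellipsoid_mask(g, center = c(0, -18, 18), semiaxes = c(72, 88, 76))
  }
  g
}

#' Ellipsoidal mask on a grid
#'
#' @param grid a [voxel_grid()].
#' @param center,semiaxes mm.
#' @return logical array over the grid.
#' @export
ellipsoid_mask <- function(grid, center, semiaxes) {
  xyz <- voxel_centers(grid)
  d <- sweep(xyz, 2, center)
  d <- sweep(d, 2, semiaxes, "/")
  array(rowSums(d^2) <= 1, dim = grid$shape)
}

#' Millimetre coordinates of every voxel center
#' @param grid a [voxel_grid()].
#' @return matrix (prod(shape) x 3) in array order.
#' @export
voxel_centers <- function(grid) {
  s <- grid$shape
  ijk <- cbind(
    rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  )
  voxel_to_world(grid, ijk)
}

#' Convert 0-based voxel indices to world mm
#' @param grid a [voxel_grid()].
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Convert world mm to nearest 0-based voxel indices
#' @param grid a [voxel_grid()].
#' @param xyz n x 3 matrix of world coordinates.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  v <- t(solve(grid$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
  round(v)
}

voxel_spacing <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' @keywords internal
in_bounds <- function(grid, ijk) {
  ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
}

# 0-based ijk -> 1-based linear index into arrays with dim = shape
linear_index <- function(grid, ijk) {
  s <- grid$shape
  1L + ijk[, 1] + s[1] * (ijk[, 2] + s[2] * ijk[, 3])
}

grids_match <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}
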