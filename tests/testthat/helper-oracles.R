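# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: flood fill is plain R recursion over an array,
# the reference tracker re-implements the lookup rule at a 0.01 mm step, and
# kernel values come from direct evaluation.

# Brute-force connected components by repeated flood fill (R, queue-based).
flood_fill_labels <- function(vol, connectivity = 26) {
  d <- dim(vol)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, ]
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (start in which(vol)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- arrayInd(v, d)
      nb <- sweep(off, 2, as.integer(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      grow <- lin[vol[lin] & lab[lin] == 0L]
      lab[grow] <- nxt
      queue <- c(queue, grow)
    }
  }
  lab
}

# canonical form of a labeling: list of sorted voxel-index sets, sorted by
# first element, so labelings can be compared up to renumbering
canonical_components <- function(lab) {
  sets <- split(which(lab > 0), lab[lab > 0])
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

# Fine-step reference integrator: same nearest-voxel direction lookup and
# halting rules as the tracker, Euler steps of `step` (default 0.01 mm).
# Returns the endpoint of one propagation half.
ref_propagate <- function(field, p0, d0, step = 0.01, ang_deg = 45,
                          budget = 800) {
  inv <- solve(field$grid$affine)
  costhr <- cos(ang_deg * pi / 180)
  p <- p0
  d <- d0
  len <- 0
  repeat {
    v <- round((inv %*% c(p, 1))[1:3])
    if (any(v < 0) || any(v >= field$grid$shape)) break
    vi <- v + 1L
    np <- field$n_peaks[vi[1], vi[2], vi[3]]
    if (np == 0 || !field$mask[vi[1], vi[2], vi[3]]) break
    pk <- field$peaks[, seq_len(np), vi[1], vi[2], vi[3], drop = FALSE]
    pk <- matrix(pk, nrow = 3)
    dots <- as.vector(d %*% pk)
    best <- which.max(abs(dots))
    if (abs(dots[best]) < costhr - 1e-12) break
    nd <- sign(dots[best]) * pk[, best]
    if (len + step > budget + 1e-9) break
    pn <- p + step * nd
    vn <- round((inv %*% c(pn, 1))[1:3])
    if (any(vn < 0) || any(vn >= field$grid$shape)) break
    if (!field$mask[vn[1] + 1, vn[2] + 1, vn[3] + 1]) break
    p <- pn
    d <- nd
    len <- len + step
  }
  list(endpoint = p, length = len)
}

# small cube grid helper: n^3 voxels, `spacing` mm, centered on the origin
cube_grid <- function(n, spacing = 1) {
  affine <- diag(c(rep(spacing, 3), 1))
  affine[1:3, 4] <- -spacing * (n - 1) / 2
  voxel_grid(c(n, n, n), affine)
}

# uniform +x orientation field over a cube grid
uniform_x_field <- function(n = 41, spacing = 1) {
  g <- cube_grid(n, spacing)
  peaks <- array(0, dim = c(3, 1, g$shape))
  peaks[1, 1, , , ] <- 1
  orientation_field(g, peaks)
}

# concentric circular tangent field (in the z = 0 plane) around `center`
circular_field <- function(n = 121, spacing = 1, center = c(0, 0, 0)) {
  g <- cube_grid(n, spacing)
  xyz <- voxel_centers(g)
  dx <- xyz[, 1] - center[1]
  dy <- xyz[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  tx <- ifelse(r > 1e-9, -dy / r, 0)
  ty <- ifelse(r > 1e-9, dx / r, 0)
  peaks <- array(0, dim = c(3, 1, g$shape))
  peaks[1, 1, , , ] <- array(tx, dim = g$shape)
  peaks[2, 1, , , ] <- array(ty, dim = g$shape)
  orientation_field(g, peaks)
}
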