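#' Synthetic foci table
#'
#' Emulates the structure of a published multi-study foci table: a handful of
#' activation loci shared across studies, per-study Gaussian jitter around
#' each locus, optional uniform background foci, and per-study sample sizes
#' drawn from a range typical of the fMRI literature (14-255 participants in
#' the emulated table).
#'
#' @param loci matrix of mm coordinates (one row per planted locus); may be
#'   NULL/empty for a pure-noise table.
#' @param n_studies number of studies.
#' @param subjects_range integer (min, max) for per-study sample sizes.
#' @param jitter_sigma isotropic per-focus Gaussian jitter (mm).
#' @param foci_per_study_per_locus planted foci per study per locus.
#' @param background_foci uniform-over-mask foci per study.
#' @param grid a [voxel_grid()] supplying the background mask.
#' @param seed RNG seed; draws are deterministic given the seed.
#' @return A `foci_table`.
#' @export
gen_foci <- function(loci = NULL, n_studies = 10, subjects_range = c(14, 255),
                     jitter_sigma = 4, foci_per_study_per_locus = 1,
                     background_foci = 0, grid = mni_grid(), seed = 1) {
  stopifnot(jitter_sigma >= 0, n_studies >= 1, foci_per_study_per_locus >= 0,
            background_foci >= 0)
  if (!is.null(loci)) loci <- matrix(loci, ncol = 3)
  mask_idx <- which(grid$mask)
  with_seed(seed, {
    rows <- lapply(seq_len(n_studies), function(s) {
      n_sub <- sample(subjects_range[1]:subjects_range[2], 1)
      pts <- NULL
      if (!is.null(loci) && nrow(loci) > 0 && foci_per_study_per_locus > 0) {
        rep_loci <- loci[rep(seq_len(nrow(loci)), each = foci_per_study_per_locus), ,
                         drop = FALSE]
        pts <- rep_loci + matrix(stats::rnorm(3 * nrow(rep_loci), 0, jitter_sigma),
                                 ncol = 3)
      }
      if (background_foci > 0) {
        pick <- mask_idx[sample.int(length(mask_idx), background_foci, replace = TRUE)]
        bg <- voxel_to_world(grid, arrayInd(pick, grid$shape) - 1L)
        pts <- rbind(pts, bg)
      }
      if (is.null(pts) || nrow(pts) == 0) stop("study with no foci; check the spec")
      data.frame(study_id = sprintf("synth%02d", s), task = "synthetic",
                 n_subjects = n_sub, space = "MNI",
                 x = pts[, 1], y = pts[, 2], z = pts[, 3])
    })
    parse_foci_table(do.call(rbind, rows))
  })
}

#' Synthetic spherical parcellation
#'
#' Voxelizes spherical parcels at given left-hemisphere centers and mirrors
#' them across the midline (x -> -x), yielding one labeled region per
#' hemisphere per spec row. Labels 1..K are left, K+1..2K right. Overlapping
#' parcels (after voxelization) are an error naming the offending pair.
#'
#' @param grid a [voxel_grid()].
#' @param specs data.frame with columns `region`, `cluster`, `x`, `y`, `z`
#'   (left-hemisphere center, mm) and optionally `radius` (mm, default 3).
#' @param radius default parcel radius when `specs$radius` is absent.
#' @return A [parcellation()].
#' @export
gen_parcellation <- function(grid, specs = salience_regions(), radius = 3) {
  if (!"radius" %in% names(specs)) specs$radius <- radius
  K <- nrow(specs)
  labels <- array(0L, dim = grid$shape)
  regions <- data.frame(
    label = seq_len(2 * K),
    region = rep(specs$region, 2),
    hemisphere = rep(c("L", "R"), each = K),
    cluster = rep(specs$cluster, 2),
    stringsAsFactors = FALSE)
  centers <- rbind(as.matrix(specs[, c("x", "y", "z")]),
                   as.matrix(specs[, c("x", "y", "z")]) %*% diag(c(-1, 1, 1)))
  for (l in seq_len(2 * K)) {
    m <- sphere_union_mask(centers[l, , drop = FALSE],
                           specs$radius[(l - 1) %% K + 1], grid)
    clash <- labels[m]
    clash <- clash[clash > 0]
    if (length(clash) > 0) {
      stop(sprintf("parcels overlap after voxelization: %s/%s and %s/%s",
                   regions$region[clash[1]], regions$hemisphere[clash[1]],
                   regions$region[l], regions$hemisphere[l]))
    }
    labels[m] <- l
  }
  parcellation(grid, labels, regions)
}

#' Bundle specification
#'
#' Geometry and cohort statistics of one planted fiber bundle connecting two
#' named regions, mirrored into both hemispheres. Kinds: `straight` (line
#' segment between the parcel centers), `arc` (circular arc bulging by
#' `bulge_mm` out of the chord), `u_shape` (half-circle over the chord, the
#' classic U-fiber morphology). Per-hemisphere density scaling is by tube
#' multiplicity: `count_scale` (a positive integer per hemisphere) congruent
#' copies of the tube are rasterized side by side, offset along the curve's
#' binormal so they stay disjoint. Because every copy has identical radius
#' and curvature (hence identical streamline retention) and uniform
#' whole-brain seeding makes expected counts proportional to swept volume,
#' expected count ratios equal the `count_scale` ratio exactly.
#'
#' @param kind "straight", "arc" or "u_shape".
#' @param region_a,region_b endpoint region names (must exist in the
#'   parcellation).
#' @param tube_radius_mm base tube radius.
#' @param presence_prob probability a subject expresses the bundle (drawn
#'   independently per hemisphere).
#' @param count_scale length-2 positive integers `(L, R)`: tube multiplicity
#'   per hemisphere.
#' @param bulge_mm arc bulge height (ignored for straight/u_shape).
#' @param bulge_dir approximate bulge direction (mm vector); projected
#'   perpendicular to the chord.
#' @param end_inset_mm how far short of each parcel center the centerline
#'   stops (keeps bundle tangents of different bundles from mixing at shared
#'   endpoints).
#' @export
bundle_spec <- function(kind = c("straight", "arc", "u_shape"),
                        region_a, region_b, tube_radius_mm = 3.5,
                        presence_prob = 1, count_scale = c(L = 1, R = 1),
                        bulge_mm = 8, bulge_dir = c(0, -1, 0),
                        end_inset_mm = 0) {
  kind <- match.arg(kind)
  stopifnot(presence_prob >= 0, presence_prob <= 1, tube_radius_mm > 0,
            length(count_scale) == 2, all(count_scale >= 1),
            all(count_scale == round(count_scale)))
  structure(list(kind = kind, region_a = region_a, region_b = region_b,
                 tube_radius_mm = tube_radius_mm, presence_prob = presence_prob,
                 count_scale = count_scale, bulge_mm = bulge_mm,
                 bulge_dir = bulge_dir, end_inset_mm = end_inset_mm),
            class = "bundle_spec")
}

# Dense centerline (points + unit tangents) for a bundle between two mm
# endpoints. `ds` is the sampling step along the curve.
bundle_centerline <- function(kind, p, q, bulge_mm, bulge_dir, ds = 0.25) {
  chord <- q - p
  len <- sqrt(sum(chord^2))
  if (len < 1e-6) stop("bundle endpoints coincide")
  u <- chord / len
  if (kind == "straight") {
    s <- seq(0, len, by = ds)
    pts <- outer(s, u) + matrix(p, nrow = length(s), ncol = 3, byrow = TRUE)
    return(list(points = pts, tangents = matrix(u, nrow = length(s), ncol = 3,
                                                byrow = TRUE)))
  }
  # perpendicular bulge direction
  v <- bulge_dir - sum(bulge_dir * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-6) stop("bulge direction parallel to the chord")
  v <- v / nv
  if (kind == "u_shape") {
    # semicircle from p to q bulging toward v: x(t) = c - r cos(t) u + r sin(t) v
    r <- len / 2
    ctr <- (p + q) / 2
    theta <- seq(0, pi, length.out = max(8, ceiling(pi * r / ds)))
    pts <- sweep(outer(-cos(theta), u * r) + outer(sin(theta), v * r), 2, ctr, "+")
    tan_ <- outer(sin(theta), u) + outer(cos(theta), v)
  } else { # arc through p,q with sagitta bulge_mm
    h <- bulge_mm
    r <- h / 2 + len^2 / (8 * h)
    ctr <- (p + q) / 2 + v * (h - r)
    half <- asin(pmin(1, (len / 2) / r))
    theta <- seq(-half, half, length.out = max(8, ceiling(2 * half * r / ds)))
    pts <- sweep(outer(sin(theta), u * r) + outer(cos(theta), v * r), 2, ctr, "+")
    tan_ <- outer(cos(theta), u) - outer(sin(theta), v)
  }
  tan_ <- tan_ / sqrt(rowSums(tan_^2))
  list(points = pts, tangents = tan_)
}

# curvature radius of the rasterized geometry (for validity checks)
bundle_curvature_radius <- function(kind, p, q, bulge_mm) {
  len <- sqrt(sum((q - p)^2))
  switch(kind,
         straight = Inf,
         u_shape = len / 2,
         arc = bulge_mm / 2 + len^2 / (8 * bulge_mm))
}

#' Synthetic multi-subject cohort of orientation fields
#'
#' Plans a cohort: for every subject and hemisphere, each bundle is present
#' with its `presence_prob`; present bundles are rasterized as unit-tangent
#' tubes (up to 3 overlapping bundle peaks per voxel). Returns the per-subject
#' presence plan and ground-truth edge table up front; per-subject fields are
#' materialized lazily with [cohort_field()] to keep memory bounded.
#'
#' @param bundles list of [bundle_spec()]s; endpoints must exist in `parc`.
#' @param parc a [parcellation()].
#' @param n_subjects cohort size.
#' @param seed RNG seed for the presence draws.
#' @return A `synthetic_cohort`: list with `plan` (data.frame subject x
#'   bundle x hemisphere presence), `truth` (expected edges: subject, pair,
#'   hemisphere, present, scale), `bundles`, `parc`, `n_subjects`.
#' @export
gen_cohort <- function(bundles, parc, n_subjects = 25, seed = 1) {
  stopifnot(length(bundles) >= 1, n_subjects >= 1)
  regs <- parc$regions
  for (b in bundles) {
    for (r in c(b$region_a, b$region_b)) {
      if (!r %in% regs$region) stop("bundle endpoint not in parcellation: ", r)
    }
  }
  plan <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      do.call(rbind, lapply(seq_along(bundles), function(bi) {
        data.frame(subject = s, bundle = bi, hemisphere = c("L", "R"),
                   present = stats::runif(2) < bundles[[bi]]$presence_prob)
      }))
    }))
  })
  truth <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
    b <- bundles[[plan$bundle[i]]]
    data.frame(subject = plan$subject[i],
               region_a = min(b$region_a, b$region_b),
               region_b = max(b$region_a, b$region_b),
               hemisphere = plan$hemisphere[i], present = plan$present[i],
               scale = unname(b$count_scale[match(plan$hemisphere[i], c("L", "R"))]))
  }))
  structure(list(plan = plan, truth = truth, bundles = bundles, parc = parc,
                 n_subjects = n_subjects, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d bundle(s)\n",
              x$n_subjects, length(x$bundles)))
  invisible(x)
}

#' Materialize one subject's orientation field
#'
#' @param cohort a [gen_cohort()] result.
#' @param subject subject index in 1..n_subjects.
#' @return An [orientation_field()] on the parcellation grid.
#' @export
cohort_field <- function(cohort, subject) {
  stopifnot(subject >= 1, subject <= cohort$n_subjects)
  parc <- cohort$parc
  grid <- parc$grid
  regs <- parc$regions
  sel <- cohort$plan[cohort$plan$subject == subject & cohort$plan$present, ,
                     drop = FALSE]
  maxp <- 3L
  peaks <- array(0, dim = c(3L, maxp, grid$shape))
  npk <- array(0L, dim = grid$shape)
  sp <- voxel_spacing(grid)
  for (i in seq_len(nrow(sel))) {
    b <- cohort$bundles[[sel$bundle[i]]]
    h <- sel$hemisphere[i]
    ctr_of <- function(region) {
      lab <- regs$label[regs$region == region & regs$hemisphere == h]
      idx <- which(parc$labels == lab)
      if (length(idx) == 0) stop("empty parcel for ", region, "/", h)
      colMeans(voxel_to_world(grid, arrayInd(idx, grid$shape) - 1L))
    }
    p <- ctr_of(b$region_a)
    q <- ctr_of(b$region_b)
    if (b$end_inset_mm > 0) {
      u <- (q - p) / sqrt(sum((q - p)^2))
      p <- p + u * b$end_inset_mm
      q <- q - u * b$end_inset_mm
    }
    bd <- b$bulge_dir
    if (h == "R") bd <- bd * c(-1, 1, 1)  # mirror the bulge with the geometry
    if (bundle_curvature_radius(b$kind, p, q, b$bulge_mm) < 3 * 1.5) {
      stop("bundle curvature radius below 3 steps; the tracker cannot follow it")
    }
    cl <- bundle_centerline(b$kind, p, q, b$bulge_mm, bd)
    # density scaling: count_scale congruent tube copies offset along the
    # binormal, spaced to stay disjoint
    k <- as.integer(unname(b$count_scale[match(h, c("L", "R"))]))
    u <- (q - p) / sqrt(sum((q - p)^2))
    v <- bd - sum(bd * u) * u
    if (sqrt(sum(v^2)) < 1e-6) {
      # bulge direction (ir)relevant and parallel to the chord: any
      # perpendicular will do for the copy offsets
      alt <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v <- alt - sum(alt * u) * u
    }
    v <- v / sqrt(sum(v^2))
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    offsets <- if (k == 1) 0 else
      (seq_len(k) - (k + 1) / 2) * (2 * b$tube_radius_mm + 0.5)
    for (off in offsets) {
      pts <- sweep(cl$points, 2, off * w, "+")
      rast <- rasterize_tube(grid, pts, cl$tangents, b$tube_radius_mm)
      for (j in seq_along(rast$voxel)) {
        vox <- rast$voxel[j]
        ijk <- arrayInd(vox, grid$shape)
        slot <- npk[vox] + 1L
        if (slot > maxp) next  # at most 3 crossing peaks per voxel
        peaks[, slot, ijk[1], ijk[2], ijk[3]] <- rast$tangent[j, ]
        npk[vox] <- slot
      }
    }
  }
  orientation_field(grid, peaks, mask = grid$mask)
}

# Mark voxels within `r_tube` mm of the polyline; each voxel gets the tangent
# of the nearest centerline sample. Errors if the tube exits the grid.
rasterize_tube <- function(grid, points, tangents, r_tube) {
  inv <- solve(grid$affine)
  sp <- voxel_spacing(grid)
  nv <- ceiling(r_tube / sp)
  # accumulate candidate voxels per sample, keep nearest-sample tangent
  acc <- list()
  for (s in seq_len(nrow(points))) {
    ctr <- (inv %*% c(points[s, ], 1))[1:3]
    lo <- floor(ctr - nv); hi <- ceiling(ctr + nv)
    if (any(lo < 0) || any(hi > grid$shape - 1)) {
      stop("bundle tube exits the grid")
    }
    box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    mm <- voxel_to_world(grid, box)
    d2 <- rowSums(sweep(mm, 2, points[s, ])^2)
    keep <- d2 <= r_tube^2
    if (!any(keep)) next
    lin <- linear_index(grid, box[keep, , drop = FALSE])
    acc[[length(acc) + 1L]] <- data.frame(v = lin, d2 = d2[keep], s = s)
  }
  all <- do.call(rbind, acc)
  if (is.null(all)) stop("tube rasterized to zero voxels")
  all <- all[order(all$v, all$d2), ]
  first <- !duplicated(all$v)
  list(voxel = all$v[first], tangent = tangents[all$s[first], , drop = FALSE])
}

#' Fixture accessor (alias)
#'
#' Convenience re-export of [fixture_tables()] kept with the other
#' generators: packaged transcriptions of the study/foci table and the
#' connection-strength table used in regression tests.
#' @export
synthetic_fixture_tables <- function() fixture_tables()
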