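#' Pipeline run configuration
#'
#' One configuration object drives the full foci -> ALE -> parcel selection ->
#' tractography -> statistics pipeline. Every tunable defaults to the
#' published analysis settings: cluster alpha 0.05, 1000 permutations, voxel
#' p .001, 10% overlap threshold, 45 degree angular threshold, 1.5 mm step,
#' 800 mm maximum and 1 mm minimum streamline length, minimum edge strength
#' 10 tracts, and a 25-subject cohort.
#'
#' @param foci path to a foci TSV, a `foci_table`, or NULL to skip the
#'   ALE/selection stages (all parcellation regions are then used).
#' @param parcellation a [parcellation()] (or list(nii, json) paths).
#' @param cohort a [gen_cohort()] result supplying per-subject orientation
#'   fields, or a function(subject) returning an [orientation_field()].
#' @param grid ALE analysis grid (default [mni_grid()]).
#' @param n_subjects cohort size N.
#' @param cluster_alpha,n_perm,voxel_p_threshold,kernel_fwhm ALE settings.
#' @param overlap_threshold parcel inclusion threshold (strict).
#' @param mask_source "spheres" or "clusters" (see [select_parcels()]).
#' @param tracking a [tracking_params()].
#' @param min_edge_strength schematic edge filter (mean tracts).
#' @param seed root seed; per-stage seeds are derived deterministically.
#' @export
run_config <- function(foci = NULL, parcellation = NULL, cohort = NULL,
                       grid = mni_grid(), n_subjects = 25,
                       cluster_alpha = 0.05, n_perm = 1000,
                       voxel_p_threshold = 0.001, kernel_fwhm = NULL,
                       overlap_threshold = 0.10,
                       mask_source = "spheres",
                       tracking = tracking_params(),
                       min_edge_strength = 10, seed = 1,
                       cache_dir = NULL) {
  cfg <- list(foci = foci, parcellation = parcellation, cohort = cohort,
              grid = grid, n_subjects = n_subjects,
              cluster_alpha = cluster_alpha, n_perm = n_perm,
              voxel_p_threshold = voxel_p_threshold, kernel_fwhm = kernel_fwhm,
              overlap_threshold = overlap_threshold, mask_source = mask_source,
              tracking = tracking, min_edge_strength = min_edge_strength,
              seed = seed, cache_dir = cache_dir)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (cfg$voxel_p_threshold <= 0 || cfg$voxel_p_threshold >= 1) {
    stop("config error: voxel_p_threshold must be in (0, 1)")
  }
  if (cfg$cluster_alpha <= 0 || cfg$cluster_alpha >= 1) {
    stop("config error: cluster_alpha must be in (0, 1)")
  }
  if (cfg$overlap_threshold <= 0 || cfg$overlap_threshold >= 1) {
    stop("config error: overlap_threshold must be in (0, 1)")
  }
  if (cfg$n_perm < 1) stop("config error: n_perm must be >= 1")
  if (cfg$n_subjects < 1) stop("config error: n_subjects must be >= 1")
  if (cfg$min_edge_strength < 0) stop("config error: min_edge_strength must be >= 0")
  if (is.null(cfg$parcellation)) stop("config error: a parcellation is required")
  invisible(TRUE)
}

# deterministic per-stage seed derivation from the root seed
stage_seed <- function(root, stage) {
  offs <- c(ale = 101L, cohort = 211L, track = 307L)
  (as.integer(root) * 7919L + offs[[stage]]) %% .Machine$integer.max
}

# content-addressed stage cache: key = md5 of the serialized inputs
cache_get <- function(cache_dir, key, compute) {
  if (is.null(cache_dir)) return(compute())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(key, tmp)
  path <- file.path(cache_dir, paste0(unname(tools::md5sum(tmp)), ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- compute()
  saveRDS(val, path)
  val
}

#' Run the full pipeline
#'
#' Stages in order: foci ingestion and Talairach->MNI normalization, ALE with
#' cluster-level inference, percentage-overlap parcel selection, per-subject
#' whole-brain tractography with pairwise two-ROI counting, and edge
#' statistics with the fiber-type taxonomy and the minimum-strength network
#' filter. Identical config + seed produces an identical report. Any stage
#' failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return A `pipeline_report`: list with `selection`, `ale` (or NULL),
#'   `edge_stats`, `network`, `provenance`.
#' @export
run_all <- function(config) {
  validate_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  parc <- stage("parcellation", {
    p <- config$parcellation
    if (inherits(p, "parcellation")) p else read_parcellation(p$nii, p$json)
  })

  ale <- NULL
  if (!is.null(config$foci)) {
    foci <- stage("foci", {
      f <- config$foci
      if (!inherits(f, "foci_table")) f <- parse_foci_table(f)
      tal_to_mni(f)
    })
    ale <- stage("ale", {
      cache_get(config$cache_dir,
                list("ale", foci, config$grid, config$kernel_fwhm,
                     config$n_perm, config$cluster_alpha,
                     config$voxel_p_threshold, config$seed),
                function() cluster_inference(foci, config$grid, list(
                  cluster_alpha = config$cluster_alpha,
                  voxel_p_threshold = config$voxel_p_threshold,
                  n_perm = config$n_perm, kernel_fwhm = config$kernel_fwhm,
                  rng_seed = stage_seed(config$seed, "ale"))))
    })
  }

  selection <- stage("parcel_selection", {
    if (is.null(ale)) {
      out <- parc$regions
      out$fraction <- NA_real_
      out$included <- TRUE
      structure(out, class = c("parcel_selection", "data.frame"),
                threshold = config$overlap_threshold)
    } else {
      select_parcels(parc, ale, mask_source = config$mask_source,
                     threshold = config$overlap_threshold)
    }
  })

  included_regions <- unique(selection$region[selection$included])
  if (length(included_regions) < 2) {
    stop("pipeline stage 'parcel_selection' failed: fewer than two regions selected",
         call. = FALSE)
  }
  sub_parc <- stage("parcel_selection", {
    keep <- parc$regions$region %in% included_regions
    labs <- parc$labels
    labs[!(labs %in% parc$regions$label[keep])] <- 0L
    parcellation(parc$grid, labs, parc$regions[keep, , drop = FALSE])
  })

  connectomes <- stage("tractography", {
    field_of <- if (inherits(config$cohort, "synthetic_cohort")) {
      function(s) cohort_field(config$cohort, s)
    } else if (is.function(config$cohort)) {
      config$cohort
    } else {
      stop("no cohort of orientation fields supplied")
    }
    lapply(seq_len(config$n_subjects), function(s) {
      tp <- config$tracking
      tp$rng_seed <- (stage_seed(config$seed, "track") + s) %% .Machine$integer.max
      subject_connectome(field_of(s), sub_parc, tp,
                         subject_id = sprintf("subj%03d", s))
    })
  })

  stats <- stage("edge_stats", {
    cmap <- stats::setNames(parc$regions$cluster, parc$regions$region)
    edge_stats(connectomes, cmap, n_total = config$n_subjects)
  })
  network <- stage("network", build_network(stats, config$min_edge_strength))

  structure(list(
    selection = selection, ale = ale, edge_stats = stats, network = network,
    provenance = list(
      seed = config$seed,
      n_subjects = config$n_subjects,
      params = config[c("cluster_alpha", "n_perm", "voxel_p_threshold",
                        "kernel_fwhm", "overlap_threshold", "mask_source",
                        "min_edge_strength")],
      tracking = unclass(config$tracking),
      package_version = as.character(utils::packageVersion("salnet")))
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  regions selected: %d\n", sum(x$selection$included)))
  cat(sprintf("  edges retained:   %d of %d\n", nrow(x$network$edges),
              nrow(x$edge_stats)))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' JSON report (selection, formatted edge table, retained network, and
#' provenance) plus CSV tables and a GraphML export of the network.
#'
#' @param report a [run_all()] result.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report$selection),
                   file.path(dir, "parcel_selection.csv"), row.names = FALSE)
  utils::write.csv(format_edge_stats(report$edge_stats),
                   file.path(dir, "edge_stats.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    selection = as.data.frame(report$selection),
    edges = format_edge_stats(report$network$edges),
    provenance = report$provenance
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_network_graphml(report$network, file.path(dir, "network.graphml"))
  if (!is.null(report$ale)) write_ale_result(report$ale, file.path(dir, "ale"))
  invisible(dir)
}
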