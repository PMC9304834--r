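#' Parse a study/foci table
#'
#' Reads a tab-separated table of published activation peaks into a
#' `foci_table`: one row per focus with the study-level fields repeated.
#' Consecutive rows sharing the same study entry (id, task, sample size and
#' space) are grouped into one study; a study id recurring later in the table
#' starts a new study, matching the convention of published summary tables
#' that may list the same report twice.
#'
#' Expected columns: `study_id`, `task`, `n_subjects`, `space` (`MNI` or
#' `TAL`), `x`, `y`, `z`, and optionally `sphere_volume` (mm^3).
#'
#' @param source a file path or a data.frame already in the column layout.
#' @return A `foci_table`: data.frame of foci with columns above plus
#'   `study`, an integer study index; attribute `n_studies`.
#' @export
parse_foci_table <- function(source) {
  df <- if (is.data.frame(source)) {
    source
  } else {
    utils::read.delim(source, sep = "\t", stringsAsFactors = FALSE,
                      quote = "", comment.char = "")
  }
  if (nrow(df) == 0) stop("no studies")
  need <- c("study_id", "task", "n_subjects", "space", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"sphere_volume" %in% names(df)) df$sphere_volume <- NA_real_
  for (col in c("x", "y", "z", "n_subjects", "sphere_volume")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "" & df[[col]] != "NA")
    if (length(bad) > 0) {
      stop(sprintf("malformed numeric cell in column '%s' at row(s) %s",
                   col, paste(bad, collapse = ", ")))
    }
    df[[col]] <- v
  }
  df$space <- toupper(trimws(df$space))
  df$space[df$space == "TALAIRACH"] <- "TAL"
  unknown <- setdiff(unique(df$space), c("MNI", "TAL"))
  if (length(unknown) > 0) stop("unknown space token: ", paste(unknown, collapse = ", "))
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    stop("non-finite coordinates")
  }
  if (any(abs(df[, c("x", "y", "z")]) > 120)) {
    stop("coordinate outside +/-120 mm; not a plausible stereotaxic peak")
  }
  if (any(df$n_subjects < 1)) stop("n_subjects must be >= 1")

  key <- paste(df$study_id, df$task, df$n_subjects, df$space, sep = "\r")
  run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  df$study <- as.integer(run)
  structure(df, class = c("foci_table", "data.frame"),
            n_studies = max(df$study))
}

#' @export
print.foci_table <- function(x, ...) {
  cat(sprintf("<foci_table> %d studies, %d foci (%d TAL, %d MNI)\n",
              attr(x, "n_studies"), nrow(x),
              sum(x$space == "TAL"), sum(x$space == "MNI")))
  invisible(x)
}

#' Number of studies in a foci table
#' @param table a `foci_table`.
#' @export
n_studies <- function(table) attr(table, "n_studies")

#' Write a foci table back to TSV
#' @param table a `foci_table`.
#' @param path output file.
#' @export
write_foci_table <- function(table, path) {
  cols <- c("study_id", "task", "n_subjects", "space", "x", "y", "z", "sphere_volume")
  utils::write.table(as.data.frame(table)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Lancaster et al. (2007) icbm_spm2tal affine: maps MNI coordinates produced
# with SPM-normalised templates to Talairach space. The Talairach->MNI
# conversion used here is its matrix inverse, as in meta-analysis tools that
# offer an "SPM conversion" of published Talairach peaks.
icbm_spm2tal <- matrix(c(
   0.9254,  0.0024, -0.0118, -1.0207,
  -0.0048,  0.9316, -0.0871, -1.7667,
   0.0152,  0.0883,  0.8924,  4.0926,
   0,       0,       0,       1), nrow = 4, byrow = TRUE)

#' Convert Talairach foci to MNI space
#'
#' Applies the inverse of the Lancaster `icbm_spm2tal` affine to every
#' Talairach-space focus; MNI foci pass through unchanged (with a warning if
#' the input is a single MNI focus, since the call is then a no-op).
#'
#' @param x either a `foci_table` or a numeric length-3 coordinate.
#' @param space for the coordinate form: "TAL" or "MNI".
#' @return Same shape as the input, with all coordinates in MNI space.
#' @export
tal_to_mni <- function(x, space = "TAL") {
  A <- solve(icbm_spm2tal)
  if (inherits(x, "foci_table") || is.data.frame(x)) {
    is_tal <- x$space == "TAL"
    if (any(is_tal)) {
      p <- t(A %*% rbind(t(as.matrix(x[is_tal, c("x", "y", "z")])), 1))
      x$x[is_tal] <- p[, 1]; x$y[is_tal] <- p[, 2]; x$z[is_tal] <- p[, 3]
      x$space[is_tal] <- "MNI"
    }
    return(x)
  }
  stopifnot(is.numeric(x), length(x) == 3)
  if (identical(space, "MNI")) {
    warning("tal_to_mni called on an MNI focus; returning it unchanged")
    return(x)
  }
  as.vector((A %*% c(x, 1))[1:3])
}

#' Kernel sphere radius for a focus
#'
#' Published peaks sometimes carry an activation volume; the corresponding
#' sphere radius is `(3 V / 4 pi)^(1/3)`. Peaks without a volume get the
#' default radius (3 mm).
#'
#' @param sphere_volume volume in mm^3, or `NA`/`NULL` when absent.
#' @param default_r default radius in mm (> 0).
#' @return radius in mm.
#' @export
sphere_radius <- function(sphere_volume = NA, default_r = 3) {
  stopifnot(default_r > 0)
  if (is.null(sphere_volume) || length(sphere_volume) == 0) return(default_r)
  out <- rep(default_r, length(sphere_volume))
  has <- !is.na(sphere_volume)
  if (any(sphere_volume[has] <= 0)) stop("sphere_volume must be positive")
  out[has] <- (3 * sphere_volume[has] / (4 * pi))^(1 / 3)
  out
}

#' Packaged study/foci fixture
#'
#' The transcription of the 35-study salience-network meta-analysis table
#' shipped with the package (per-focus rows; coordinates as printed,
#' including the repeated resting-state study and one unnamed study row).
#'
#' @return A `foci_table`.
#' @export
salience_foci_table <- function() {
  parse_foci_table(system.file("extdata", "salience_foci_table1.tsv",
                               package = "salnet", mustWork = TRUE))
}
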