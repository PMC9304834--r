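#' Minimal NIfTI-1 input/output
#'
#' Self-contained single-file NIfTI-1 (`.nii` / `.nii.gz`) reader and writer
#' covering the subset of the format the pipeline emits and consumes: 3-D or
#' 4-D volumes, the common datatypes, and an sform voxel-to-world affine.
#' Written volumes are little-endian with `vox_offset = 352` and sform code 2.
#'
#' No NIfTI package is available in the target library set, so these routines
#' are implemented directly against the published header layout.
#'
#' @param path file path; a `.gz` suffix triggers transparent (de)compression.
#' @param data numeric/integer/logical array (3-D or 4-D).
#' @param affine 4x4 voxel-to-world matrix.
#' @param datatype one of "float32", "float64", "int16", "int32", "uint8".
#' @return `read_nifti` returns `list(data, affine)`.
#' @name nifti_io
NULL

.nifti_types <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

#' @rdname nifti_io
#' @export
write_nifti <- function(data, affine, path, datatype = "float32") {
  ty <- .nifti_types[[match.arg(datatype, names(.nifti_types))]]
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  stopifnot(length(dims) %in% c(3L, 4L))
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                       # sizeof_hdr
  w_raw(36L)                        # data_type, db_name, extents, session_error, regular, dim_info
  dim8 <- c(length(dims), dims, rep(1L, 7 - length(dims)))
  w_i16(dim8)                       # dim[8]
  w_f32(c(0, 0, 0))                 # intent_p1..p3
  w_i16(0L)                         # intent_code
  w_i16(ty$code)                    # datatype
  w_i16(ty$bitpix)                  # bitpix
  w_i16(0L)                         # slice_start
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  w_f32(c(1, sp, rep(1, 4)))        # pixdim[8]
  w_f32(352)                        # vox_offset
  w_f32(c(1, 0))                    # scl_slope, scl_inter
  w_i16(0L); w_raw(1L); w_raw(1L)   # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0))                 # cal_max, cal_min, slice_duration
  w_f32(0)                          # toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_raw(80L); w_raw(24L)            # descrip, aux_file
  w_i16(0L)                         # qform_code
  w_i16(2L)                         # sform_code
  w_f32(rep(0, 6))                  # quatern_b..d, qoffset_x..z
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(16L)                        # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); w_raw(1L)  # magic
  w_raw(4L)                         # extension flag

  vals <- as.vector(data)
  if (ty$what == "integer") vals <- as.integer(round(vals)) else vals <- as.double(vals)
  writeBin(vals, con, size = ty$size, endian = "little")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header")
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  rd <- function(off, n, what, size, signed = TRUE)
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  dim8 <- rd(40L, 8L, "integer", 2L)
  nd <- dim8[1]
  if (!nd %in% c(3L, 4L)) stop("unsupported NIfTI dimensionality: ", nd)
  dims <- dim8[2:(1 + nd)]
  code <- rd(70L, 1L, "integer", 2L)
  ty_i <- which(vapply(.nifti_types, function(t) t$code == code, logical(1)))
  if (length(ty_i) == 0) stop("unsupported NIfTI datatype code: ", code)
  ty <- .nifti_types[[ty_i]]
  pixdim <- rd(76L, 8L, "double", 4L)
  vox_offset <- rd(108L, 1L, "double", 4L)
  scl_slope <- rd(112L, 1L, "double", 4L)
  scl_inter <- rd(116L, 1L, "double", 4L)
  sform <- rd(254L, 1L, "integer", 2L)
  affine <- diag(4)
  if (sform > 0) {
    affine[1, ] <- rd(280L, 4L, "double", 4L)
    affine[2, ] <- rd(296L, 4L, "double", 4L)
    affine[3, ] <- rd(312L, 4L, "double", 4L)
  } else {
    diag(affine)[1:3] <- pixdim[2:4]
  }
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, ty$what, n = n, size = ty$size, endian = endian,
                  signed = ty$signed)
  if (length(vals) < n) stop("truncated NIfTI data section")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, dim = dims), affine = affine)
}
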