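#' Minimal NIfTI-1 input/output
#'
#' The package reads and writes uncompressed (`.nii`) and gzip-compressed
#' (`.nii.gz`) single-file NIfTI-1 volumes with a diagonal RAS affine.
#' Only the features needed for CVR mapping are supported: 3D/4D arrays,
#' common numeric datatypes, sform affine. No extensions are written.
#'
#' @name nifti-io
NULL

NIFTI_HDR_SIZE <- 348L

.nii_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D or 4D array as NIfTI-1
#'
#' @param data numeric array, 3 or 4 dimensions.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size length-3 voxel edge lengths in mm (diagonal affine, RAS).
#' @param tr repetition time in seconds for the 4th dimension (`pixdim[4]`).
#' @param datatype one of `"float32"`, `"float64"`, `"int16"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size = c(3, 3, 3), tr = 0,
                        datatype = "float32") {
  nd <- length(dim(data))
  if (is.null(dim(data)) || nd < 3L || nd > 4L)
    stop("write_nifti: `data` must be a 3D or 4D array")
  stopifnot(length(voxel_size) == 3L)
  dt <- switch(datatype,
    float32 = list(code = 16L, bitpix = 32L, size = 4L, what = "double"),
    float64 = list(code = 64L, bitpix = 64L, size = 8L, what = "double"),
    int16   = list(code = 4L,  bitpix = 16L, size = 2L, what = "integer"),
    stop("write_nifti: unsupported datatype ", datatype)
  )
  dims <- rep(1L, 8L)
  dims[1L] <- nd
  dims[seq_len(nd) + 1L] <- dim(data)
  pixdim <- rep(0, 8)
  pixdim[1] <- 1                       # qfac
  pixdim[2:4] <- voxel_size
  pixdim[5] <- tr

  # compose the 348-byte header in memory (gz connections cannot seek)
  hdr <- raw(NIFTI_HDR_SIZE)
  put <- function(off, bytes) {
    hdr[(off + 1L):(off + length(bytes))] <<- bytes
  }
  r_i32 <- function(x) writeBin(as.integer(x), raw(), size = 4L)
  r_i16 <- function(x) writeBin(as.integer(x), raw(), size = 2L)
  r_f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4L)
  put(0L, r_i32(NIFTI_HDR_SIZE))                 # sizeof_hdr
  put(40L, r_i16(dims))                          # dim[8]
  put(70L, r_i16(c(dt$code, dt$bitpix)))         # datatype, bitpix
  put(76L, r_f32(pixdim))                        # pixdim[8]
  put(108L, r_f32(352))                          # vox_offset
  put(112L, r_f32(c(1, 0)))                      # scl_slope, scl_inter
  put(123L, as.raw(bitwOr(2L, 8L)))              # xyzt_units: mm | sec
  desc <- charToRaw(sprintf("%-80s", "cvrmir"))
  put(148L, desc[1:80])                          # descrip
  put(252L, r_i16(c(0L, 1L)))                    # qform_code=0, sform_code=1
  srow <- rbind(c(voxel_size[1], 0, 0, 0),
                c(0, voxel_size[2], 0, 0),
                c(0, 0, voxel_size[3], 0))
  put(280L, r_f32(as.numeric(t(srow))))          # srow_x/y/z
  put(344L, c(charToRaw("n+1"), as.raw(0L)))     # magic

  con <- .nii_con(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                         # no extensions
  vals <- as.vector(data)
  if (dt$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = dt$size)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file written by this package or any
#'   NIfTI-1 writer using a single-file layout.
#' @return list with `data` (array), `voxel_size` (mm), `tr` (seconds),
#'   `affine` (4x4 voxel-to-world matrix).
#' @export
read_nifti <- function(path) {
  con <- .nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("read_nifti: truncated header in ", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("read_nifti: not a NIfTI-1 file: ", path)
  i16 <- function(off, n) readBin(hdr[(off + 1L):(off + 2L * n)], "integer",
                                  n = n, size = 2L)
  f32 <- function(off, n) readBin(hdr[(off + 1L):(off + 4L * n)], "double",
                                  n = n, size = 4L)
  dims <- i16(40L, 8L)
  nd <- dims[1L]
  shape <- dims[2L:(1L + nd)]
  datatype <- i16(70L, 1L)
  pixdim <- f32(76L, 8L)
  vox_offset <- f32(108L, 1L)
  scl_slope <- f32(112L, 1L)
  scl_inter <- f32(116L, 1L)
  sform_code <- i16(254L, 1L)
  srow <- matrix(f32(280L, 12L), nrow = 3L, byrow = TRUE)
  spec <- switch(as.character(datatype),
    "2"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "integer", size = 2L, signed = TRUE),
    "8"  = list(what = "integer", size = 4L, signed = TRUE),
    "16" = list(what = "double",  size = 4L, signed = TRUE),
    "64" = list(what = "double",  size = 8L, signed = TRUE),
    stop("read_nifti: unsupported datatype code ", datatype)
  )
  n_vox <- prod(shape)
  # skip from end of header to vox_offset
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, spec$what, n = n_vox, size = spec$size,
                  signed = spec$signed)
  if (length(vals) < n_vox) stop("read_nifti: truncated data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(as.numeric(vals), dim = shape)
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (sform_code == 0L)
    affine <- rbind(cbind(diag(pixdim[2:4]), 0), c(0, 0, 0, 1))
  list(data = data, voxel_size = abs(pixdim[2:4]), tr = pixdim[5],
       affine = affine)
}

#' Convert voxel indices to world (mm) coordinates
#'
#' @param ijk matrix (n x 3) or length-3 vector of 0-based voxel indices.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  stopifnot(ncol(ijk) == 3L, all(dim(affine) == c(4L, 4L)))
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}
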