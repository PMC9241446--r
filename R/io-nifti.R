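# Minimal NIfTI-1 codec (single-file .nii, little endian).
#
# No NIfTI package is assumed at run time; the format's fixed 348-byte
# header is written/parsed directly.  Data are stored as float32 unless
# `datatype` says otherwise on read.  Good enough for phantom volumes and
# scalar maps; not a general-purpose NIfTI library (no .hdr/.img pairs,
# no compression, no qform rotations).

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

#' Write a numeric array as a NIfTI-1 volume
#'
#' @param x numeric array (2-D, 3-D or 4-D); stored as float32.
#' @param path output file path (`.nii`).
#' @param pixdim voxel dimensions in mm (recycled/padded to the array rank).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = NULL) {
  if (!is.array(x) && !is.matrix(x)) x <- as.array(x)
  dm <- dim(x)
  nd <- length(dm)
  if (nd < 2L || nd > 4L) stop_bscb("write_nifti supports 2-D to 4-D arrays")
  if (is.null(pixdim)) pixdim <- rep(1, nd)
  pixdim <- rep_len(as.numeric(pixdim), nd)

  dim8 <- c(nd, dm, rep(1L, 7L - nd))
  pd8 <- c(1, pixdim, rep(1, 7 - nd))

  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wF <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wC <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }

  wI(348L, 4)                          # sizeof_hdr
  wC("", 10); wC("", 18)               # data_type, db_name
  wI(0L, 4); wI(0L, 2)                 # extents, session_error
  wC("r", 1); wC("", 1)                # regular, dim_info
  wI(dim8, 2)                          # dim[8]
  wF(c(0, 0, 0)); wI(0L, 2)            # intent_p1..p3, intent_code
  wI(16L, 2); wI(32L, 2); wI(0L, 2)    # datatype=float32, bitpix, slice_start
  wF(pd8)                              # pixdim[8]
  wF(352); wF(1); wF(0)                # vox_offset, scl_slope, scl_inter
  wI(0L, 2); wC("", 1)                 # slice_end, slice_code
  wC(rawToChar(as.raw(10L)), 1)        # xyzt_units: mm | sec
  wF(c(0, 0, 0, 0))                    # cal_max, cal_min, slice_duration, toffset
  wI(c(0L, 0L), 4)                     # glmax, glmin
  wC("bscbmark", 80); wC("", 24)       # descrip, aux_file
  wI(0L, 2); wI(1L, 2)                 # qform_code=0, sform_code=1
  wF(c(0, 0, 0, 0, 0, 0))              # quatern b,c,d + qoffset x,y,z
  wF(c(pd8[2], 0, 0, 0))               # srow_x
  wF(c(0, pd8[3], 0, 0))               # srow_y
  wF(c(0, 0, pd8[4], 0))               # srow_z
  wC("", 16); wC("n+1", 4)             # intent_name, magic
  writeBin(raw(4L), con)               # extension flag
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()] (or any uncompressed
#' little-endian single-file NIfTI with a supported datatype)
#'
#' @param path `.nii` file path.
#' @return numeric array with attribute `pixdim`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  rI <- function(off, size, n = 1L, signed = TRUE)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = "little")
  rF <- function(off, n = 1L)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4L,
            endian = "little")
  if (rI(0, 4) != 348L) stop_bscb("not a NIfTI-1 file (sizeof_hdr != 348): %s", path)
  dim8 <- rI(40, 2, 8)
  nd <- dim8[1]
  dm <- dim8[2:(1 + nd)]
  datatype <- rI(70, 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop_bscb("unsupported NIfTI datatype code %d", datatype)
  pixdim <- rF(76, 8)[2:(1 + nd)]
  vox_offset <- rF(108)
  scl_slope <- rF(112); scl_inter <- rF(116)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(dm)
  x <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = "little")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  out <- array(as.numeric(x), dim = dm)
  attr(out, "pixdim") <- pixdim
  out
}
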