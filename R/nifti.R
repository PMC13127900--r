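#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained reader/writer for uncompressed single-file NIfTI-1 (`.nii`)
#' volumes, covering the subset this package emits: 3D/4D arrays, uint8,
#' int16, int32 or float32 storage, diagonal sform affine built from the
#' voxel dimensions. No gzip, quaternions, extensions or scaling slopes.
#' No NIfTI package is assumed to be installed; for anything beyond this
#' subset use a dedicated neuroimaging I/O package.
#'
#' @param x numeric or integer array (3D or 4D).
#' @param path file path ending in `.nii`.
#' @param voxel_size_mm numeric length-3, stored in `pixdim[2:4]`. For gapped
#'   multislice data the third entry should be the *interslice spacing*, not
#'   the slice thickness (the convention used throughout this package).
#' @param datatype one of `"auto"`, `"uint8"`, `"int16"`, `"int32"`,
#'   `"float32"`. `"auto"` picks uint8/int16 for label-like integer data and
#'   float32 otherwise.
#' @return `write_nifti()` returns `path` invisibly. `read_nifti()` returns a
#'   list with elements `data` (array), `voxel_size_mm` and `datatype`.
#' @examples
#' f <- tempfile(fileext = ".nii")
#' write_nifti(array(1:24, c(2, 3, 4)), f, voxel_size_mm = c(2.4, 2.4, 10))
#' v <- read_nifti(f)
#' stopifnot(identical(dim(v$data), c(2L, 3L, 4L)))
#' @export
write_nifti <- function(x, path, voxel_size_mm = c(1, 1, 1),
                        datatype = "auto") {
  dm <- dim(x)
  if (is.null(dm) || !(length(dm) %in% c(3L, 4L)))
    stop("write_nifti: 'x' must be a 3D or 4D array")
  if (identical(datatype, "auto")) {
    iv <- is.integer(x) ||
      (is.numeric(x) && all(x == round(x)) && max(abs(range(x))) < 32767)
    datatype <- if (iv) {
      if (min(x) >= 0 && max(x) <= 255) "uint8" else "int16"
    } else "float32"
  }
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L,
                 stop("write_nifti: unsupported datatype ", datatype))
  bitpix <- switch(datatype, uint8 = 8L, int16 = 16L, int32 = 32L,
                   float32 = 32L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  wi(348L, 4)                                    # sizeof_hdr
  writeBin(raw(36), con)                         # unused through dim_info
  d8 <- c(length(dm), dm, rep(1L, 7 - length(dm)))
  wi(d8, 2)                                      # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                      # intent_p1..3, intent_code
  wi(code, 2); wi(bitpix, 2); wi(0L, 2)          # datatype, bitpix, slice_start
  pix <- c(1, voxel_size_mm, rep(1, 4))
  wf(pix)                                        # pixdim[8]
  wf(352); wf(1); wf(0)                          # vox_offset, scl_slope/inter
  wi(0L, 2); writeBin(raw(1), con)               # slice_end, slice_code
  wi(10L, 1)                                     # xyzt_units = mm | sec
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)            # cal_max.. glmin
  writeBin(raw(104), con)                        # descrip + aux_file
  wi(0L, 2); wi(1L, 2)                           # qform_code 0, sform_code 1
  wf(rep(0, 6))                                  # quaternions
  wf(c(voxel_size_mm[1], 0, 0, 0))               # srow_x
  wf(c(0, voxel_size_mm[2], 0, 0))               # srow_y
  wf(c(0, 0, voxel_size_mm[3], 0))               # srow_z
  writeBin(raw(16), con)                         # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); writeBin(raw(1), con)
  writeBin(raw(4), con)                          # extension flag
  vals <- as.vector(x)
  if (datatype == "float32") {
    writeBin(as.double(vals), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(vals), con,
             size = if (datatype == "uint8") 1 else if (datatype == "int16") 2 else 4,
             endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")
  sz <- ri(1, 4)
  if (!identical(sz, 348L)) stop("read_nifti: not a little-endian NIfTI-1 file")
  invisible(readBin(con, "raw", 36))
  dm <- ri(8, 2)
  invisible(rf(3)); invisible(ri(1, 2))          # intent_p1..3, intent_code
  code <- ri(1, 2); invisible(ri(2, 2))          # datatype; bitpix, slice_start
  pix <- rf(8)
  vox_offset <- rf(1); invisible(rf(2))
  ndim <- dm[1]
  dims <- dm[2:(1 + ndim)]
  n <- prod(dims)
  seek(con, vox_offset)
  data <- switch(as.character(code),
    "2"  = readBin(con, "integer", n = n, size = 1, signed = FALSE,
                   endian = "little"),
    "4"  = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "8"  = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "16" = readBin(con, "double",  n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double",  n = n, size = 8, endian = "little"),
    stop("read_nifti: unsupported datatype code ", code))
  dim(data) <- dims
  list(data = data, voxel_size_mm = pix[2:4],
       datatype = switch(as.character(code), "2" = "uint8", "4" = "int16",
                         "8" = "int32", "16" = "float32", "64" = "float64"))
}
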