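# Minimal NIfTI-1 I/O.
#
# No NIfTI package ships with this environment, so the package carries a
# small, strict reader/writer for the subset of NIfTI-1 it needs: 3D/4D
# single-file .nii (optionally gzipped), little-endian, float32/float64/
# int16/uint8 data, pixdim voxel sizes, no extensions. That subset is enough
# to interoperate with nibabel/SPM/FSL for the volumes this package produces.

nifti_datatypes <- list(
  "2"  = list(what = "integer", size = 1L, signed = FALSE, r = "integer"),
  "4"  = list(what = "integer", size = 2L, signed = TRUE,  r = "integer"),
  "8"  = list(what = "integer", size = 4L, signed = TRUE,  r = "integer"),
  "16" = list(what = "double",  size = 4L, signed = TRUE,  r = "double"),
  "64" = list(what = "double",  size = 8L, signed = TRUE,  r = "double")
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D or 4D array as a NIfTI-1 volume
#'
#' Writes a single-file little-endian `.nii` (gzipped when the path ends in
#' `.gz`). Doubles are stored as float64 by default so that write/read
#' round-trips are bit-exact; pass `datatype = "float32"` for compactness.
#'
#' @param data Numeric 3D or 4D array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm Numeric length-3 voxel size in millimetres.
#' @param tr_s Repetition time in seconds stored in `pixdim[4]` (0 for 3D).
#' @param datatype `"float64"`, `"float32"`, `"int16"` or `"uint8"`.
#' @return The path, invisibly.
#' @export
nifti_write <- function(data, path, voxel_size_mm = c(1, 1, 1), tr_s = 0,
                        datatype = "float64") {
  nd <- length(dim(data))
  if (!(nd %in% c(3L, 4L))) stop_sl("nifti_write: data must be 3D or 4D")
  if (any(!is.finite(data))) stop_sl("nifti_write: non-finite values in data")
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop_sl("nifti_write: unsupported datatype '%s'", datatype))
  info <- nifti_datatypes[[as.character(code)]]
  dims <- dim(data)
  dim_field <- c(nd, dims, rep(1L, 7 - nd))
  pixdim <- c(0, voxel_size_mm, if (nd == 4L) tr_s else 0, 0, 0, 0)

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wI <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wF <- function(x, size = 4L) writeBin(as.double(x), con, size = size,
                                        endian = "little")
  wC <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), len))],
               raw(len - min(length(raw), len))), con)
  }
  wI(348L, 4)                      # sizeof_hdr
  wC("", 10); wC("", 18)           # data_type, db_name (unused)
  wI(0L, 4); wI(0L, 2); wC("r", 1) # extents, session_error, regular
  writeBin(as.raw(0L), con)        # dim_info
  wI(dim_field, 2)
  wF(rep(0, 3)); wI(0L, 2)         # intent_p1..p3, intent_code
  wI(code, 2)                      # datatype
  wI(info$size * 8L, 2)            # bitpix
  wI(0L, 2)                        # slice_start
  wF(pixdim)
  wF(352)                          # vox_offset
  wF(1); wF(0)                     # scl_slope, scl_inter
  wI(0L, 2); writeBin(as.raw(c(0L, 0L)), con)  # slice_end, slice_code, xyzt
  wF(0); wF(0)                     # cal_max, cal_min
  wF(0); wI(0L, 4); wI(0L, 4)      # slice_duration, toffset, glmax
  wI(0L, 4)                        # glmin
  wC("soundloc3d", 80)             # descrip
  wC("", 24)                       # aux_file
  wI(0L, 2); wI(1L, 2)             # qform_code = 0, sform_code = 1
  wF(rep(0, 6))                    # quaternions b,c,d + qoffsets... (6 floats)
  # srow: diagonal voxel-size affine
  wF(c(voxel_size_mm[1], 0, 0, 0))
  wF(c(0, voxel_size_mm[2], 0, 0))
  wF(c(0, 0, voxel_size_mm[3], 0))
  wC("", 16)                       # intent_name
  wC("n+1", 4)                     # magic
  writeBin(raw(4L), con)           # extension flag: none
  if (info$what == "integer") {
    wI(as.vector(data), info$size)
  } else {
    wF(as.vector(data), info$size)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package (or any compatible writer)
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (3D/4D array), `voxel_size_mm`, `tr_s`,
#'   `datatype`.
#' @export
nifti_read <- function(path) {
  if (!file.exists(path)) stop_sl("nifti_read: no such file: %s", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 348L) stop_sl("nifti_read: truncated header in %s", path)
  rI <- function(off, size, n = 1L) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rF <- function(off, n = 1L, size = 4L) {
    readBin(hdr[(off + 1L):(off + size * n)], "double", n = n, size = size,
            endian = "little")
  }
  if (rI(0L, 4L) != 348L) stop_sl("nifti_read: %s is not NIfTI-1 (bad sizeof_hdr)", path)
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop_sl("nifti_read: unsupported magic '%s' in %s", magic, path)
  dim_field <- rI(40L, 2L, 8L)
  nd <- dim_field[1]
  if (!(nd %in% c(3L, 4L))) stop_sl("nifti_read: only 3D/4D supported (got %dD)", nd)
  dims <- dim_field[2:(1 + nd)]
  code <- rI(70L, 2L)
  info <- nifti_datatypes[[as.character(code)]]
  if (is.null(info)) stop_sl("nifti_read: unsupported datatype code %d", code)
  pixdim <- rF(76L, 8L)
  vox_offset <- rF(108L)
  slope <- rF(112L); inter <- rF(116L)
  skip <- vox_offset - 352L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, info$what, n = n, size = info$size,
                  signed = info$signed, endian = "little")
  if (length(vals) < n) stop_sl("nifti_read: %s truncated (%d of %d values)",
                                path, length(vals), n)
  if (slope != 0 && !(slope == 1 && inter == 0)) vals <- vals * slope + inter
  list(data = array(vals, dims),
       voxel_size_mm = pixdim[2:4],
       tr_s = if (nd == 4L) pixdim[5] else 0,
       datatype = switch(as.character(code), "2" = "uint8", "4" = "int16",
                         "8" = "int32", "16" = "float32", "64" = "float64"))
}
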