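# Minimal NIfTI-1 single-file (.nii / .nii.gz) input/output.
#
# No NIfTI package is assumed: the format's 348-byte header is written and
# parsed directly with readBin/writeBin. Only what a CBF analysis needs is
# supported: 3D scalar volumes, little- or big-endian ingest, datatypes
# uint8/int16/int32/float32/float64, scl_slope/scl_inter rescaling on read,
# float32 (default) or uint8 on write. Orientation metadata beyond pixdim
# is passed through as identity; inputs are assumed already spatially
# normalized to a common grid.

.nifti_types <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

.nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param vol a [volume3d] object, or a plain 3D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"float32"` (default) or `"uint8"` (for masks/atlases).
#' @param voxel_size numeric length-3 voxel edges in mm; taken from `vol`
#'   when it is a `volume3d`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = c("float32", "uint8", "int32"),
                        voxel_size = c(2, 2, 2)) {
  datatype <- match.arg(datatype)
  if (inherits(vol, "volume3d")) {
    voxel_size <- vol$voxel_size
    vol <- vol$data
  }
  if (length(dim(vol)) != 3L) stop("write_nifti expects a 3D array", call. = FALSE)
  ty <- .nifti_types[[datatype]]
  con <- .nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wd <- function(x, size) writeBin(as.double(x), con, size = size, endian = "little")
  wc <- function(s, len) {
    r <- c(charToRaw(s), raw(len))[seq_len(len)]
    writeBin(r, con)
  }
  wi(348L, 4)                         # sizeof_hdr
  wc("", 10); wc("", 18); wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)
  wi(c(3L, dim(vol), 1L, 1L, 1L, 1L), 2)  # dim[8]
  wd(c(0, 0, 0), 4); wi(0L, 2)             # intent_p1-3, intent_code
  wi(ty$code, 2); wi(ty$bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wd(c(0, voxel_size, 1, 0, 0, 0), 4)     # pixdim[8] (qfac 0)
  wd(352, 4)                               # vox_offset
  wd(c(1, 0), 4)                           # scl_slope, scl_inter
  wi(0L, 2); wi(0L, 1); wi(0L, 1)          # slice_end, slice_code, xyzt_units
  wd(c(0, 0, 0, 0), 4)                     # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4)                         # glmax, glmin
  wc("", 80); wc("", 24)                   # descrip, aux_file
  wi(c(0L, 1L), 2)                         # qform_code, sform_code
  wd(c(0, 0, 0, 0, 0, 0), 4)               # quatern b,c,d, qoffset x,y,z
  wd(c(voxel_size[1], 0, 0, 0), 4)         # srow_x
  wd(c(0, voxel_size[2], 0, 0), 4)         # srow_y
  wd(c(0, 0, voxel_size[3], 0), 4)         # srow_z
  wc("", 16)                               # intent_name
  wc("n+1", 4)                             # magic
  writeBin(raw(4), con)                    # extension flag
  if (ty$what == "integer") {
    writeBin(as.integer(round(vol)), con, size = ty$size, endian = "little")
  } else {
    writeBin(as.double(vol), con, size = ty$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file NIfTI-1 (`.nii`/`.nii.gz`). 4D inputs with a trailing
#' singleton dimension are squeezed to 3D. `scl_slope`/`scl_inter` are
#' applied when `scl_slope != 0`.
#'
#' @param path file path.
#' @param subject_id id attached to the returned volume; defaults to the
#'   file name without extension.
#' @return a [volume3d].
#' @export
read_nifti <- function(path, subject_id = NULL) {
  subject_id <- subject_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  con <- .nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, raw(), n = 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file (short header): ", path, call. = FALSE)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "': ", path, call. = FALSE)
  dims <- readBin(hdr_raw[41:56], "integer", n = 8, size = 2, endian = endian)
  ndim <- dims[1]
  shape <- dims[2:(1 + max(ndim, 3))]
  shape[shape == 0L] <- 1L
  if (ndim > 3L && any(shape[4:ndim] != 1L)) {
    stop("only 3D volumes are supported: ", path, call. = FALSE)
  }
  shape <- shape[1:3]
  dt_code <- readBin(hdr_raw[71:72], "integer", size = 2, endian = endian)
  ty_idx <- vapply(.nifti_types, function(t) t$code == dt_code, logical(1))
  if (!any(ty_idx)) stop("unsupported NIfTI datatype code ", dt_code, ": ", path, call. = FALSE)
  ty <- .nifti_types[[which(ty_idx)]]
  pixdim <- readBin(hdr_raw[77:108], "double", n = 8, size = 4, endian = endian)
  vox_offset <- readBin(hdr_raw[109:112], "double", size = 4, endian = endian)
  scl_slope <- readBin(hdr_raw[113:116], "double", size = 4, endian = endian)
  scl_inter <- readBin(hdr_raw[117:120], "double", size = 4, endian = endian)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, raw(), n = as.integer(skip))
  n_vox <- prod(shape)
  vals <- readBin(con, ty$what, n = n_vox, size = ty$size,
                  signed = ty$signed, endian = endian)
  if (length(vals) < n_vox) stop("truncated NIfTI data: ", path, call. = FALSE)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  volume3d(array(as.double(vals), dim = shape),
           voxel_size = pixdim[2:4], subject_id = subject_id)
}
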