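# Minimal uncompressed NIfTI-1 (.nii) support: enough to export component
# maps scattered into a binary mask and to read masks/volumes back. Data are
# stored as float32 (written) and read for the common numeric datatypes.
# Header layout follows the NIfTI-1 standard (348-byte header, single-file
# magic "n+1", data at byte 352, identity sform).

.nifti_pad <- function(con, n) writeBin(raw(n), con)

#' Write a 3-D or 4-D array as an uncompressed NIfTI-1 volume
#'
#' @param data Numeric array (3-D volume or 4-D stack).
#' @param path Output path ending in `.nii`.
#' @param pixdim Voxel sizes, recycled to 3 values.
#' @return `path`, invisibly. Values are stored as float32.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1)) {
  if (!(length(dim(data)) %in% c(3L, 4L))) {
    stop("data must be a 3-D or 4-D array")
  }
  dims <- dim(data)
  ndim <- length(dims)
  dim_field <- rep(1L, 8L)
  dim_field[1] <- ndim
  dim_field[1 + seq_len(ndim)] <- dims
  pixdim <- rep_len(pixdim, 3L)
  pixdim_field <- c(1, pixdim, 1, 1, 1, 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  .nifti_pad(con, 36L)                                      # through dim_info
  writeBin(as.integer(dim_field), con, size = 2, endian = "little")
  .nifti_pad(con, 14L)                                      # intent fields
  writeBin(16L, con, size = 2, endian = "little")           # datatype float32
  writeBin(32L, con, size = 2, endian = "little")           # bitpix
  writeBin(0L, con, size = 2, endian = "little")            # slice_start
  writeBin(pixdim_field, con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")           # vox_offset
  writeBin(1, con, size = 4, endian = "little")             # scl_slope
  writeBin(0, con, size = 4, endian = "little")             # scl_inter
  .nifti_pad(con, 4L)                                       # slice_end..xyzt
  .nifti_pad(con, 24L)                                      # cal/slice/toffset
  .nifti_pad(con, 104L)                                     # descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")     # qform=0 sform=1
  .nifti_pad(con, 24L)                                      # quatern/qoffset
  srow <- rbind(c(pixdim[1], 0, 0, 0),
                c(0, pixdim[2], 0, 0),
                c(0, 0, pixdim[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4, endian = "little")
  .nifti_pad(con, 16L)                                      # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)                                     # magic NUL
  .nifti_pad(con, 4L)                                       # extension flag
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 volume
#'
#' Supports datatypes uint8, int16, int32, float32 and float64 and both
#' endiannesses; applies the scale slope/intercept when set.
#'
#' @param path Path to an uncompressed `.nii` file.
#' @return List with `data` (array), `dim`, `pixdim`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (hdr_size != 348L) endian <- "big"  # dim sanity check below validates
  seek(con, 40)
  dim_field <- readBin(con, "integer", 8, size = 2, endian = endian)
  if (dim_field[1] < 1 || dim_field[1] > 7) stop("not a NIfTI-1 file: ", path)
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  dims <- dim_field[1 + seq_len(dim_field[1])]
  n <- prod(dims)
  seek(con, max(vox_offset, 352))
  vals <- switch(as.character(datatype),
    "2"  = readBin(con, "integer", n, size = 1, signed = FALSE,
                   endian = endian),
    "4"  = readBin(con, "integer", n, size = 2, endian = endian),
    "8"  = readBin(con, "integer", n, size = 4, endian = endian),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype: ", datatype)
  )
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(as.numeric(vals), dim = dims), dim = dims,
       pixdim = pixdim[2:4])
}

#' Export component maps into a masked volume
#'
#' Scatters each column of `maps` into the nonzero voxels of `mask` (in the
#' mask's column-major order, the package-wide voxel-order convention) and
#' writes a 4-D NIfTI-1 stack with zeros outside the mask.
#'
#' @param maps V x N numeric matrix, V = number of in-mask voxels.
#' @param mask 3-D array; nonzero entries define the voxel order.
#' @param path Output `.nii` path.
#' @param pixdim Voxel sizes.
#' @return `path`, invisibly.
#' @export
write_component_volumes <- function(maps, mask, path, pixdim = c(1, 1, 1)) {
  maps <- as.matrix(maps)
  mask <- (mask != 0)
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  v <- sum(mask)
  if (v != nrow(maps)) {
    stop(sprintf("mask/voxel-count mismatch: mask has %d voxels, maps %d rows",
                 v, nrow(maps)))
  }
  n <- ncol(maps)
  out <- array(0, dim = c(dim(mask), n))
  idx <- which(mask)
  nvol <- prod(dim(mask))
  for (j in seq_len(n)) {
    out[idx + (j - 1L) * nvol] <- maps[, j]
  }
  write_nifti(out, path, pixdim = pixdim)
}
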