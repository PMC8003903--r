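# NIfTI-1 reader/writer (uncompressed .nii, single file, 3D or 4D).
# Implemented against the published 348-byte header layout because no NIfTI
# package is available in the target environment. Data are stored as
# float64 by default so that write/read round-trips are exact; the sform
# carries the geometry under the zero-based voxel-center convention used
# throughout the package.

.NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, bitpix = 8),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32),
  `16` = list(what = "double",  size = 4, signed = TRUE,  bitpix = 32),
  `64` = list(what = "double",  size = 8, signed = TRUE,  bitpix = 64)
)

#' Write a 3D or 4D array as NIfTI-1
#'
#' @param data numeric array (3D, or 4D with the 4th axis e.g. echoes).
#' @param geometry an [image_geometry()] for the first three axes.
#' @param path output path (`.nii`, uncompressed).
#' @param datatype NIfTI datatype code: 64 (float64, default, lossless for
#'   doubles) or 16 (float32).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, geometry, path, datatype = 64) {
  .assert(is.array(data) && length(dim(data)) %in% c(3, 4),
          "data must be a 3D or 4D array")
  .assert(inherits(geometry, "image_geometry"), "geometry must be an image_geometry")
  .assert(all(dim(data)[1:3] == geometry$dims),
          "geometry dims do not match the data array")
  dt <- .NIFTI_DTYPES[[as.character(datatype)]]
  .assert(!is.null(dt) && datatype %in% c(16, 64),
          "datatype must be 16 (float32) or 64 (float64)")
  nd <- length(dim(data))
  dim8 <- rep(1L, 8); dim8[1] <- nd; dim8[1 + seq_len(nd)] <- dim(data)
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:4] <- geometry$spacing
  if (nd == 4) pixdim[5] <- 1
  aff <- geometry$direction %*% diag(geometry$spacing)

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size, what = "integer") {
    writeBin(x, con, size = size, endian = "little", useBytes = TRUE)
  }
  wchar <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), n))],
               rep(as.raw(0), max(0, n - length(raw)))), con)
  }
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  wchar("", 10); wchar("", 18)                              # data_type, db_name
  writeBin(0L, con, size = 4, endian = "little")            # extents
  writeBin(0L, con, size = 2, endian = "little")            # session_error
  writeBin(charToRaw("r"), con)                             # regular
  writeBin(as.raw(0), con)                                  # dim_info
  writeBin(as.integer(dim8), con, size = 2, endian = "little")
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")    # intent_p1..p3
  writeBin(0L, con, size = 2, endian = "little")            # intent_code
  writeBin(as.integer(datatype), con, size = 2, endian = "little")
  writeBin(as.integer(dt$bitpix), con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")            # slice_start
  writeBin(as.numeric(pixdim), con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")           # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")       # scl_slope, scl_inter
  writeBin(0L, con, size = 2, endian = "little")            # slice_end
  writeBin(as.raw(c(0, 2)), con)                            # slice_code, xyzt_units (mm)
  writeBin(c(0, 0, 0, 0), con, size = 4, endian = "little") # cal_max..toffset
  writeBin(c(0L, 0L), con, size = 4, endian = "little")     # glmax, glmin
  wchar("qmricart", 80); wchar("", 24)                      # descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")     # qform_code, sform_code
  writeBin(rep(0, 6), con, size = 4, endian = "little")     # quatern, qoffset
  for (r in 1:3) {
    writeBin(c(aff[r, ], geometry$origin[r]), con, size = 4, endian = "little")
  }
  wchar("", 16)                                             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)             # magic
  writeBin(rep(as.raw(0), 4), con)                          # extension flag
  if (datatype == 64) {
    writeBin(as.numeric(data), con, size = 8, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' Supports uncompressed single-file NIfTI-1 (3D or 4D) with datatypes
#' uint8, int16, int32, float32, float64, either endianness.
#'
#' @param path path to a `.nii` file.
#' @return list with `data` (array) and `geometry` ([image_geometry()];
#'   sform when present, else spacing-only).
#' @export
read_nifti <- function(path) {
  .assert(file.exists(path), paste("file not found:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sz <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = endian)
    .assert(sz == 348L, "malformed NIfTI: field sizeof_hdr is not 348")
  }
  seek(con, 40)
  dim8 <- readBin(con, "integer", 8, size = 2, endian = endian)
  .assert(dim8[1] %in% 3:4, "malformed NIfTI: field dim[0] must be 3 or 4")
  dims <- dim8[1 + seq_len(dim8[1])]
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  dt <- .NIFTI_DTYPES[[as.character(datatype)]]
  .assert(!is.null(dt), paste("malformed NIfTI: unsupported field datatype", datatype))
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  seek(con, 108)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  seek(con, 112)
  scl <- readBin(con, "numeric", 2, size = 4, endian = endian)
  seek(con, 254)
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 280)
  srow <- matrix(readBin(con, "numeric", 12, size = 4, endian = endian),
                 nrow = 3, byrow = TRUE)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  .assert(magic %in% c("n+1", "ni1"), "malformed NIfTI: field magic")

  n <- prod(dims)
  seek(con, vox_offset)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  .assert(length(vals) == n, "malformed NIfTI: truncated data section")
  vals <- as.numeric(vals)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) {
    vals <- vals * scl[1] + scl[2]
  }
  if (sform_code >= 1) {
    a <- srow[, 1:3]
    spacing <- sqrt(colSums(a^2))
    direction <- sweep(a, 2, spacing, "/")
    origin <- srow[, 4]
  } else {
    spacing <- pixdim[2:4]
    direction <- diag(3)
    origin <- c(0, 0, 0)
  }
  geom <- image_geometry(origin = origin, spacing = spacing,
                         direction = direction, dims = dims[1:3])
  list(data = array(vals, dims), geometry = geom)
}

#' Write a multi-echo volume as 4D NIfTI with a JSON sidecar
#'
#' The echo axis is the 4th NIfTI dimension; echo times (ms) are recorded
#' in a sidecar `<path minus .nii>.json` under `EchoTimes`.
#'
#' @param volume a [multi_echo_volume()].
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  .assert(inherits(volume, "multi_echo_volume"), "volume must be a multi_echo_volume")
  write_nifti(volume$data, volume$geometry, path)
  sidecar <- sub("\\.nii$", ".json", path)
  jsonlite::write_json(list(EchoTimes = volume$echo_times), sidecar,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-echo volume from NIfTI
#'
#' Accepts a single 4D file, or a character vector of per-echo 3D files
#' (ascending echo order) whose geometries must agree.
#'
#' @param path one 4D `.nii` path or several 3D `.nii` paths.
#' @param echo_times echo times (ms); when `NULL`, read from the JSON
#'   sidecar of the (first) file.
#' @return a [multi_echo_volume()].
#' @export
read_volume <- function(path, echo_times = NULL) {
  if (is.null(echo_times)) {
    sidecar <- sub("\\.nii$", ".json", path[1])
    .assert(file.exists(sidecar),
            "echo_times not given and no JSON sidecar found")
    echo_times <- as.numeric(jsonlite::read_json(sidecar,
                                                 simplifyVector = TRUE)$EchoTimes)
  }
  if (length(path) == 1L) {
    nii <- read_nifti(path)
    .assert(length(dim(nii$data)) == 4, "expected a 4D multi-echo NIfTI")
    return(multi_echo_volume(echo_times, nii$data, nii$geometry))
  }
  parts <- lapply(path, read_nifti)
  g0 <- parts[[1]]$geometry
  for (p in parts[-1]) {
    same <- max(abs(p$geometry$origin - g0$origin),
                abs(p$geometry$spacing - g0$spacing),
                abs(p$geometry$direction - g0$direction)) < 1e-6 &&
      all(p$geometry$dims == g0$dims)
    .assert(same, "geometry mismatch across per-echo files")
  }
  data <- array(0, c(g0$dims, length(parts)))
  for (i in seq_along(parts)) data[, , , i] <- parts[[i]]$data
  multi_echo_volume(echo_times, data, g0)
}
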