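# Minimal DICOM reader for geometry-header extraction only (explicit VR,
# little endian). The registration stage needs six tags: Rows, Columns,
# PixelSpacing, SliceThickness, ImagePositionPatient and
# ImageOrientationPatient; everything else is skipped.

.DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Extract image geometry from a DICOM header
#'
#' Reads an explicit-VR little-endian DICOM file and returns the acquisition
#' geometry needed for header-based registration. The direction matrix
#' columns are the row direction, the column direction
#' (ImageOrientationPatient) and their cross product (slice normal);
#' spacing combines PixelSpacing with SliceThickness; the origin is
#' ImagePositionPatient.
#'
#' @param path path to a DICOM file.
#' @param n_slices number of slices for the third dimension (a single file
#'   carries one frame; default 1).
#' @return an [image_geometry()].
#' @export
read_dicom_geometry <- function(path, n_slices = 1L) {
  .assert(file.exists(path), paste("file not found:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132)
  .assert(length(preamble) == 132 &&
            rawToChar(preamble[129:132]) == "DICM",
          "malformed DICOM: missing DICM magic")
  want <- c("0028,0010", "0028,0011", "0028,0030", "0018,0050",
            "0020,0032", "0020,0037")
  got <- list()
  repeat {
    hdr <- readBin(con, "raw", 8)
    if (length(hdr) < 8) break
    group <- readBin(hdr[1:2], "integer", 1, size = 2, signed = FALSE,
                     endian = "little")
    elem <- readBin(hdr[3:4], "integer", 1, size = 2, signed = FALSE,
                    endian = "little")
    vr <- rawToChar(hdr[5:6])
    if (vr %in% .DICOM_LONG_VRS) {
      len <- readBin(con, "integer", 1, size = 4, endian = "little")
    } else {
      len <- readBin(hdr[7:8], "integer", 1, size = 2, signed = FALSE,
                     endian = "little")
    }
    tag <- sprintf("%04x,%04x", group, elem)
    if (tag == "7fe0,0010") break  # pixel data: nothing else to read
    if (len < 0) stop("malformed DICOM: negative length for tag ", tag,
                      call. = FALSE)
    val <- readBin(con, "raw", len)
    .assert(length(val) == len,
            paste("malformed DICOM: truncated value for tag", tag))
    if (tag %in% want) {
      got[[tag]] <- switch(vr,
        US = readBin(val, "integer", len / 2, size = 2, signed = FALSE,
                     endian = "little"),
        DS = as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
        stop("malformed DICOM: unexpected VR ", vr, " for tag ", tag,
             call. = FALSE)
      )
    }
    if (all(want %in% names(got))) break
  }
  miss <- setdiff(want, names(got))
  .assert(length(miss) == 0,
          paste("malformed DICOM: missing tag(s)", paste(miss, collapse = ", ")))
  rows <- got[["0028,0010"]]; cols <- got[["0028,0011"]]
  ps <- got[["0028,0030"]]; st <- got[["0018,0050"]]
  ipp <- got[["0020,0032"]]; iop <- got[["0020,0037"]]
  .assert(length(ps) == 2 && length(ipp) == 3 && length(iop) == 6,
          "malformed DICOM: wrong multiplicity in geometry tags")
  rdir <- iop[1:3]; cdir <- iop[4:6]
  ndir <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
            rdir[3] * cdir[1] - rdir[1] * cdir[3],
            rdir[1] * cdir[2] - rdir[2] * cdir[1])
  # PixelSpacing is (row spacing, column spacing): distance between rows
  # first. Our first axis advances along the row direction, i.e. across
  # columns, so it carries the column spacing.
  image_geometry(origin = ipp,
                 spacing = c(ps[2], ps[1], st),
                 direction = cbind(rdir, cdir, ndir),
                 dims = c(cols, rows, n_slices))
}
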