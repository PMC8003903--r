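# Writes a minimal synthetic explicit-VR little-endian DICOM file carrying
# only the geometry tags the package reads. Used as the fixture oracle: the
# values planted here must come back from read_dicom_geometry().

write_dicom_fixture <- function(path, rows, cols, pixel_spacing,
                                slice_thickness, ipp, iop) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  elem <- function(group, el, vr, payload) {
    writeBin(as.integer(group), con, size = 2, endian = "little")
    writeBin(as.integer(el), con, size = 2, endian = "little")
    writeBin(charToRaw(vr), con)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      writeBin(as.raw(c(0, 0)), con)
      writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(length(payload)), con, size = 2, endian = "little")
    }
    writeBin(payload, con)
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
  ds <- function(x) {
    s <- paste(sprintf("%.10g", x), collapse = "\\")
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")  # DICOM values have even length
    charToRaw(s)
  }
  # a couple of tags the reader must skip over without stumbling
  elem(0x0008, 0x0060, "CS", charToRaw("MR"))
  elem(0x0018, 0x0050, "DS", ds(slice_thickness))
  elem(0x0020, 0x0032, "DS", ds(ipp))
  elem(0x0020, 0x0037, "DS", ds(iop))
  elem(0x0028, 0x0010, "US", us(rows))
  elem(0x0028, 0x0011, "US", us(cols))
  elem(0x0028, 0x0030, "DS", ds(pixel_spacing))
  invisible(path)
}
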