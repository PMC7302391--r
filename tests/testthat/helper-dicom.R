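# Write a tiny synthetic single-frame DICOM (explicit VR, little endian,
# 16-bit unsigned) for I/O tests.
write_test_dicom <- function(path, pixels, slope = 1, intercept = 0) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  elem_us <- function(g, e, val) {
    w16(g); w16(e); writeChar("US", con, eos = NULL); w16(2L); w16(val)
  }
  elem_ds <- function(g, e, s) {
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    w16(g); w16(e); writeChar("DS", con, eos = NULL); w16(nchar(s))
    writeChar(s, con, eos = NULL)
  }
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  elem_us(0x0028, 0x0002, 1L)             # SamplesPerPixel
  elem_us(0x0028, 0x0010, nrow(pixels))   # Rows
  elem_us(0x0028, 0x0011, ncol(pixels))   # Columns
  elem_us(0x0028, 0x0100, 16L)            # BitsAllocated
  elem_us(0x0028, 0x0103, 0L)             # PixelRepresentation (unsigned)
  elem_ds(0x0028, 0x1052, as.character(intercept))
  elem_ds(0x0028, 0x1053, as.character(slope))
  w16(0x7FE0); w16(0x0010)
  writeChar("OW", con, eos = NULL); w16(0L)
  writeBin(2L * length(pixels), con, size = 4L, endian = "little")
  writeBin(as.integer(t(pixels)), con, size = 2L, endian = "little")
  invisible(path)
}
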