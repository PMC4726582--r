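# Minimal single-frame CT DICOM codec: Explicit VR Little Endian only,
# 16-bit monochrome pixel data, the rescale tags required to recover HU.
# Enough to round-trip the package's own output and to ingest simple
# scanner exports; encapsulated/compressed transfer syntaxes are rejected.

.dcm_uid_explicit_le <- "1.2.840.10008.1.2.1"
.dcm_uid_ct_storage <- "1.2.840.10008.5.1.4.1.1.2"
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")

.dcm_pad <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

# Encode one data element in Explicit VR LE.
.dcm_elem <- function(group, elem, vr, value) {
  body <- switch(vr,
    US = .dcm_uint16(value),
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    UI = .dcm_pad(charToRaw(value), as.raw(0x00)),
    OW = value,  # caller supplies raw
    .dcm_pad(charToRaw(as.character(value))))  # CS/LO/DS/...
  len <- length(body)
  hdr <- c(.dcm_uint16(group), .dcm_uint16(elem), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    hdr <- c(hdr, as.raw(c(0, 0)),
             writeBin(as.integer(len), raw(), size = 4, endian = "little"))
  } else {
    hdr <- c(hdr, .dcm_uint16(len))
  }
  c(hdr, body)
}

.dcm_format_ds <- function(x) {
  # DS values are at most 16 bytes
  s <- formatC(x, format = "g", digits = 10)
  substr(s, 1, 16)
}

# Write one ct_slice as a DICOM file. HU are stored as int16 with
# slope 1 / intercept -1024, so quantization error is at most 0.5 HU.
write_dicom_file <- function(slice, path, instance = 1L) {
  px <- slice$pixels
  slope <- 1
  intercept <- -1024
  stored <- round_half_up((px - intercept) / slope)
  stored[stored < 0] <- 0
  stored[stored > 32767] <- 32767
  # DICOM pixel order is row-major (first row left to right)
  stored_rm <- as.integer(t(stored))
  pix_raw <- writeBin(stored_rm, raw(), size = 2, endian = "little")

  sop_uid <- sprintf("1.2.826.0.1.3680043.9.7435.1.%d.%d",
                     as.integer(Sys.getpid()) %% 100000L, instance)
  meta <- c(
    .dcm_elem(0x0002, 0x0002, "UI", .dcm_uid_ct_storage),
    .dcm_elem(0x0002, 0x0003, "UI", sop_uid),
    .dcm_elem(0x0002, 0x0010, "UI", .dcm_uid_explicit_le))
  meta <- c(.dcm_elem(0x0002, 0x0000, "UL", length(meta)), meta)

  loc <- if (is.na(slice$slice_location)) 0 else slice$slice_location
  pid <- if (is.na(slice$patient_id)) "ANON" else slice$patient_id
  ds <- c(
    .dcm_elem(0x0008, 0x0016, "UI", .dcm_uid_ct_storage),
    .dcm_elem(0x0008, 0x0018, "UI", sop_uid),
    .dcm_elem(0x0008, 0x0060, "CS", "CT"),
    .dcm_elem(0x0010, 0x0020, "LO", pid),
    .dcm_elem(0x0020, 0x1041, "DS", .dcm_format_ds(loc)),
    .dcm_elem(0x0028, 0x0002, "US", 1L),
    .dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_elem(0x0028, 0x0010, "US", nrow(px)),
    .dcm_elem(0x0028, 0x0011, "US", ncol(px)),
    .dcm_elem(0x0028, 0x0030, "DS",
              paste(.dcm_format_ds(slice$spacing[1]),
                    .dcm_format_ds(slice$spacing[2]), sep = "\\")),
    .dcm_elem(0x0028, 0x0100, "US", 16L),
    .dcm_elem(0x0028, 0x0101, "US", 16L),
    .dcm_elem(0x0028, 0x0102, "US", 15L),
    .dcm_elem(0x0028, 0x0103, "US", 1L),
    .dcm_elem(0x0028, 0x1052, "DS", .dcm_format_ds(intercept)),
    .dcm_elem(0x0028, 0x1053, "DS", .dcm_format_ds(slope)),
    .dcm_elem(0x7FE0, 0x0010, "OW", pix_raw))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

# Decode a string value, dropping DICOM's NUL/space padding bytes.
.dcm_raw_str <- function(r) {
  r <- r[r != as.raw(0)]
  sub(" +$", "", rawToChar(r))
}

.dcm_read_u16 <- function(r, pos) {
  readBin(r[pos:(pos + 1L)], "integer", size = 2, signed = FALSE,
          endian = "little")
}

# Parse a DICOM file into a named list of raw element values.
.dcm_parse <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 140L || rawToChar(r[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM file (missing DICM magic)", path),
         call. = FALSE)
  pos <- 133L
  out <- list()
  while (pos + 7L <= length(r)) {
    group <- .dcm_read_u16(r, pos)
    elem <- .dcm_read_u16(r, pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or unsupported transfer syntax", call. = FALSE)
    if (vr %in% .dcm_long_vrs) {
      len <- readBin(r[(pos + 8L):(pos + 11L)], "integer", size = 4,
                     endian = "little")
      vstart <- pos + 12L
    } else {
      len <- .dcm_read_u16(r, pos + 6L)
      vstart <- pos + 8L
    }
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr,
                       value = if (len > 0L) r[vstart:(vstart + len - 1L)]
                               else raw(0))
    pos <- vstart + len
  }
  ts <- out[["0002,0010"]]
  if (!is.null(ts) &&
      .dcm_raw_str(ts$value) != .dcm_uid_explicit_le)
    stop("unsupported DICOM transfer syntax (need Explicit VR LE)",
         call. = FALSE)
  out
}

.dcm_get_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(.dcm_raw_str(el$value))
}

.dcm_get_ds <- function(el) {
  s <- .dcm_get_str(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcm_get_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", size = 2, signed = FALSE, endian = "little")
}

# Read one DICOM file back to a ct_slice (HU via rescale slope/intercept).
read_dicom_file <- function(path) {
  d <- .dcm_parse(path)
  need <- function(key, what) {
    if (is.null(d[[key]]))
      stop(sprintf("DICOM file '%s' is missing tag (%s) %s",
                   basename(path), key, what), call. = FALSE)
    d[[key]]
  }
  rows <- .dcm_get_us(need("0028,0010", "Rows"))
  cols <- .dcm_get_us(need("0028,0011", "Columns"))
  spacing <- .dcm_get_ds(need("0028,0030", "PixelSpacing"))
  intercept <- .dcm_get_ds(need("0028,1052", "RescaleIntercept"))
  slope <- .dcm_get_ds(need("0028,1053", "RescaleSlope"))
  signed <- identical(.dcm_get_us(d[["0028,0103"]]), 1L)
  bits <- .dcm_get_us(d[["0028,0100"]])
  if (!is.null(bits) && bits != 16L)
    stop("only 16-bit DICOM pixel data is supported", call. = FALSE)
  pix <- need("7FE0,0010", "PixelData")
  stored <- readBin(pix$value, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
  if (!signed) stored <- as.numeric(stored)
  hu <- slope * stored + intercept
  loc <- .dcm_get_ds(d[["0020,1041"]])
  pid <- .dcm_get_str(d[["0010,0020"]])
  ct_slice(matrix(hu, nrow = rows, ncol = cols, byrow = TRUE),
           spacing = spacing,
           slice_location = if (is.null(loc)) NA_real_ else loc,
           patient_id = if (is.null(pid)) NA_character_ else pid)
}
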