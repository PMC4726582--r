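#' Read CT slices from NIfTI or a DICOM series
#'
#' Reads a single-file NIfTI image (2-D, or 3-D treated as a stack of
#' transversal slices) or a directory of single-frame DICOM files. Stored
#' values are converted to Hounsfield units (for DICOM, via the mandatory
#' rescale slope/intercept tags; missing tags are an error naming the tag).
#' Slices are returned sorted by ascending slice location, ties broken by
#' filename; inconsistent pixel spacing across a series is an error.
#'
#' @param path path to a `.nii`/`.nii.gz` file, a single `.dcm` file, or a
#'   directory containing a DICOM series.
#' @param format `"nifti"` or `"dicom"`; the default guesses from `path`.
#' @return A list of [ct_slice()] objects (possibly of length one).
#' @seealso [write_ct()]
#' @export
read_ct <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.dcm$", path, ignore.case = TRUE))
      "dicom" else "nifti"
  }
  if (!file.exists(path))
    stop(sprintf("'%s' does not exist", path), call. = FALSE)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    # pixdim is float32 in the header; round away representation noise
    pd <- round(RNifti::pixdim(img), 6)
    if (length(dim(arr)) == 2L) {
      return(list(ct_slice(arr[, , drop = TRUE], spacing = pd[1:2])))
    }
    if (length(dim(arr)) != 3L)
      stop("NIfTI image must be 2-D or 3-D", call. = FALSE)
    dz <- if (length(pd) >= 3L) pd[3] else 1
    lapply(seq_len(dim(arr)[3]), function(k)
      ct_slice(arr[, , k], spacing = pd[1:2],
               slice_location = (k - 1) * dz))
  } else {
    files <- if (dir.exists(path)) {
      sort(list.files(path, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE))
    } else path
    if (length(files) == 0L)
      stop(sprintf("no DICOM files found in '%s'", path), call. = FALSE)
    slices <- lapply(files, read_dicom_file)
    sp <- vapply(slices, function(s) s$spacing, numeric(2))
    if (any(abs(sp - sp[, 1]) > 1e-6))
      stop("inconsistent pixel spacing across DICOM series", call. = FALSE)
    loc <- vapply(slices, function(s) s$slice_location, numeric(1))
    loc[is.na(loc)] <- Inf
    slices[order(loc, basename(files))]
  }
}

#' Write CT slices to NIfTI or a DICOM series
#'
#' NIfTI output stores HU as 64-bit floats (bit-exact round trip through
#' [read_ct()]); DICOM output stores 16-bit integers with rescale
#' slope 1 / intercept -1024, so the round-trip error is at most 0.5 HU.
#' Multi-slice NIfTI requires uniformly spaced slice locations.
#'
#' @param slices a [ct_slice()] or a list of them (consistent shape and
#'   spacing).
#' @param path output file (`nifti`) or directory (`dicom`; one
#'   `slice_NNN.dcm` file per slice is created).
#' @param format `"nifti"` or `"dicom"`.
#' @return `path`, invisibly.
#' @export
write_ct <- function(slices, path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (inherits(slices, "ct_slice")) slices <- list(slices)
  if (length(slices) == 0L) stop("no slices to write", call. = FALSE)
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  sp <- vapply(slices, function(s) s$spacing, numeric(2))
  if (any(dims != dims[, 1]) || any(abs(sp - sp[, 1]) > 1e-9))
    stop("slices must share shape and spacing", call. = FALSE)
  if (format == "nifti") {
    if (length(slices) == 1L) {
      img <- RNifti::asNifti(slices[[1]]$pixels)
      RNifti::pixdim(img) <- slices[[1]]$spacing
    } else {
      loc <- vapply(slices, function(s) s$slice_location, numeric(1))
      dz <- diff(loc)
      if (any(is.na(loc)) || length(unique(round(dz, 6))) != 1L)
        stop("multi-slice NIfTI needs uniformly spaced slice locations",
             call. = FALSE)
      arr <- array(0, c(dims[, 1], length(slices)))
      for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$pixels
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- c(slices[[1]]$spacing, dz[1])
    }
    ok <- tryCatch({RNifti::writeNifti(img, path, datatype = "double"); TRUE},
                   error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("cannot write NIfTI to '%s': %s", path,
                   conditionMessage(ok)), call. = FALSE)
  } else {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop(sprintf("cannot create directory '%s'", path),
                    call. = FALSE)
    }
    for (k in seq_along(slices))
      write_dicom_file(slices[[k]],
                       file.path(path, sprintf("slice_%03d.dcm", k)),
                       instance = k)
  }
  invisible(path)
}

#' Export a windowed display as PNG
#'
#' Renders a slice through a [window_preset()] and writes an 8-bit
#' grayscale PNG, the way a viewing workstation would display it.
#'
#' @inheritParams apply_window
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_png <- function(slice, preset, path) {
  disp <- apply_window(slice, preset)
  png::writePNG(disp / 255, path)
  invisible(path)
}
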