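#' CT slice container
#'
#' A single transversal CT slice: a matrix of attenuation values in
#' Hounsfield units (HU) together with its pixel spacing and minimal
#' metadata. All processing functions in the package operate on this class.
#'
#' Pixel values are clamped on construction to the 12-bit CT range
#' \eqn{[-1024, 3071]} HU (with a warning when clamping occurs), matching
#' what scanners can encode; non-finite values are an error.
#'
#' @param pixels numeric matrix of attenuation values (HU); rows index the
#'   anterior-posterior axis, columns the left-right axis.
#' @param spacing numeric length-2 vector, (row, col) pixel size in mm.
#' @param slice_location slice position along the scanner axis in mm, or
#'   `NA`.
#' @param patient_id opaque patient label, or `NA`.
#' @param level_tag one of `"ganglionic"`, `"supraganglionic"`, `"other"`:
#'   the ASPECTS slab the slice belongs to.
#' @param processed logical; `TRUE` marks a slice that has been through
#'   [apply_bc()].
#' @return An object of class `ct_slice`.
#' @examples
#' s <- ct_slice(matrix(30, 16, 16), spacing = c(0.9, 0.9))
#' range(s$pixels)
#' @export
ct_slice <- function(pixels, spacing = c(1, 1), slice_location = NA_real_,
                     patient_id = NA_character_,
                     level_tag = c("other", "ganglionic", "supraganglionic"),
                     processed = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("'pixels' must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be two strictly positive numbers (mm)", call. = FALSE)
  level_tag <- match.arg(level_tag)
  n_out <- sum(pixels < -1024 | pixels > 3071)
  if (n_out > 0L) {
    warning(sprintf("%d pixel(s) outside [-1024, 3071] HU clamped on ingest",
                    n_out), call. = FALSE)
    pixels[pixels < -1024] <- -1024
    pixels[pixels > 3071] <- 3071
  }
  structure(
    list(pixels = pixels, spacing = spacing,
         slice_location = as.numeric(slice_location),
         patient_id = patient_id, level_tag = level_tag,
         processed = isTRUE(processed)),
    class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, spacing %.3f x %.3f mm%s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              if (x$processed) " [BC-processed]" else ""))
  if (!is.na(x$slice_location))
    cat(sprintf("  slice location: %.2f mm\n", x$slice_location))
  if (!is.na(x$patient_id))
    cat(sprintf("  patient: %s\n", x$patient_id))
  cat(sprintf("  level: %s; HU range [%.1f, %.1f]\n",
              x$level_tag, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.ct_slice <- function(x, ...) x$pixels

#' Display window preset
#'
#' A linear HU-to-gray display mapping defined by a window width and level,
#' as used in clinical CT reading (a standard brain window is width 80 HU at
#' level 40 HU; narrow stroke windows go down to width 35-45 HU).
#'
#' @param width window width in HU; must be > 0.
#' @param level window level (centre) in HU.
#' @return An object of class `window_preset`.
#' @seealso [apply_window()]
#' @export
window_preset <- function(width, level) {
  stopifnot_scalar_num(width, "width", positive = TRUE)
  stopifnot_scalar_num(level, "level")
  structure(list(width = width, level = level), class = "window_preset")
}

#' @export
print.window_preset <- function(x, ...) {
  cat(sprintf("<window_preset> width %g HU, level %g HU\n", x$width, x$level))
  invisible(x)
}

#' Render a slice through a display window
#'
#' Maps HU values to integer display values in \[0, 255\]: values at or
#' below `level - width/2` map to 0, values at or above `level + width/2`
#' map to 255, linear in between. Rounding is half-up so window midpoints
#' render identically across platforms (the midpoint of an 80/40 window is
#' exactly 128).
#'
#' @param slice a [ct_slice()] (or a plain numeric matrix of HU values).
#' @param preset a [window_preset()].
#' @return Integer matrix of display values in \[0, 255\].
#' @examples
#' w <- window_preset(80, 40)
#' apply_window(matrix(c(0, 40, 80), 1), w)
#' @export
apply_window <- function(slice, preset) {
  stopifnot(inherits(preset, "window_preset"))
  px <- if (inherits(slice, "ct_slice")) slice$pixels else slice
  lo <- preset$level - preset$width / 2
  y <- round_half_up(255 * (px - lo) / preset$width)
  y[y < 0] <- 0L
  y[y > 255] <- 255L
  storage.mode(y) <- "integer"
  y
}
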