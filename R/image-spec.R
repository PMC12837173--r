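#' Describe the geometry of an en-face OCTA scan
#'
#' An `image_spec` records everything needed to convert between pixels and
#' millimetres for a square en-face angiogram: the pixel dimensions, the
#' physical side length of the scan field (3 mm for macula-centered scans,
#' 6 mm for optic-nerve-head scans), the anatomical center and the eye.
#'
#' Pixel coordinates follow raster convention: origin at the top-left corner,
#' x to the right, y downward, and pixel `(row i, col j)` (1-based) has its
#' center at `(j - 0.5, i - 0.5)` pixels. All geometric operations in the
#' package sample at pixel centers under this convention.
#'
#' @param width_px,height_px image dimensions in pixels (must be equal).
#' @param field_mm physical side length of the square scan in mm.
#' @param center_type `"macula"` or `"onh"`.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @return An object of class `image_spec`.
#' @examples
#' image_spec(512, 512, field_mm = 3, center_type = "macula", laterality = "OD")
#' @export
image_spec <- function(width_px, height_px = width_px, field_mm,
                       center_type = c("macula", "onh"),
                       laterality = c("OD", "OS")) {
  center_type <- match.arg(center_type)
  laterality <- match.arg(laterality)
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px <= 0L || height_px <= 0L)
    stop_octa("zero-size-image", "image dimensions must be positive")
  if (width_px != height_px)
    stop_octa("invalid-spec", "en-face scans are square: width_px must equal height_px")
  if (!is.finite(field_mm) || field_mm <= 0)
    stop_octa("invalid-spec", "field_mm must be a positive finite number")
  structure(list(width_px = width_px, height_px = height_px,
                 field_mm = as.numeric(field_mm),
                 center_type = center_type, laterality = laterality),
            class = "image_spec")
}

#' Physical pixel pitch of a scan
#' @param spec an [image_spec()].
#' @return mm per pixel (scalar).
#' @export
mm_per_px <- function(spec) spec$field_mm / spec$width_px

#' @export
print.image_spec <- function(x, ...) {
  cat(sprintf("<image_spec> %dx%d px, %.1f mm field (%s, %s), %.4f mm/px\n",
              x$width_px, x$height_px, x$field_mm, x$center_type,
              x$laterality, mm_per_px(x)))
  invisible(x)
}

## Pixel-center coordinate grids in px units (matrices matching the image).
pixel_centers <- function(spec) {
  xs <- matrix(rep(seq_len(spec$width_px) - 0.5, each = spec$height_px),
               nrow = spec$height_px)
  ys <- matrix(rep(seq_len(spec$height_px) - 0.5, times = spec$width_px),
               nrow = spec$height_px)
  list(x = xs, y = ys)
}

#' Construct an en-face angiogram object
#'
#' Wraps an 8-bit grayscale image matrix together with its [image_spec()].
#' Pixel values are integers in 0..255 (0 = no flow signal).
#'
#' @param pixels integer matrix in 0..255, `height_px` rows.
#' @param spec the [image_spec()] describing calibration.
#' @return An object of class `enface_angiogram`.
#' @export
enface_angiogram <- function(pixels, spec) {
  stopifnot(inherits(spec, "image_spec"), is.matrix(pixels))
  if (nrow(pixels) != spec$height_px || ncol(pixels) != spec$width_px)
    stop_octa("invalid-spec", "pixel matrix does not match spec dimensions")
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L | pixels > 255L))
    stop_octa("invalid-spec", "pixels must be 8-bit (0..255)")
  structure(list(pixels = pixels, spec = spec), class = "enface_angiogram")
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf("<enface_angiogram> %dx%d px (%s %s), intensity %d..%d\n",
              x$spec$width_px, x$spec$height_px, x$spec$center_type,
              x$spec$laterality, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read / write 8-bit grayscale PNG angiogram images
#'
#' @param img an [enface_angiogram()] (or logical matrix for masks).
#' @param path file path.
#' @param spec an [image_spec()] supplying calibration when reading.
#' @return `read_angiogram_png` returns an [enface_angiogram()];
#'   `write_mask_png`/`read_mask_png` handle boolean masks.
#' @export
write_angiogram_png <- function(img, path) {
  stopifnot(inherits(img, "enface_angiogram"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

#' @rdname write_angiogram_png
#' @export
read_angiogram_png <- function(path, spec) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  enface_angiogram(matrix(as.integer(round(arr * 255)), nrow = nrow(arr)), spec)
}

#' @rdname write_angiogram_png
#' @param mask logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, target = path)
  invisible(path)
}

#' @rdname write_angiogram_png
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  arr > 0.5
}
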