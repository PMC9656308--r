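# Domain containers for captures and flow maps.
#
# Pixel conventions used throughout the package:
#   * channel values are integers on the 8-bit scale 0..255;
#   * pixel coordinates are 0-based, row-major, origin at the top-left;
#   * all rectangular selections are half-open intervals [x0,x1) x [y0,y1).

#' RGB capture image
#'
#' A 2-D grid of RGB triples as captured from the ultrasound scanner
#' (DICOM secondary capture, TIFF or PNG). Channel values are integers in
#' 0--255. A grayscale matrix is accepted and replicated across channels.
#'
#' @param pixels numeric array `height x width x 3` (or a matrix, treated as
#'   an achromatic image) with values in 0--255.
#' @param pixel_spacing optional physical pixel size in mm/pixel; a single
#'   number (isotropic) or a length-2 vector `c(row, col)`. Must be positive.
#' @param metadata free-form list of capture metadata (acquisition settings,
#'   photometric interpretation, source file); carried along, never computed on.
#' @return an object of class `microv_rgb` with fields `pixels`, `height`,
#'   `width`, `pixel_spacing`, `metadata`.
#' @export
rgb_image <- function(pixels, pixel_spacing = NULL, metadata = list()) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be a height x width x 3 array (or a matrix)")
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must be finite and in 0..255")
  pixel_spacing <- check_spacing(pixel_spacing)
  structure(
    list(pixels = pixels,
         height = dim(pixels)[1], width = dim(pixels)[2],
         pixel_spacing = pixel_spacing, metadata = metadata),
    class = "microv_rgb")
}

#' Flow-intensity image
#'
#' A 2-D grid of 8-bit flow intensities: 255 is the highest flow the scanner
#' displays, 0 is no flow. This is the quantitative product of retro-converting
#' a color capture through an inverse LUT (or of passing a grayscale capture
#' through unchanged).
#'
#' @param pixels integer matrix with values in 0--255.
#' @param pixel_spacing optional mm/pixel, as in [rgb_image()].
#' @param colormap_name identifier of the color map used to produce the image,
#'   or `NULL`.
#' @param chroma_mask optional logical matrix of the same dimensions; `TRUE`
#'   marks pixels classified achromatic (B-mode background), `FALSE` pixels
#'   classified colored (Doppler overlay).
#' @return an object of class `microv_flow`.
#' @export
flow_image <- function(pixels, pixel_spacing = NULL, colormap_name = NULL,
                       chroma_mask = NULL) {
  if (!is.matrix(pixels))
    stop("'pixels' must be a matrix")
  if (any(!is.finite(pixels)) || any(pixels != round(pixels)) ||
      min(pixels) < 0 || max(pixels) > 255)
    stop("flow values must be integers in 0..255")
  storage.mode(pixels) <- "integer"
  if (!is.null(chroma_mask)) {
    if (!is.logical(chroma_mask) || !identical(dim(chroma_mask), dim(pixels)))
      stop("'chroma_mask' must be a logical matrix with the image's dimensions")
  }
  pixel_spacing <- check_spacing(pixel_spacing)
  structure(
    list(pixels = pixels,
         height = nrow(pixels), width = ncol(pixels),
         pixel_spacing = pixel_spacing,
         colormap_name = colormap_name, chroma_mask = chroma_mask),
    class = "microv_flow")
}

check_spacing <- function(pixel_spacing) {
  if (is.null(pixel_spacing)) return(NULL)
  if (!is.numeric(pixel_spacing) || !length(pixel_spacing) %in% 1:2 ||
      any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop("'pixel_spacing' must be one or two positive numbers (mm/pixel)")
  as.numeric(pixel_spacing)
}

#' Per-pixel chroma of an RGB image
#'
#' Chroma is `max(R,G,B) - min(R,G,B)`: 0 for achromatic (gray) pixels.
#' MicroV captures overlay chromatic Doppler color on an achromatic B-mode
#' background, so chroma separates overlay from background.
#'
#' @param image a [rgb_image()] or a `height x width x 3` array.
#' @return a numeric matrix of chroma values.
#' @export
pixel_chroma <- function(image) {
  px <- if (inherits(image, "microv_rgb")) image$pixels else image
  pmax(px[, , 1], px[, , 2], px[, , 3]) - pmin(px[, , 1], px[, , 2], px[, , 3])
}

#' @export
print.microv_rgb <- function(x, ...) {
  cat(sprintf("MicroV RGB capture: %d x %d px%s\n", x$height, x$width,
              if (is.null(x$pixel_spacing)) "" else
                sprintf(", %s mm/px", paste(format(x$pixel_spacing), collapse = " x "))))
  invisible(x)
}

#' @export
print.microv_flow <- function(x, ...) {
  cat(sprintf("Flow image: %d x %d px, intensities %d..%d%s%s\n",
              x$height, x$width, min(x$pixels), max(x$pixels),
              if (is.null(x$colormap_name)) "" else
                sprintf(", colormap %s", x$colormap_name),
              if (is.null(x$chroma_mask)) "" else
                sprintf(", %.1f%% achromatic", 100 * mean(x$chroma_mask))))
  invisible(x)
}
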