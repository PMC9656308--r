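# Retro-conversion of color captures to 8-bit flow intensity.

#' Retro-convert a chromatic (MV0-style) capture to flow intensity
#'
#' Inverts the display LUT: every pixel is assigned the gray value of its
#' nearest colormap entry (squared Euclidean distance in raw sRGB space, ties
#' to the larger gray). Pixels whose chroma (`max - min` channel) is at or
#' below `chroma_threshold` are classified achromatic in the output's
#' `chroma_mask`; under `background_policy = "zero"` they are assigned flow 0,
#' under `"nearest"` (default) they are matched through the LUT like any other
#' pixel, which reproduces an unconditional LUT application over the whole
#' frame.
#'
#' @param image a [rgb_image()].
#' @param map a [colormap()] with 256 entries.
#' @param chroma_threshold non-negative; chroma at or below it marks a pixel
#'   achromatic. Default 0: only exactly gray pixels.
#' @param background_policy `"nearest"` or `"zero"`.
#' @return a [flow_image()] carrying the source spacing, the map name and the
#'   chroma mask.
#' @export
retroconvert_mv0 <- function(image, map, chroma_threshold = 0,
                             background_policy = c("nearest", "zero")) {
  if (!inherits(image, "microv_rgb")) stop("'image' must be a microv_rgb")
  if (!inherits(map, "microv_colormap") || nrow(map$colors) != 256L)
    stop("'map' must be a 256-entry microv_colormap")
  if (image$height < 1L || image$width < 1L) stop("empty image")
  if (!is.numeric(chroma_threshold) || chroma_threshold < 0)
    stop("'chroma_threshold' must be non-negative")
  background_policy <- match.arg(background_policy)

  h <- image$height; w <- image$width
  px <- matrix(as.numeric(image$pixels), h * w, 3L)
  # match unique colors only; captures reuse few distinct colors
  key <- px[, 1] * 65536 + px[, 2] * 256 + px[, 3]
  uk <- unique(key)
  pos <- match(key, uk)
  first <- match(uk, key)
  res <- nearest_gray(px[first, , drop = FALSE], map)
  gray <- matrix(res$gray[pos], h, w)

  mask <- pixel_chroma(image) <= chroma_threshold
  if (background_policy == "zero") gray[mask] <- 0L
  flow_image(gray, pixel_spacing = image$pixel_spacing,
             colormap_name = map$name, chroma_mask = mask)
}

#' Pass an MV2 (grayscale) capture through unchanged
#'
#' MV2 captures are already 256-tone grayscale flow maps (255 = white =
#' highest flow, 0 = black = no flow), so no retro-conversion is applied: the
#' flow value is the gray channel value. An image with chroma above
#' `tolerance` at any pixel is rejected — use [retroconvert_mv0()] for
#' chromatic captures.
#'
#' @param image a [rgb_image()] with (near-)equal channels, or a plain
#'   grayscale matrix with values in 0--255.
#' @param tolerance maximum admissible per-pixel chroma (default 0).
#' @return a [flow_image()] without a chroma mask.
#' @export
passthrough_mv2 <- function(image, tolerance = 0) {
  if (is.matrix(image)) image <- rgb_image(image)
  if (!inherits(image, "microv_rgb"))
    stop("'image' must be a microv_rgb or a grayscale matrix")
  ch <- pixel_chroma(image)
  bad <- ch > tolerance
  if (any(bad))
    stop(sprintf(
      "image is not achromatic: %.2f%% of pixels exceed chroma tolerance %g; use retroconvert_mv0()",
      100 * mean(bad), tolerance))
  g <- round((image$pixels[, , 1] + image$pixels[, , 2] + image$pixels[, , 3]) / 3)
  flow_image(g, pixel_spacing = image$pixel_spacing, colormap_name = "MV2")
}
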