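# Reading captures (DICOM / TIFF / PNG) and writing 8-bit TIFF products.

#' Read a capture image
#'
#' Dispatches on file extension: `.dcm`/`.dicom` through the package's DICOM
#' reader, `.tif`/`.tiff` through \pkg{tiff}, `.png` through \pkg{png}.
#' Grayscale rasters are replicated across channels so the result is always
#' RGB; alpha channels are dropped.
#'
#' @param path input file.
#' @return a [rgb_image()]; DICOM pixel spacing, photometric interpretation
#'   and modality are carried in `pixel_spacing` / `metadata`.
#' @export
read_capture <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    dcm = ,
    dicom = read_dicom_image(path),
    tif = ,
    tiff = raster_to_rgb(tiff::readTIFF(path), path),
    png = raster_to_rgb(png::readPNG(path), path),
    stop("unsupported capture format '.", ext, "' (use DICOM, TIFF or PNG)"))
}

# readTIFF/readPNG return values in [0,1]; recover the 8-bit integers.
raster_to_rgb <- function(x, path) {
  px <- round(x * 255)
  if (length(dim(px)) == 3L && dim(px)[3] >= 3L)
    px <- px[, , 1:3, drop = FALSE]
  else if (length(dim(px)) == 3L)
    px <- px[, , 1]
  rgb_image(px, metadata = list(source = path))
}

#' Write / read a flow image as single-channel 8-bit TIFF
#'
#' @param flow a [flow_image()].
#' @param path output/input path.
#' @return `write_flow_tiff()` returns `path` invisibly; `read_flow_tiff()`
#'   a [flow_image()].
#' @export
write_flow_tiff <- function(flow, path) {
  stopifnot(inherits(flow, "microv_flow"))
  tiff::writeTIFF(flow$pixels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_flow_tiff
#' @export
read_flow_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  flow_image(round(x * 255))
}

#' Write an RGB image as 8-bit TIFF
#'
#' @param image a [rgb_image()].
#' @param path output path.
#' @export
write_rgb_tiff <- function(image, path) {
  stopifnot(inherits(image, "microv_rgb"))
  tiff::writeTIFF(image$pixels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a chroma mask as 8-bit TIFF (255 = achromatic, 0 = colored)
#'
#' @param mask logical matrix (e.g. a flow image's `chroma_mask`).
#' @param path output path.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}
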