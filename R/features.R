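# First-order radiomic analysis: rectangular ROI statistics and histogram.

#' Rectangular ROI in pixel coordinates
#'
#' Coordinates are 0-based, half-open: the box covers columns `x0..x1-1` and
#' rows `y0..y1-1`. `inset` shrinks the box on every side, which is how the
#' displayed outline of the Doppler color box is excluded from analysis.
#'
#' @param x0,y0,x1,y1 integer corner coordinates, `x0 < x1`, `y0 < y1`.
#' @param inset non-negative integer margin excluded on all four sides.
#' @return object of class `microv_roi`.
#' @export
roi_box <- function(x0, y0, x1, y1, inset = 0L) {
  v <- c(x0, y0, x1, y1, inset)
  if (any(!is.finite(v)) || any(v != round(v)))
    stop("ROI coordinates and inset must be integers")
  if (inset < 0) stop("'inset' must be non-negative")
  if (x0 + inset >= x1 - inset || y0 + inset >= y1 - inset)
    stop("ROI is empty after applying inset ", inset)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1),
                 inset = as.integer(inset)),
            class = "microv_roi")
}

#' Extract a rectangular ROI from a flow image
#'
#' Returns the sub-grid covered by the box after applying its inset; pixel
#' spacing, colormap name and (cropped) chroma mask are propagated.
#'
#' @param image a [flow_image()].
#' @param box a [roi_box()].
#' @return a [flow_image()] of the selected sub-grid.
#' @export
extract_roi <- function(image, box) {
  stopifnot(inherits(image, "microv_flow"), inherits(box, "microv_roi"))
  x0 <- box$x0 + box$inset; x1 <- box$x1 - box$inset
  y0 <- box$y0 + box$inset; y1 <- box$y1 - box$inset
  if (x0 < 0 || y0 < 0 || x1 > image$width || y1 > image$height)
    stop(sprintf("ROI [%d,%d)x[%d,%d) lies outside the %d x %d image",
                 x0, x1, y0, y1, image$width, image$height))
  rows <- (y0 + 1L):y1; cols <- (x0 + 1L):x1
  flow_image(image$pixels[rows, cols, drop = FALSE],
             pixel_spacing = image$pixel_spacing,
             colormap_name = image$colormap_name,
             chroma_mask = if (is.null(image$chroma_mask)) NULL else
               image$chroma_mask[rows, cols, drop = FALSE])
}

#' First-order statistics of a flow ROI
#'
#' Computes the selected area, mean, standard deviation, minimum, maximum,
#' mode (most frequent intensity, with its count) and the full 256-bin
#' histogram of the flow intensities in the ROI. All pixels of the ROI enter
#' the statistics; the chroma mask, if present, is not applied. The standard
#' deviation uses the population convention (divide by N) by default; mode
#' ties are broken toward the lower intensity and flagged in the record.
#'
#' @param roi a [flow_image()] (typically from [extract_roi()]) or an integer
#'   vector of intensities in 0--255.
#' @param stdev `"population"` (divide by N, default) or `"sample"`
#'   (divide by N-1).
#' @return object of class `microv_features`: `n_pixels`, `area_px2`,
#'   `area_mm2` (NA without spacing), `mean`, `stdev`, `min`, `max`,
#'   `mode_value`, `mode_count`, `mode_tie` (logical), `histogram`
#'   (256 counts, intensity 0..255).
#' @export
first_order_features <- function(roi, stdev = c("population", "sample")) {
  stdev <- match.arg(stdev)
  spacing <- NULL
  if (inherits(roi, "microv_flow")) {
    spacing <- roi$pixel_spacing
    v <- as.integer(roi$pixels)
  } else if (is.numeric(roi)) {
    if (any(roi != round(roi)) || any(roi < 0) || any(roi > 255))
      stop("intensities must be integers in 0..255")
    v <- as.integer(roi)
  } else stop("'roi' must be a flow image or an intensity vector")
  n <- length(v)
  if (n == 0L) stop("empty ROI")

  counts <- tabulate(v + 1L, nbins = 256L)
  mode_count <- max(counts)
  modes <- which(counts == mode_count) - 1L  # intensities achieving the max
  m <- mean(v)
  ss <- sum((v - m)^2)
  sd_val <- if (stdev == "population") sqrt(ss / n) else
    if (n > 1L) sqrt(ss / (n - 1L)) else NA_real_
  area_mm2 <- if (is.null(spacing)) NA_real_ else
    n * prod(rep(spacing, length.out = 2L))
  structure(
    list(n_pixels = n, area_px2 = as.numeric(n), area_mm2 = area_mm2,
         mean = m, stdev = sd_val, min = min(v), max = max(v),
         mode_value = modes[1L], mode_count = mode_count,
         mode_tie = length(modes) > 1L,
         histogram = counts, stdev_convention = stdev),
    class = "microv_features")
}

#' @export
print.microv_features <- function(x, digits = 3, ...) {
  cat(sprintf(
    "First-order features: N=%d  Area=%s px^2%s\n  Mean=%s  StDev=%s  Min=%d  Max=%d  Mode=%d (%d)%s\n",
    x$n_pixels, format(x$area_px2),
    if (is.na(x$area_mm2)) "" else sprintf(" (%.3f mm^2)", x$area_mm2),
    format(round(x$mean, digits)), format(round(x$stdev, digits)),
    x$min, x$max, x$mode_value, x$mode_count,
    if (isTRUE(x$mode_tie)) " [tie]" else ""))
  invisible(x)
}

#' Write a feature table
#'
#' One row per record, with the conventional columns `N`, `Area`, `Mean`,
#' `StDev`, `Min`, `Max` and `Mode` rendered as `"value (count)"`, preceded by
#' an identifier column. The unformatted numeric mode and (when available)
#' metric area are appended so the table remains machine-readable.
#'
#' @param records list of [first_order_features()] results.
#' @param ids character vector of unique case identifiers, one per record.
#' @param path output CSV path, or `NULL` to only return the data frame.
#' @return the table as a data frame, invisibly when written.
#' @export
write_feature_table <- function(records, ids, path = NULL) {
  if (length(records) == 0L) stop("no feature records to write")
  if (inherits(records, "microv_features")) records <- list(records)
  if (!all(vapply(records, inherits, TRUE, "microv_features")))
    stop("'records' must be microv_features objects")
  ids <- as.character(ids)
  if (length(ids) != length(records))
    stop("need exactly one identifier per record")
  if (anyDuplicated(ids))
    stop("duplicate identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  num <- function(f) vapply(records, function(r) as.numeric(r[[f]]), 0)
  tab <- data.frame(
    Case = ids,
    N = vapply(records, function(r) r$n_pixels, 0L),
    Area = num("area_px2"),
    Mean = num("mean"),
    StDev = num("stdev"),
    Min = num("min"),
    Max = num("max"),
    Mode = vapply(records, function(r)
      sprintf("%d (%d)", r$mode_value, r$mode_count), ""),
    ModeValue = num("mode_value"),
    ModeCount = num("mode_count"),
    AreaMm2 = num("area_mm2"),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Export a record's histogram as CSV and a rendered TIFF bar plot
#'
#' Writes `<stem>_histogram.csv` (columns `intensity`, `count`, 256 rows) and
#' `<stem>_histogram.tif`, an 8-bit grayscale raster of the bar plot rendered
#' directly into pixels (black bars on white).
#'
#' @param record a [first_order_features()] result.
#' @param stem output path stem (directory must exist and be writable).
#' @return character vector of the two paths written, invisibly.
#' @export
export_histogram <- function(record, stem) {
  stopifnot(inherits(record, "microv_features"))
  dir <- dirname(stem)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  csv <- paste0(stem, "_histogram.csv")
  tif <- paste0(stem, "_histogram.tif")
  utils::write.csv(
    data.frame(intensity = 0:255, count = record$histogram),
    csv, row.names = FALSE)
  tiff::writeTIFF(render_histogram(record$histogram), tif,
                  bits.per.sample = 8L)
  invisible(c(csv = csv, tiff = tif))
}

# Rasterise a 256-bin histogram as a bar plot: 2 px per bin, fixed plot
# height, values in [0,1] for writeTIFF (0 = black bar, 1 = white background).
render_histogram <- function(counts, height = 200L) {
  img <- matrix(1, height, 512L)
  top <- max(counts)
  if (top > 0) {
    bar <- round(height * counts / top)
    for (i in which(bar > 0)) {
      rows <- (height - bar[i] + 1L):height
      img[rows, c(2L * i - 1L, 2L * i)] <- 0
    }
  }
  img
}
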