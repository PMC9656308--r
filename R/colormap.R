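# Inverse look-up tables for MicroV color scales.
#
# The display color scale is divided into 256 segments; the first (highest
# flow) segment is assigned gray 255, the last 0, so higher flow rates always
# map to whiter output. A colormap object stores the 256 (color, gray) pairs
# in that order.

#' Construct a MicroV colormap
#'
#' @param colors numeric 256 x 3 matrix of RGB colors (channels 0--255), one
#'   row per scale segment, highest-flow segment first.
#' @param name short identifier, e.g. `"MV0"` or `"MV2"`.
#' @param provenance free-form character note on where the colors came from.
#' @return object of class `microv_colormap` with fields `colors` (256 x 3),
#'   `gray` (the fixed sequence 255..0), `name`, `provenance`.
#' @export
colormap <- function(colors, name = "custom", provenance = "user") {
  colors <- as.matrix(colors)
  if (nrow(colors) != 256L || ncol(colors) != 3L)
    stop("a colormap needs exactly 256 RGB entries (got ", nrow(colors), ")")
  if (any(!is.finite(colors)) || min(colors) < 0 || max(colors) > 255)
    stop("colormap channel values must be finite and in 0..255")
  dimnames(colors) <- list(NULL, c("r", "g", "b"))
  structure(
    list(colors = colors, gray = 255:0, name = name, provenance = provenance),
    class = "microv_colormap")
}

#' Color-scale strip cropped from a capture
#'
#' The strip is the color bar displayed alongside a MicroV image. Its
#' orientation must be given explicitly: silent auto-detection could flip the
#' whole flow semantics, so `high` has no default.
#'
#' @param pixels RGB array `height x width x 3` (or a matrix for an achromatic
#'   strip), channels 0--255.
#' @param high which edge of the strip is the highest-flow end: `"top"`,
#'   `"bottom"` (vertical scale axis), `"left"` or `"right"` (horizontal).
#' @return object of class `microv_scale_strip`.
#' @export
scale_strip <- function(pixels, high) {
  if (missing(high))
    stop("'high' (orientation of the highest-flow end) must be given explicitly")
  high <- match.arg(high, c("top", "bottom", "left", "right"))
  img <- rgb_image(pixels)
  axis_len <- if (high %in% c("top", "bottom")) img$height else img$width
  if (axis_len < 256L)
    stop("scale strip must span at least 256 pixels along the scale axis (got ",
         axis_len, ")")
  structure(list(pixels = img$pixels, high = high), class = "microv_scale_strip")
}

#' Build an inverse LUT from a color-scale strip
#'
#' Partitions the scale axis into 256 equal-length segments; each segment's
#' representative color is computed from its pixels, averaging across the
#' transverse axis first. Segment 0 at the highest-flow end receives gray 255,
#' the final segment gray 0.
#'
#' @param strip a [scale_strip()].
#' @param name identifier for the resulting map.
#' @param stat how to summarise each segment's rows: `"mean"` (default; robust
#'   to scale-bar antialiasing) or `"median"`.
#' @return a [colormap()].
#' @export
build_colormap_from_strip <- function(strip, name = "custom",
                                      stat = c("mean", "median")) {
  if (!inherits(strip, "microv_scale_strip"))
    stop("'strip' must be a microv_scale_strip")
  stat <- match.arg(stat)
  px <- strip$pixels
  # orient so the scale runs along rows, highest flow in row 1
  if (strip$high %in% c("left", "right"))
    px <- aperm(px, c(2, 1, 3))
  if (strip$high %in% c("bottom", "right"))
    px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
  n <- dim(px)[1]
  # transverse average first, one RGB per scale row
  rows <- apply(px, c(1, 3), mean)
  bounds <- floor(n * (0:256) / 256)
  colors <- matrix(0, 256L, 3L)
  fun <- if (stat == "mean") mean else stats::median
  for (i in seq_len(256L)) {
    seg <- rows[(bounds[i] + 1L):bounds[i + 1L], , drop = FALSE]
    colors[i, ] <- apply(seg, 2, fun)
  }
  colormap(colors, name = name,
           provenance = sprintf("built from %d-px scale strip (%s)", n, stat))
}

# cache for packaged maps
.microv_cache <- new.env(parent = emptyenv())

#' Packaged colormaps
#'
#' `"MV2"` is the grayscale display map (gray `g` is shown as the achromatic
#' color `(g,g,g)`; 255 = white = highest flow) and is generated analytically.
#' `"MV0"` is the chromatic flow-rate coding; the vendor's exact RGB table is
#' machine-specific, so the package ships a *synthetic* stand-in scale strip
#' (`inst/extdata/mv0_synthetic_strip.csv`) and rebuilds the LUT from it with
#' [build_colormap_from_strip()]. For bit-exact work on real captures, rebuild
#' the LUT from your own machine's scale bar.
#'
#' @param name `"MV0"` or `"MV2"`.
#' @return a [colormap()].
#' @export
builtin_colormap <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% c("MV0", "MV2"))
    stop("unknown colormap '", paste(name, collapse = ","),
         "'; available built-in maps: MV0, MV2")
  key <- paste0("map_", name)
  if (!is.null(.microv_cache[[key]])) return(.microv_cache[[key]])
  map <- if (name == "MV2") {
    g <- 255:0
    colormap(cbind(g, g, g), name = "MV2", provenance = "analytic grayscale ramp")
  } else {
    path <- system.file("extdata", "mv0_synthetic_strip.csv",
                        package = "microvflow", mustWork = TRUE)
    tab <- utils::read.csv(path)
    strip <- scale_strip(array(rep(as.matrix(tab[, c("r", "g", "b")]), each = 1),
                               dim = c(nrow(tab), 1L, 3L))[, c(1, 1, 1, 1), ,
                                                           drop = FALSE],
                         high = "top")
    m <- build_colormap_from_strip(strip, name = "MV0")
    m$provenance <- "synthetic stand-in scale strip (packaged)"
    m
  }
  .microv_cache[[key]] <- map
  map
}

#' Nearest colormap entry for a color
#'
#' Finds the entry minimising squared Euclidean distance to `color` in raw
#' sRGB channel space; ties are broken in favour of the larger gray value
#' (higher flow). The distance is returned so callers can threshold off-scale
#' colors.
#'
#' @param map a [colormap()].
#' @param color numeric RGB triple in 0--255.
#' @return list with `gray` (0--255), `distance` (Euclidean, >= 0) and
#'   `index` (1-based entry row).
#' @export
nearest_entry <- function(map, color) {
  stopifnot(inherits(map, "microv_colormap"))
  if (length(color) != 3L || any(!is.finite(color)))
    stop("'color' must be a finite RGB triple")
  res <- nearest_gray(matrix(as.numeric(color), 1L, 3L), map)
  list(gray = res$gray[1], distance = sqrt(res$dist2[1]), index = res$index[1])
}

# Vectorised nearest-entry matching: px is an N x 3 numeric matrix.
# Entries are stored gray-descending, so with ties.method = "first" an exact
# distance tie resolves to the larger gray. Integer-valued inputs keep all
# arithmetic exact in doubles, so ties are exact, not approximate.
# Chunked to bound the N x 256 distance matrix.
nearest_gray <- function(px, map, chunk = 16384L) {
  n <- nrow(px)
  cols <- map$colors
  cn2 <- rowSums(cols^2)
  gray <- integer(n); dist2 <- numeric(n); index <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    block <- px[idx, , drop = FALSE]
    d <- sweep(-2 * (block %*% t(cols)), 2L, cn2, "+")  # |c|^2 - 2 p.c
    best <- max.col(-d, ties.method = "first")
    index[idx] <- best
    gray[idx] <- map$gray[best]
    dist2[idx] <- d[cbind(seq_along(idx), best)] + rowSums(block^2)
  }
  dist2[dist2 < 0] <- 0  # guard rounding at exact matches
  list(gray = gray, dist2 = dist2, index = index)
}

#' Write / read an ImageJ-style text LUT
#'
#' Plain-text 3-column (R, G, B) file with 256 whitespace-separated lines,
#' first line = gray 255 (highest flow). Channel values are rounded to
#' integers on write.
#'
#' @param map a [colormap()].
#' @param path file path.
#' @return `write_lut_text()` returns `path` invisibly; `read_lut_text()`
#'   returns a [colormap()].
#' @export
write_lut_text <- function(map, path) {
  stopifnot(inherits(map, "microv_colormap"))
  m <- round(map$colors)
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_lut_text
#' @param name identifier for the map read from file.
#' @export
read_lut_text <- function(path, name = "custom") {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(m) != 256L || ncol(m) != 3L)
    stop("LUT file must have 256 rows and 3 columns (got ",
         nrow(m), " x ", ncol(m), ")")
  colormap(m, name = name, provenance = paste("LUT file", path))
}

#' Write / read the JSON form of a colormap
#'
#' Carries name, provenance and the gray column explicitly, so the file is
#' self-describing.
#'
#' @inheritParams write_lut_text
#' @export
write_colormap_json <- function(map, path) {
  stopifnot(inherits(map, "microv_colormap"))
  obj <- list(name = map$name, provenance = map$provenance,
              gray = map$gray,
              r = map$colors[, 1], g = map$colors[, 2], b = map$colors[, 3])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_colormap_json
#' @export
read_colormap_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(obj$gray), 255:0))
    stop("colormap JSON must carry the gray sequence 255..0")
  colormap(cbind(obj$r, obj$g, obj$b), name = obj$name,
           provenance = obj$provenance)
}

#' @export
print.microv_colormap <- function(x, ...) {
  cat(sprintf("MicroV colormap '%s': 256 entries, gray 255..0 (%s)\n",
              x$name, x$provenance))
  invisible(x)
}
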