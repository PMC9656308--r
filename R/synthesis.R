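# Synthetic MicroV-like captures with known ground truth.
#
# A phantom emulates the scene the pipeline is built for: a rectangular
# Doppler color box containing colormap-encoded flow over an achromatic
# speckle B-mode background, with a color-scale bar along one edge and a
# one-pixel box outline. Because the truth flow grid is known, every pipeline
# stage can be checked exactly.

#' Phantom specification
#'
#' Defaults describe a mid-sized capture: a 512 x 384 frame with a
#' 220 x 172 px color box (about 38k analysed pixels, the order of magnitude
#' of a clinical ROI), eight vessels of random-walk geometry with Gaussian
#' transverse flow profiles, achromatic speckle background, and a connected
#' necrotic region with no flow covering 15% of the box.
#'
#' @param width,height frame size in pixels.
#' @param box a [roi_box()] for the Doppler color box; must lie inside the
#'   frame.
#' @param n_vessels number of vessels to draw.
#' @param amplitude_range `c(min, max)` peak flow per vessel, 0--255.
#' @param thickness_range `c(min, max)` vessel full width in pixels.
#' @param speckle_mean,speckle_sd background speckle gray level parameters
#'   (Gaussian, clipped to 0--255; chroma exactly 0).
#' @param speckle_chroma_jitter optional small uniform jitter (in channel
#'   units) added to one background channel, to stress chroma thresholding;
#'   default 0 so background classification is unambiguous.
#' @param necrotic_fraction fraction of the box (0--1) covered by a connected
#'   region where flow is forced to 0.
#' @param colormap builtin colormap name used to render the box ("MV0" or
#'   "MV2").
#' @param seed integer; the same spec and seed always produce a bit-identical
#'   phantom.
#' @return object of class `microv_phantom_spec`.
#' @export
phantom_spec <- function(width = 512L, height = 384L,
                         box = roi_box(96L, 64L, 316L, 236L),
                         n_vessels = 8L,
                         amplitude_range = c(40, 254),
                         thickness_range = c(2, 6),
                         speckle_mean = 60, speckle_sd = 18,
                         speckle_chroma_jitter = 0,
                         necrotic_fraction = 0.15,
                         colormap = "MV0",
                         seed = 1L) {
  stopifnot(inherits(box, "microv_roi"))
  if (box$x0 < 0 || box$y0 < 0 || box$x1 > width || box$y1 > height)
    stop("color box must lie inside the frame")
  if (length(amplitude_range) != 2L || any(amplitude_range < 0) ||
      any(amplitude_range > 255) || amplitude_range[1] > amplitude_range[2])
    stop("'amplitude_range' must be c(min, max) within 0..255")
  if (length(thickness_range) != 2L || any(thickness_range <= 0) ||
      thickness_range[1] > thickness_range[2])
    stop("'thickness_range' must be c(min, max), positive")
  if (necrotic_fraction < 0 || necrotic_fraction > 1)
    stop("'necrotic_fraction' must be in [0, 1]")
  if (n_vessels < 0 || n_vessels != round(n_vessels))
    stop("'n_vessels' must be a non-negative integer")
  structure(
    list(width = as.integer(width), height = as.integer(height), box = box,
         n_vessels = as.integer(n_vessels),
         amplitude_range = as.numeric(amplitude_range),
         thickness_range = as.numeric(thickness_range),
         speckle_mean = speckle_mean, speckle_sd = speckle_sd,
         speckle_chroma_jitter = speckle_chroma_jitter,
         necrotic_fraction = necrotic_fraction,
         colormap = colormap, seed = as.integer(seed)),
    class = "microv_phantom_spec")
}

#' Encode a flow image through a colormap
#'
#' The inverse of retro-conversion: the pixel with flow `g` receives the
#' (rounded) color of the colormap entry whose gray value is `g`.
#'
#' @param flow a [flow_image()].
#' @param map a [colormap()].
#' @return a [rgb_image()].
#' @export
encode_with_colormap <- function(flow, map) {
  stopifnot(inherits(flow, "microv_flow"), inherits(map, "microv_colormap"))
  cols <- round(map$colors)
  idx <- 256L - flow$pixels  # entry row for gray g is 256 - g
  px <- array(0, c(flow$height, flow$width, 3L))
  for (c in 1:3) px[, , c] <- matrix(cols[idx, c], flow$height, flow$width)
  rgb_image(px, pixel_spacing = flow$pixel_spacing)
}

#' Generate a synthetic MicroV phantom
#'
#' Vessels are random-walk polylines with Gaussian transverse flow profiles;
#' each vessel's peak amplitude and thickness are drawn from the spec ranges,
#' and the flow field is the pixelwise maximum over vessels, with centreline
#' pixels carrying the exact peak amplitude. A connected necrotic region
#' (grown by randomized flood fill) zeroes the requested fraction of the box.
#' The rendered frame encodes the truth through the spec's colormap inside
#' the box, draws a one-pixel achromatic box outline and a 256-px color-scale
#' bar (highest flow at the top) on the right edge, over achromatic Gaussian
#' speckle. Randomness is fully determined by `spec$seed`; the caller's RNG
#' state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `microv_phantom`: `truth_flow` (a [flow_image()],
#'   0 outside the box), `rendered` (a [rgb_image()]), `spec`, and `bar`
#'   (the scale-bar geometry as half-open pixel bounds plus its orientation).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "microv_phantom_spec"))
  box <- spec$box
  bw <- box$x1 - box$x0; bh <- box$y1 - box$y0
  rmax <- ceiling(1.5 * max(spec$thickness_range))  # stamp radius at 3 sigma
  if (min(bw, bh) <= 2L * rmax + 2L)
    stop("color box too small for the requested vessel thickness")
  h <- spec$height; w <- spec$width
  if (h < 256L + 2L)
    stop("frame height must be at least 258 px to hold the 256-px scale bar")
  if (w - 14L < box$x1)
    stop("frame too narrow to place the scale bar beside the color box")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  field <- matrix(0, bh, bw)
  if (spec$n_vessels > 0L) {
    for (v in seq_len(spec$n_vessels))
      field <- pmax(field, draw_vessel(bh, bw,
                                       stats::runif(1, spec$amplitude_range[1],
                                                    spec$amplitude_range[2]),
                                       stats::runif(1, spec$thickness_range[1],
                                                    spec$thickness_range[2])))
  }
  truth_box <- round(field)
  if (spec$necrotic_fraction > 0) {
    target <- round(spec$necrotic_fraction * bh * bw)
    if (target > 0) truth_box[grow_region(bh, bw, target)] <- 0
  }
  truth <- matrix(0L, h, w)
  truth[(box$y0 + 1L):box$y1, (box$x0 + 1L):box$x1] <- truth_box

  # achromatic speckle background
  g <- pmin(pmax(round(stats::rnorm(h * w, spec$speckle_mean, spec$speckle_sd)), 0), 255)
  rendered <- array(rep(matrix(g, h, w), 3L), c(h, w, 3L))
  if (spec$speckle_chroma_jitter > 0) {
    jit <- round(stats::runif(h * w, 0, spec$speckle_chroma_jitter))
    rendered[, , 1] <- pmin(rendered[, , 1] + matrix(jit, h, w), 255)
  }

  # encode truth inside the box
  map <- builtin_colormap(spec$colormap)
  enc <- encode_with_colormap(flow_image(truth_box), map)
  rendered[(box$y0 + 1L):box$y1, (box$x0 + 1L):box$x1, ] <- enc$pixels

  # one-pixel achromatic outline on the box border
  for (c in 1:3) {
    rendered[c(box$y0 + 1L, box$y1), (box$x0 + 1L):box$x1, c] <- 220
    rendered[(box$y0 + 1L):box$y1, c(box$x0 + 1L, box$x1), c] <- 220
  }

  # 256-px scale bar on the right edge, highest flow at the top
  bar_y0 <- if (box$y0 + 256L <= h) box$y0 else 0L
  bar <- list(x0 = w - 14L, x1 = w - 6L, y0 = bar_y0, y1 = bar_y0 + 256L,
              high = "top")
  cols <- round(map$colors)
  for (c in 1:3)
    rendered[(bar$y0 + 1L):bar$y1, (bar$x0 + 1L):bar$x1, c] <-
      matrix(cols[, c], 256L, bar$x1 - bar$x0)

  structure(
    list(truth_flow = flow_image(truth, colormap_name = spec$colormap),
         rendered = rgb_image(rendered),
         spec = spec, bar = bar),
    class = "microv_phantom")
}

# Gaussian-profile vessel along a random-walk polyline, rasterised onto a
# bh x bw grid; the centreline pixels carry exactly the peak amplitude.
draw_vessel <- function(bh, bw, amplitude, thickness) {
  sigma <- thickness / 2
  r <- ceiling(3 * sigma)
  n_steps <- round(1.5 * max(bh, bw))
  x <- stats::runif(1, r, bw - 1 - r); y <- stats::runif(1, r, bh - 1 - r)
  theta <- stats::runif(1, 0, 2 * pi)
  prof <- matrix(0, bh, bw)
  cl_r <- integer(n_steps); cl_c <- integer(n_steps)
  for (s in seq_len(n_steps)) {
    theta <- theta + stats::rnorm(1, 0, 0.15)
    x2 <- x + cos(theta); y2 <- y + sin(theta)
    if (x2 < 0 || x2 > bw - 1) { theta <- pi - theta; x2 <- x }
    if (y2 < 0 || y2 > bh - 1) { theta <- -theta; y2 <- y }
    x <- x2; y <- y2
    # stamp the Gaussian profile on the neighbourhood of the path point
    ci <- max(0, floor(x) - r):min(bw - 1, floor(x) + r)
    ri <- max(0, floor(y) - r):min(bh - 1, floor(y) + r)
    d2 <- outer((ri - y)^2, (ci - x)^2, "+")
    patch <- amplitude * exp(-d2 / (2 * sigma^2))
    prof[ri + 1L, ci + 1L] <- pmax(prof[ri + 1L, ci + 1L], patch)
    cl_r[s] <- round(y) + 1L; cl_c[s] <- round(x) + 1L
  }
  prof[cbind(cl_r, cl_c)] <- amplitude
  prof
}

# Connected region of `target` pixels grown by randomised flood fill.
# Returns a logical bh x bw mask.
grow_region <- function(bh, bw, target) {
  target <- min(target, bh * bw)
  mask <- matrix(FALSE, bh, bw)
  frontier <- matrix(c(sample.int(bh, 1L), sample.int(bw, 1L)), 1L, 2L)
  taken <- 0L
  while (taken < target && nrow(frontier) > 0L) {
    i <- sample.int(nrow(frontier), 1L)
    p <- frontier[i, ]; frontier <- frontier[-i, , drop = FALSE]
    if (mask[p[1], p[2]]) next
    mask[p[1], p[2]] <- TRUE; taken <- taken + 1L
    nb <- rbind(p + c(1L, 0L), p - c(1L, 0L), p + c(0L, 1L), p - c(0L, 1L))
    nb <- nb[nb[, 1] >= 1L & nb[, 1] <= bh & nb[, 2] >= 1L & nb[, 2] <= bw, ,
             drop = FALSE]
    nb <- nb[!mask[nb], , drop = FALSE]
    frontier <- rbind(frontier, nb)
  }
  mask
}

#' Crop a phantom's scale bar as a ScaleStrip
#'
#' @param phantom a [generate_phantom()] result.
#' @return a [scale_strip()] suitable for [build_colormap_from_strip()].
#' @export
crop_scale_bar <- function(phantom) {
  stopifnot(inherits(phantom, "microv_phantom"))
  b <- phantom$bar
  scale_strip(phantom$rendered$pixels[(b$y0 + 1L):b$y1,
                                      (b$x0 + 1L):b$x1, , drop = FALSE],
              high = b$high)
}

#' End-to-end parameter recovery check
#'
#' Runs the full pipeline on a phantom — retro-conversion, ROI extraction at
#' inset 1 (excluding the box outline), first-order features — and compares
#' every statistic with the same statistics computed on the ground-truth flow
#' over the pixels classified as colored. Because the colormap encoding is
#' lossless for injective integer maps, all discrepancies should be exactly
#' zero.
#'
#' @param phantom a [generate_phantom()] result.
#' @param map colormap to decode with; defaults to the phantom's own.
#' @param chroma_threshold,background_policy passed to [retroconvert_mv0()];
#'   the default zero-threshold `"zero"` policy zeroes the achromatic speckle.
#' @return object of class `microv_recovery`: a comparison table
#'   (`statistic`, `truth`, `recovered`, `abs_diff`), the number of colored
#'   pixels, the per-pixel value mismatch count, the histogram bin mismatch
#'   count, and `all_match`.
#' @export
recover_parameters_check <- function(phantom, map = NULL,
                                     chroma_threshold = 0,
                                     background_policy = "zero") {
  stopifnot(inherits(phantom, "microv_phantom"))
  if (is.null(map)) map <- builtin_colormap(phantom$spec$colormap)
  box <- phantom$spec$box
  inner <- roi_box(box$x0, box$y0, box$x1, box$y1, inset = 1L)

  flow <- retroconvert_mv0(phantom$rendered, map,
                           chroma_threshold = chroma_threshold,
                           background_policy = background_policy)
  roi <- extract_roi(flow, inner)
  troi <- extract_roi(phantom$truth_flow, inner)
  colored <- !roi$chroma_mask
  n_col <- sum(colored)
  if (n_col == 0L) {
    return(structure(list(table = NULL, n_colored = 0L,
                          value_mismatches = NA_integer_,
                          histogram_mismatches = NA_integer_,
                          all_match = NA), class = "microv_recovery"))
  }
  rv <- roi$pixels[colored]; tv <- troi$pixels[colored]
  fr <- first_order_features(rv); ft <- first_order_features(tv)
  stats_of <- function(f) c(n_pixels = f$n_pixels, mean = f$mean,
                            stdev = f$stdev, min = f$min, max = f$max,
                            mode_value = f$mode_value,
                            mode_count = f$mode_count)
  a <- stats_of(ft); b <- stats_of(fr)
  tab <- data.frame(statistic = names(a), truth = unname(a),
                    recovered = unname(b), abs_diff = abs(unname(a - b)))
  hmis <- sum(fr$histogram != ft$histogram)
  vmis <- sum(rv != tv)
  structure(list(table = tab, n_colored = n_col,
                 value_mismatches = vmis, histogram_mismatches = hmis,
                 all_match = vmis == 0L && hmis == 0L && all(tab$abs_diff == 0)),
            class = "microv_recovery")
}

#' @export
print.microv_recovery <- function(x, ...) {
  if (is.null(x$table)) {
    cat("Recovery check: no colored pixels in ROI\n")
    return(invisible(x))
  }
  cat(sprintf("Recovery check over %d colored pixels: %s\n", x$n_colored,
              if (isTRUE(x$all_match)) "exact match" else "MISMATCH"))
  print(x$table, row.names = FALSE)
  cat(sprintf("pixel mismatches: %d, histogram bin mismatches: %d\n",
              x$value_mismatches, x$histogram_mismatches))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes `<stem>_rendered.tif` (RGB), `<stem>_truth.tif` (8-bit grayscale)
#' and `<stem>_spec.json`; optionally also a DICOM secondary capture of the
#' rendered frame.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @param dicom also write `<stem>_rendered.dcm`.
#' @return named character vector of paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom", dicom = FALSE) {
  stopifnot(inherits(phantom, "microv_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rendered = file.path(dir, paste0(stem, "_rendered.tif")),
             truth = file.path(dir, paste0(stem, "_truth.tif")),
             spec = file.path(dir, paste0(stem, "_spec.json")))
  write_rgb_tiff(phantom$rendered, paths[["rendered"]])
  write_flow_tiff(phantom$truth_flow, paths[["truth"]])
  write_phantom_spec_json(phantom$spec, paths[["spec"]])
  if (dicom) {
    paths[["dicom"]] <- file.path(dir, paste0(stem, "_rendered.dcm"))
    write_dicom(phantom$rendered, paths[["dicom"]])
  }
  invisible(paths)
}

#' Serialise / restore a phantom spec as JSON
#'
#' @param spec a [phantom_spec()].
#' @param path JSON file.
#' @export
write_phantom_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "microv_phantom_spec"))
  obj <- unclass(spec)
  obj$box <- unclass(spec$box)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec_json
#' @export
read_phantom_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- obj$box
  phantom_spec(width = obj$width, height = obj$height,
               box = roi_box(b$x0, b$y0, b$x1, b$y1, b$inset),
               n_vessels = obj$n_vessels,
               amplitude_range = obj$amplitude_range,
               thickness_range = obj$thickness_range,
               speckle_mean = obj$speckle_mean, speckle_sd = obj$speckle_sd,
               speckle_chroma_jitter = obj$speckle_chroma_jitter,
               necrotic_fraction = obj$necrotic_fraction,
               colormap = obj$colormap, seed = obj$seed)
}
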