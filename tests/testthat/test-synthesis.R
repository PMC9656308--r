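test_that("colormap encoding reproduces the display semantics", {
  mv2 <- builtin_colormap("MV2")
  white <- encode_with_colormap(flow_image(matrix(255L, 6, 8)), mv2)
  black <- encode_with_colormap(flow_image(matrix(0L, 6, 8)), mv2)
  expect_true(all(white$pixels == 255))  # highest flow renders white
  expect_true(all(black$pixels == 0))    # no flow renders black
})

test_that("phantom generation is bit-deterministic under a seed", {
  spec <- small_phantom_spec(seed = 101L)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$truth_flow$pixels, p2$truth_flow$pixels)
  expect_identical(p1$rendered$pixels, p2$rendered$pixels)
  p3 <- generate_phantom(small_phantom_spec(seed = 102L))
  expect_false(identical(p1$truth_flow$pixels, p3$truth_flow$pixels))
})

test_that("phantom generation leaves the caller's RNG state untouched", {
  set.seed(500)
  before <- .Random.seed
  invisible(generate_phantom(small_phantom_spec(seed = 1L)))
  expect_identical(.Random.seed, before)
})

test_that("an empty scene has zero flow everywhere in the box", {
  p <- generate_phantom(small_phantom_spec(seed = 5L, n_vessels = 0L,
                                           necrotic_fraction = 0))
  expect_true(all(p$truth_flow$pixels == 0L))
})

test_that("truth flow is zero outside the color box", {
  p <- generate_phantom(small_phantom_spec(seed = 6L))
  box <- p$spec$box
  outside <- p$truth_flow$pixels
  outside[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1] <- 0L
  expect_true(all(outside == 0L))
})

test_that("fixed-amplitude vessels peak exactly at the requested amplitude", {
  p <- generate_phantom(small_phantom_spec(seed = 7L, n_vessels = 5L,
                                           amplitude_range = c(200, 200),
                                           necrotic_fraction = 0))
  expect_identical(max(p$truth_flow$pixels), 200L)
  # recompute the box statistics directly from the generated truth grid
  box <- p$spec$box
  grid <- p$truth_flow$pixels[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1]
  f <- first_order_features(flow_image(grid))
  expect_equal(f$mean, sum(as.numeric(grid)) / length(grid))
  expect_identical(f$max, 200L)
})

test_that("the necrotic region zeroes the requested connected fraction", {
  frac <- 0.25
  pz <- generate_phantom(small_phantom_spec(seed = 8L, necrotic_fraction = 0,
                                            amplitude_range = c(200, 254)))
  pn <- generate_phantom(small_phantom_spec(seed = 8L, necrotic_fraction = frac,
                                            amplitude_range = c(200, 254)))
  box <- pn$spec$box
  area <- (box$x1 - box$x0) * (box$y1 - box$y0)
  zeroed <- pz$truth_flow$pixels > 0 & pn$truth_flow$pixels == 0
  # the grown region covers frac of the box, so it can zero at most that many
  # vessel pixels, and the remaining truth is a subset of the original
  expect_lte(sum(zeroed), round(frac * area))
  expect_true(all(pn$truth_flow$pixels[pn$truth_flow$pixels > 0] ==
                  pz$truth_flow$pixels[pn$truth_flow$pixels > 0]))
})

test_that("a too-small box for the vessel thickness is rejected", {
  expect_error(generate_phantom(
    phantom_spec(width = 320L, height = 280L,
                 box = roi_box(10L, 10L, 28L, 28L),
                 thickness_range = c(6, 6))), "too small")
})

test_that("the rendered scale bar rebuilds the generating colormap exactly", {
  p <- generate_phantom(small_phantom_spec(seed = 9L))
  rebuilt <- build_colormap_from_strip(crop_scale_bar(p))
  map <- builtin_colormap(p$spec$colormap)
  expect_equal(unname(rebuilt$colors), unname(round(map$colors)))
})

test_that("the full pipeline recovers truth statistics exactly", {
  p <- generate_phantom(small_phantom_spec(seed = 10L))
  rep <- recover_parameters_check(p)
  expect_true(rep$all_match)
  expect_identical(rep$value_mismatches, 0L)
  expect_identical(rep$histogram_mismatches, 0L)
  expect_true(all(rep$table$abs_diff == 0))
})

test_that("constant-amplitude phantoms recover the amplitude as the mode", {
  p <- generate_phantom(small_phantom_spec(seed = 11L, n_vessels = 6L,
                                           amplitude_range = c(180, 180),
                                           necrotic_fraction = 0))
  flow <- retroconvert_mv0(p$rendered, builtin_colormap("MV0"),
                           background_policy = "zero")
  box <- p$spec$box
  roi <- extract_roi(flow, roi_box(box$x0, box$y0, box$x1, box$y1, inset = 1L))
  vessel <- roi$pixels[roi$pixels == max(roi$pixels)]
  expect_identical(max(roi$pixels), 180L)
  # 180 is the most frequent nonzero intensity (the vessel plateau)
  nz <- roi$pixels[roi$pixels > 0]
  counts <- tabulate(nz, nbins = 255)
  expect_identical(which.max(counts), 180L)
})

test_that("phantom files and the spec sidecar round-trip", {
  dir <- tempfile()
  p <- generate_phantom(small_phantom_spec(seed = 12L))
  paths <- write_phantom(p, dir, stem = "ph", dicom = TRUE)
  expect_true(all(file.exists(paths)))
  truth <- read_flow_tiff(paths[["truth"]])
  expect_identical(truth$pixels, p$truth_flow$pixels)
  rendered <- read_capture(paths[["rendered"]])
  expect_equal(rendered$pixels, p$rendered$pixels)
  dcm <- read_capture(paths[["dicom"]])
  expect_equal(dcm$pixels, p$rendered$pixels)
  spec2 <- read_phantom_spec_json(paths[["spec"]])
  expect_identical(generate_phantom(spec2)$truth_flow$pixels,
                   p$truth_flow$pixels)
})

test_that("chroma jitter stresses the threshold logic as documented", {
  p <- generate_phantom(small_phantom_spec(seed = 13L,
                                           speckle_chroma_jitter = 3))
  flow <- retroconvert_mv0(p$rendered, builtin_colormap("MV0"),
                           chroma_threshold = 3, background_policy = "zero")
  box <- p$spec$box
  # background (outside the box, away from the scale bar) must be zeroed
  bg <- flow$pixels[, 1:(box$x0 - 1)]
  expect_true(all(bg == 0L))
})
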