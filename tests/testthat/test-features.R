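test_that("ROI extraction honours half-open bounds and inset", {
  img <- flow_image(matrix(0:99, 10, 10, byrow = TRUE))
  expect_identical(dim(extract_roi(img, roi_box(0, 0, 10, 10, inset = 1))$pixels),
                   c(8L, 8L))
  expect_identical(extract_roi(img, roi_box(0, 0, 10, 10))$pixels, img$pixels)
  # coordinate grid: pixel (x, y) holds 10*y + x, so the sub-grid is read off
  # directly from the half-open interval definition
  sub <- extract_roi(img, roi_box(2, 3, 7, 9))
  expect_identical(dim(sub$pixels), c(6L, 5L))
  expected <- outer(3:8, 2:6, function(y, x) 10L * y + x)
  expect_identical(sub$pixels, expected)
})

test_that("degenerate or out-of-bounds ROIs are rejected", {
  img <- flow_image(matrix(0L, 10, 10))
  expect_error(roi_box(0, 0, 4, 4, inset = 2), "empty")
  expect_error(extract_roi(img, roi_box(5, 5, 12, 8)), "outside")
  expect_error(roi_box(3, 3, 3, 8), "empty")
})

test_that("a constant ROI yields the degenerate statistics", {
  f <- first_order_features(flow_image(matrix(7L, 4, 5)))
  expect_identical(f$n_pixels, 20L)
  expect_equal(f$mean, 7)
  expect_equal(f$stdev, 0)
  expect_identical(c(f$min, f$max, f$mode_value), c(7L, 7L, 7L))
  expect_identical(f$mode_count, 20L)
  expect_false(f$mode_tie)
})

test_that("the full 0..255 ramp has a flat histogram and mean 127.5", {
  f <- first_order_features(flow_image(matrix(0:255, 16, 16)))
  expect_true(all(f$histogram == 1L))
  expect_equal(f$mean, sum(0:255) / 256)  # = 127.5
  expect_identical(f$min, 0L)
  expect_identical(f$max, 255L)
  expect_true(f$mode_tie)       # all intensities equally frequent
  expect_identical(f$mode_value, 0L)  # ties resolve to the lowest intensity
})

test_that("statistics match direct summation on an enumerated multiset", {
  v <- c(0L, 8L, 8L, 8L, 16L, 32L, 64L, 128L, 254L)
  f <- first_order_features(flow_image(matrix(v, 3, 3)))
  ref <- brute_features(v)
  expect_equal(f$mean, ref$mean)
  expect_equal(f$stdev, ref$stdev)
  expect_identical(f$mode_value, 8L)
  expect_identical(f$mode_count, 3L)
  expect_identical(f$histogram, ref$histogram)
})

test_that("statistics equal a brute-force oracle on random small ROIs", {
  set.seed(21)
  for (i in 1:30) {
    h <- sample(1:32, 1); w <- sample(1:32, 1)
    v <- sample(0:255, h * w, TRUE)
    f <- first_order_features(flow_image(matrix(v, h, w)))
    ref <- brute_features(v)
    expect_identical(f$n_pixels, ref$n)
    expect_identical(c(f$min, f$max), c(ref$min, ref$max))
    expect_identical(f$mode_value, as.integer(ref$mode_value))
    expect_identical(f$mode_count, as.integer(ref$mode_count))
    expect_identical(f$histogram, ref$histogram)
    expect_equal(f$mean, ref$mean, tolerance = 1e-12)
    expect_equal(f$stdev, ref$stdev, tolerance = 1e-12)
  }
})

test_that("statistics are permutation invariant and shift covariant", {
  set.seed(22)
  v <- sample(10:200, 400, TRUE)
  a <- first_order_features(v)
  b <- first_order_features(sample(v))
  expect_equal(a[c("mean", "stdev", "min", "max", "mode_value", "mode_count")],
               b[c("mean", "stdev", "min", "max", "mode_value", "mode_count")])
  shifted <- first_order_features(v + 50L)  # stays within 0..255
  expect_equal(shifted$mean, a$mean + 50)
  expect_equal(shifted$stdev, a$stdev)
})

test_that("sample and population standard deviations differ as N/(N-1)", {
  v <- c(0L, 10L, 20L, 30L)
  pop <- first_order_features(v)$stdev
  smp <- first_order_features(v, stdev = "sample")$stdev
  expect_equal(smp, stats::sd(v))
  expect_equal(smp^2 * 3 / 4, pop^2)
})

test_that("area is reported in px^2 and in mm^2 when spacing is known", {
  img <- flow_image(matrix(5L, 10, 20), pixel_spacing = 0.1)
  f <- first_order_features(img)
  expect_equal(f$area_px2, 200)
  expect_equal(f$area_mm2, 200 * 0.01)
  expect_true(is.na(first_order_features(flow_image(matrix(5L, 2, 2)))$area_mm2))
})

test_that("empty ROIs are rejected", {
  expect_error(first_order_features(integer(0)), "empty")
})

test_that("the feature table mirrors the conventional schema", {
  r1 <- first_order_features(flow_image(matrix(c(rep(8L, 3), 1L), 2, 2)))
  r2 <- first_order_features(flow_image(matrix(7L, 4, 5)))
  tab <- write_feature_table(list(r1, r2), c("case-a", "case-b"))
  expect_identical(nrow(tab), 2L)
  expect_identical(names(tab)[1:8],
                   c("Case", "N", "Area", "Mean", "StDev", "Min", "Max", "Mode"))
  expect_identical(tab$Mode[1], "8 (3)")
  expect_identical(tab$Mode[2], "7 (20)")
  expect_equal(tab$ModeValue, c(8, 7))  # unformatted numeric columns kept

  path <- tempfile(fileext = ".csv")
  write_feature_table(list(r1, r2), c("a", "b"), path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 2L)
  expect_identical(back$Mode, c("8 (3)", "7 (20)"))

  expect_error(write_feature_table(list(), character()), "no feature records")
  expect_error(write_feature_table(list(r1, r2), c("x", "x")), "duplicate")
})

test_that("histogram export writes consistent CSV and a TIFF raster", {
  dir <- tempfile(); dir.create(dir)
  const <- first_order_features(flow_image(matrix(7L, 4, 5)))
  paths <- export_histogram(const, file.path(dir, "const"))
  h <- utils::read.csv(paths[["csv"]])
  expect_identical(nrow(h), 256L)
  expect_identical(h$count[h$intensity == 7], 20L)
  expect_true(all(h$count[h$intensity != 7] == 0L))
  expect_true(file.exists(paths[["tiff"]]))
  expect_gt(file.info(paths[["tiff"]])$size, 0)

  ramp <- first_order_features(flow_image(matrix(0:255, 16, 16)))
  h2 <- utils::read.csv(export_histogram(ramp, file.path(dir, "ramp"))[["csv"]])
  expect_true(all(h2$count == 1L))
  expect_identical(sum(h2$count), ramp$n_pixels)

  expect_error(export_histogram(const, file.path(dir, "missing", "x")),
               "directory")
})
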