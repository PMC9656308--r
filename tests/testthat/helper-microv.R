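# Shared fixtures and independent oracles. Fixtures are generated in code;
# oracles are deliberately written as plain loops, independent of the
# vectorised implementation paths they check.

# exhaustive nearest-entry search with the documented tie rule
# (smallest squared distance; on a tie, the larger gray wins)
brute_nearest <- function(map, color) {
  best_gray <- -1L; best_d <- Inf
  for (i in 1:256) {
    d <- sum((map$colors[i, ] - color)^2)
    if (d < best_d || (d == best_d && map$gray[i] > best_gray)) {
      best_d <- d; best_gray <- map$gray[i]
    }
  }
  list(gray = best_gray, dist2 = best_d)
}

# first-order statistics recomputed by direct summation over the pixel list
brute_features <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  counts <- integer(256)
  for (x in v) counts[x + 1L] <- counts[x + 1L] + 1L
  mode_value <- which.max(counts) - 1L  # ties: lowest intensity
  list(n = n, mean = m, stdev = sqrt(sum((v - m)^2) / n),
       min = min(v), max = max(v),
       mode_value = mode_value, mode_count = max(counts),
       histogram = counts)
}

# solid-color strip with one row per scale segment, highest flow first
strip_from_rows <- function(rows, high = "top") {
  scale_strip(array(rep(rows, each = 1),
                    dim = c(nrow(rows), 1L, 3L))[, c(1, 1, 1), , drop = FALSE],
              high = high)
}

random_flow <- function(h, w) flow_image(matrix(sample(0:255, h * w, TRUE), h, w))

small_phantom_spec <- function(seed, n_vessels = 4L, ...) {
  phantom_spec(width = 320L, height = 280L,
               box = roi_box(40L, 10L, 200L, 150L),
               n_vessels = n_vessels, seed = seed, ...)
}
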