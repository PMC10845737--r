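test_that("histograms of degenerate images are delta distributions", {
  grey <- array(128L, dim = c(4, 4, 3))
  h <- compute_histogram(grey)
  expect_equal(unname(h$bins[129, ]), c(1, 1, 1))
  expect_equal(sum(h$bins), 3)

  bw <- array(c(0L, 255L), dim = c(2, 1, 3))
  h <- compute_histogram(bw)
  expect_equal(unname(h$bins[1, ]), rep(0.5, 3))
  expect_equal(unname(h$bins[256, ]), rep(0.5, 3))
})

test_that("histogram matches an independent per-pixel tally", {
  set.seed(51)
  for (rep in 1:5) {
    img <- random_rgb_array(12, 9)
    h <- compute_histogram(img)
    for (ch in 1:3) {
      tally <- numeric(256)
      for (i in seq_len(dim(img)[1])) for (j in seq_len(dim(img)[2])) {
        v <- img[i, j, ch]
        tally[v + 1] <- tally[v + 1] + 1
      }
      expect_equal(unname(h$bins[, ch]), tally / sum(tally))
    }
  }
})

test_that("histogram input validation catches bad rasters and masks", {
  expect_error(compute_histogram(matrix(1, 4, 4)), "RGB")
  expect_error(compute_histogram(array(300, dim = c(4, 4, 3))), "8-bit")
  img <- random_rgb_array(4, 4)
  expect_error(compute_histogram(img, mask = matrix(FALSE, 4, 4)),
               "no pixels")
  expect_error(compute_histogram(img, mask = matrix(TRUE, 2, 2)),
               "dimensions")
  # mask restricts counting to selected pixels
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE
  h <- compute_histogram(img, mask = m)
  expect_equal(unname(h$bins[img[1, 1, 1] + 1, "R"]), 1)
})

test_that("doubles in [0,1] and integer 0..255 rasters agree", {
  set.seed(52)
  img <- random_rgb_array(8, 8)
  expect_equal(compute_histogram(img / 255)$bins, compute_histogram(img)$bins)
})

test_that("aggregation averages per bin and preserves normalization", {
  h1 <- delta_histogram(0)
  h2 <- delta_histogram(255)
  agg <- aggregate_histograms(list(h1, h2))
  expect_equal(unname(agg$bins[1, ]), rep(0.5, 3))
  expect_equal(unname(agg$bins[256, ]), rep(0.5, 3))
  expect_equal(agg$source_count, 2)

  expect_equal(aggregate_histograms(list(h1))$bins, h1$bins)

  set.seed(53)
  hs <- replicate(36, random_histogram(), simplify = FALSE)
  agg <- aggregate_histograms(hs)
  expect_equal(unname(colSums(agg$bins)), rep(1, 3), tolerance = 1e-12)
  # direct summation oracle for one bin
  expect_equal(unname(agg$bins[100, "G"]),
               mean(vapply(hs, function(h) h$bins[100, "G"], numeric(1))))
  expect_error(aggregate_histograms(list()), "no histograms")
})

test_that("distance has the closed-form value for delta vs uniform", {
  d <- histogram_distance(delta_histogram(0), uniform_histogram())
  per_channel <- (1 - 1 / 256)^2 + 255 * (1 / 256)^2
  expect_equal(unname(d$per_channel), rep(per_channel, 3))
  expect_equal(d$value, 3 * per_channel)
})

test_that("distance is a symmetric non-negative form with sqrt triangle", {
  set.seed(54)
  for (rep in 1:20) {
    a <- random_histogram(); b <- random_histogram(); c <- random_histogram()
    dab <- histogram_distance(a, b)
    expect_equal(dab$value, histogram_distance(b, a)$value)
    expect_gte(dab$value, 0)
    expect_equal(dab$value, sum(dab$per_channel))
    expect_lte(sqrt(histogram_distance(a, c)$value),
               sqrt(dab$value) + sqrt(histogram_distance(b, c)$value) + 1e-12)
  }
  h <- random_histogram()
  expect_equal(histogram_distance(h, h)$value, 0)
  bad <- h; bad$bins[1, 1] <- bad$bins[1, 1] + 0.5
  expect_error(histogram_distance(bad, h), "not normalized")
})

test_that("a constant channel shift strictly increases self-distance", {
  set.seed(55)
  img <- array(sample(30:220, 16 * 16 * 3, TRUE), dim = c(16, 16, 3))
  shifted <- img + 10L  # no clipping: values stay within 0..255
  d <- histogram_distance(compute_histogram(img), compute_histogram(shifted))
  expect_gt(d$value, 0)
})

test_that("percent increase matches its definition", {
  expect_equal(percent_increase(0.0040, 0.0074), 85)
  expect_equal(percent_increase(3, 3), 0)
  expect_equal(percent_increase(2, 1), -50)
  expect_error(percent_increase(0, 1), "> 0")
})

test_that("spread summary reports peaks, support and moments", {
  s <- spread_summary(delta_histogram(40))
  expect_equal(s$peak_height, rep(1, 3))
  expect_equal(s$occupied_bins, rep(1, 3))
  expect_equal(s$std_of_values, rep(0, 3))

  s <- spread_summary(uniform_histogram())
  expect_equal(s$peak_height, rep(1 / 256, 3))
  expect_equal(s$occupied_bins, rep(256, 3))

  # brute-force moment oracle on an arbitrary histogram
  set.seed(56)
  h <- random_histogram()
  s <- spread_summary(h)
  v <- 0:255
  p <- h$bins[, "B"]
  expect_equal(s$std_of_values[s$channel == "B"],
               sqrt(sum(v^2 * p) - sum(v * p)^2))
})

test_that("nearest-reference assignment recovers labels with tie-break", {
  refs <- list(first = delta_histogram(10), second = delta_histogram(200))
  expect_equal(recover_scanner(delta_histogram(10), refs), "first")
  expect_equal(recover_scanner(delta_histogram(200), refs), "second")
  # equidistant query resolves to the first label in reference order
  mid <- aggregate_histograms(list(delta_histogram(10), delta_histogram(200)))
  expect_equal(recover_scanner(mid, refs), "first")
  expect_error(recover_scanner(mid, refs["first"]), "two reference")
  expect_error(recover_scanner(mid, list()), "no reference")
})

test_that("tiles round-trip through PNG preserving the histogram", {
  dir <- withr::local_tempdir()
  tile <- generate_tile(48, 48, "ganglion", seed = 9)
  p <- write_image_tile(tile, file.path(dir, "t.png"))
  back <- read_image_tile(p)
  expect_equal(compute_histogram(back)$bins, compute_histogram(tile)$bins)
  expect_error(read_image_tile(file.path(dir, "missing.png")), "cannot read")
})
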