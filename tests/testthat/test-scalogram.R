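test_that("channel combination sums element-wise and truncates with a warning", {
  expect_equal(combine_channels(c(1, 1), c(2, 2), c(3, 3)), c(6, 6))
  k1 <- rnorm(10)
  expect_equal(combine_channels(k1, numeric(10), numeric(10)), k1)
  expect_equal(combine_channels(k1, rev(k1), numeric(10)),
               combine_channels(numeric(10), k1, rev(k1)))
  expect_warning(out <- combine_channels(1:5, 1:4, 1:4), "truncating")
  expect_equal(length(out), 4)
})

test_that("the Morlet CWT localises tones at their pseudo-frequency", {
  fs <- 1000
  g <- scale_grid(fs)
  expect_equal(length(g$scales), 64)
  m <- cwt_magnitude(tone(100, fs, 2048), g)
  expect_equal(g$freqs[which.max(rowMeans(m))], 100, tolerance = 10)
  expect_equal(cwt_magnitude(numeric(512), g), matrix(0, 64, 512))
  m3 <- cwt_magnitude(3 * tone(100, fs, 2048), g)
  expect_equal(m3, 3 * m, tolerance = 1e-10)
})

test_that("RGB conversion is shape-stable, normalisation-invariant and flags constants", {
  set.seed(16)
  m <- matrix(abs(rnorm(64 * 300)), 64, 300)
  img <- to_rgb_image(m, 128, source_id = "a")
  expect_equal(dim(img$pixels), c(128, 128, 3))
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  img2 <- to_rgb_image(2.5 * m + 7, 128, source_id = "a")
  expect_identical(img$pixels, img2$pixels)
  cimg <- to_rgb_image(matrix(4, 10, 10), 128)
  expect_true(cimg$degenerate)
  expect_equal(length(unique(as.vector(cimg$pixels))), 3)  # one colour
  img256 <- to_rgb_image(m, 256)
  expect_equal(dim(img256$pixels), c(256, 256, 3))
  expect_error(to_rgb_image(matrix(c(1, NA), 2, 2), 128), "[Nn]on-finite")
  expect_error(to_rgb_image(m, 64), "128 or 256")
})

test_that("the jet lookup table runs blue to red through cyan and yellow", {
  lut <- jet_colors(256)
  expect_equal(dim(lut), c(256, 3))
  expect_equal(unname(lut[1, ]), c(0, 0, 1), tolerance = 0.51)  # blue end
  expect_gt(lut[1, "b"], 0.49)
  expect_equal(unname(lut[256, ]), c(0.5, 0, 0), tolerance = 0.01)
  expect_lt(lut[256, "b"], 0.01)
  mid <- lut[128, ]
  expect_gt(mid["g"], 0.9)  # green-ish middle
})

test_that("scalogram PNGs are byte-identical across repeated generation", {
  fs <- 1000
  g <- scale_grid(fs)
  x <- tone(120, fs, 1024) + 0.1 * tone(40, fs, 1024)
  img1 <- signal_scalogram(x, g, 128, source_id = "x")
  img2 <- signal_scalogram(x, g, 128, source_id = "x")
  expect_identical(img1$pixels, img2$pixels)
  expect_equal(img1$grid_hash, g$hash)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_scalogram_png(img1, p1)
  write_scalogram_png(img2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- png::readPNG(p1)
  expect_equal(dim(back), c(128, 128, 3))
})

test_that("a fixed grid produces a stable hash and differing grids differ", {
  g1 <- scale_grid(1000)
  g2 <- scale_grid(1000)
  g3 <- scale_grid(2000)
  expect_identical(g1$hash, g2$hash)
  expect_false(identical(g1$hash, g3$hash))
})
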