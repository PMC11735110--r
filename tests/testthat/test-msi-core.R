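test_that("internal container round-trips shape, pixel size and spectra", {
  g <- tiny_grid(c(4, 4), seed = 3, empty_pixel = 6)
  stem <- file.path(tempdir(), "grid_rt")
  write_msi(g, stem)
  g2 <- read_msi(stem)
  expect_equal(g2$shape, g$shape)
  expect_equal(g2$pixel_size, g$pixel_size)
  expect_equal(g2$modality, g$modality)
  expect_equal(g2$mz, g$mz)
  expect_equal(g2$intensity, g$intensity)
  expect_length(g2$mz[[6]], 0)  # empty-spectrum pixel preserved as empty
  expect_error(read_msi(file.path(tempdir(), "no_such_stem")), "metadata")
})

test_that("imzML import reads processed and continuous encodings alike", {
  g <- tiny_grid(c(3, 5), seed = 8, empty_pixel = 2)
  for (mode in c("processed", "continuous")) {
    path <- file.path(tempdir(), paste0("t_", mode, ".imzML"))
    oxmsi:::write_imzml(g, path, mode = mode, mz_size = 8L, int_size = 4L)
    g2 <- read_imzml(path)
    expect_equal(g2$shape, g$shape)
    expect_equal(g2$pixel_size, g$pixel_size)
    # 32-bit intensity storage costs precision; m/z is stored in 64-bit
    expect_equal(g2$mz, g$mz)
    expect_equal(g2$intensity, g$intensity, tolerance = 1e-6)
  }
  # both encodings of the same dataset yield identical channel extractions
  p1 <- extract_channel(read_imzml(file.path(tempdir(), "t_processed.imzML")),
                        600, 50)
  p2 <- extract_channel(read_imzml(file.path(tempdir(), "t_continuous.imzML")),
                        600, 50)
  expect_equal(p1$values, p2$values)
})

test_that("channel extraction sums in-window intensities per pixel", {
  g <- tiny_grid(c(4, 4), seed = 5)
  none <- extract_channel(g, 2000, 0.05)
  expect_true(all(none$values == 0))
  # single constructed peak
  g1 <- msi_grid(list(c(465.3)), list(c(7)), c(1, 1))
  expect_equal(extract_channel(g1, 465.30, 0.05)$values[1, 1], 7)
  # total over the image equals direct summation over all spectra
  ch <- extract_channel(g, 650, 100)
  direct <- sum(unlist(Map(function(m, i) sum(i[m >= 550 & m <= 750]),
                           g$mz, g$intensity)))
  expect_equal(sum(ch$values), direct)
  # window bounds are closed
  gedge <- msi_grid(list(c(500, 501)), list(c(3, 5)), c(1, 1))
  expect_equal(extract_channel(gedge, 500.5, 0.5)$values[1, 1], 8)
})

test_that("channel extraction is additive under spectral concatenation", {
  shape <- c(3, 3)
  a <- tiny_grid(shape, seed = 21)
  b <- tiny_grid(shape, seed = 22)
  merged_mz <- Map(c, a$mz, b$mz)
  merged_int <- Map(c, a$intensity, b$intensity)
  ord <- lapply(merged_mz, order)
  merged <- msi_grid(Map(function(m, o) m[o], merged_mz, ord),
                     Map(function(i, o) i[o], merged_int, ord), shape)
  w <- c(600, 120)
  expect_equal(extract_channel(merged, w[1], w[2])$values,
               extract_channel(a, w[1], w[2])$values +
                 extract_channel(b, w[1], w[2])$values)
})

test_that("tile assembly places tiles row-major and splits back exactly", {
  one <- channel_image(matrix(1:6, 2, 3))
  expect_equal(assemble_tiles(list(one), 1, 1)$values, one$values)
  tiles <- lapply(1:4, function(v) channel_image(matrix(v, 2, 2)))
  mosaic <- assemble_tiles(tiles, 2, 2)
  expect_equal(mosaic$values[1, 1], 1)
  expect_equal(mosaic$values[1, 3], 2)
  expect_equal(mosaic$values[3, 1], 3)
  expect_equal(mosaic$values[4, 4], 4)
  set.seed(9)
  rtiles <- lapply(1:6, function(i) channel_image(matrix(runif(12), 3, 4)))
  m <- assemble_tiles(rtiles, 2, 3)
  for (tr in 1:2) {
    for (tc in 1:3) {
      expect_equal(m$values[(tr - 1) * 3 + 1:3, (tc - 1) * 4 + 1:4],
                   rtiles[[(tr - 1) * 3 + tc]]$values)
    }
  }
  back <- split_tiles(m, 2, 3)
  for (i in 1:6) expect_equal(back[[i]]$values, rtiles[[i]]$values)
  expect_error(assemble_tiles(rtiles, 2, 2), "expected 4 tiles")
  expect_error(assemble_tiles(c(rtiles[1:5], list(one)), 2, 3), "same shape")
})

test_that("roi mean equals the arithmetic mean of covered pixels", {
  img <- channel_image(matrix(5, 8, 8))
  expect_equal(roi_mean(img, roi(2, 2, 3, 3)), 5)
  img2 <- channel_image(matrix(1:4, 2, 2))
  expect_equal(roi_mean(img2, roi(0, 0, 2, 2)), 2.5)
  set.seed(14)
  img3 <- channel_image(matrix(runif(400), 20, 20))
  r <- roi(3, 11, 7, 5)
  expect_equal(roi_mean(img3, r), mean(img3$values[4:10, 12:16]))
  expect_error(roi_mean(img2, roi(1, 1, 2, 2)), "outside")
  masked <- channel_image(matrix(1:16, 4, 4),
                          mask = matrix(rep(c(TRUE, FALSE), 8), 4, 4))
  expect_equal(roi_mean(masked, roi(0, 0, 2, 2)),
               mean(masked$values[1:2, 1:2][masked$mask[1:2, 1:2]]))
})

test_that("roi sampling is in-bounds, reproducible and mask-aware", {
  img <- channel_image(matrix(0, 128, 128))
  rois <- sample_rois(img, k = 13, size = 15, seed = 42)
  expect_length(rois, 13)
  for (r in rois) {
    expect_true(r$row0 >= 0 && r$row0 + 15 <= 128)
    expect_true(r$col0 >= 0 && r$col0 + 15 <= 128)
  }
  again <- sample_rois(img, k = 13, size = 15, seed = 42)
  expect_identical(rois, again)
  mask <- matrix(FALSE, 128, 128)
  mask[, 65:128] <- TRUE
  right <- sample_rois(img, k = 13, size = 15, seed = 1, mask = mask)
  for (r in right) expect_true(r$col0 >= 64)
  expect_error(sample_rois(channel_image(matrix(0, 10, 10)), size = 15),
               "smaller")
  expect_error(sample_rois(img, k = 5, size = 15, seed = 1,
                           mask = matrix(FALSE, 128, 128)), "valid roi")
})

test_that("combining channels across modalities without registration fails", {
  a <- channel_image(matrix(1, 4, 4), modality = "gcib_lipid")
  b <- channel_image(matrix(1, 4, 4), modality = "c60_protein")
  expect_error(ratiometric_image(a, b), "modalit")
})

test_that("channel CSV export round-trips", {
  img <- channel_image(matrix(runif(24), 4, 6), pixel_size = 3.125,
                       modality = "gcib_lipid", channel = "PE(40:4)")
  p <- file.path(tempdir(), "chan.csv")
  write_channel(img, p)
  back <- read_channel(p, pixel_size = 3.125, modality = "gcib_lipid")
  expect_equal(back$values, img$values)
})
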