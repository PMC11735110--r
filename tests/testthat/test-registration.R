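test_that("intensity normalization maps onto [0,1] and is idempotent", {
  img <- channel_image(matrix(c(0, 5, 10, 5), 2, 2))
  n <- normalize01(img)
  expect_equal(sort(unique(as.vector(n$values))), c(0, 0.5, 1))
  expect_equal(normalize01(n)$values, n$values)
  const <- normalize01(channel_image(matrix(7, 3, 3)))
  expect_true(all(const$values == 0))
})

test_that("affine transforms compose, invert and serialize faithfully", {
  t1 <- affine_from_params(shift = c(3, -2), rotation_deg = 10, scale = 1.02,
                           center = c(50, 50))
  t2 <- affine_from_params(shift = c(-1, 4), rotation_deg = -5, scale = 0.97,
                           center = c(50, 50))
  x <- cbind(c(0, 10, 99), c(0, 45, 99))
  expect_equal(apply_affine(compose_affine(t2, t1), x),
               apply_affine(t2, apply_affine(t1, x)))
  ident <- compose_affine(invert_affine(t1), t1)
  expect_equal(ident$linear, diag(2), tolerance = 1e-12)
  expect_equal(ident$translation, c(0, 0), tolerance = 1e-10)
  p <- file.path(tempdir(), "transform.json")
  write_affine2d(t1, p)
  back <- read_affine2d(p)
  expect_equal(back$linear, t1$linear)
  expect_equal(back$translation, t1$translation)
  expect_error(affine2d(matrix(0, 2, 2)), "singular")
})

test_that("MSE objective matches its definition on constructed cases", {
  shape <- c(64, 64)
  f <- blob_texture(shape, seed = 3)
  img <- normalize01(texture_image(f, shape))
  ident <- affine2d()
  expect_equal(mse_objective(img, img, ident), 0)
  one <- channel_image(matrix(1, 32, 32))
  zero <- channel_image(matrix(0, 32, 32))
  expect_equal(mse_objective(one, zero, ident), 1)
  # known shift: objective at the true transform is ~0 on the overlap
  # (raw images so both carry the same intensity scale)
  raw <- texture_image(f, shape)
  shift <- affine2d(diag(2), c(3, 0))
  moving <- texture_image(f, shape, xform = shift)
  expect_lt(mse_objective(raw, moving, shift), 1e-12)
  # hopeless overlap returns the maximal surrogate
  expect_equal(mse_objective(img, img, affine2d(diag(2), c(1000, 1000))),
               .Machine$double.xmax)
})

test_that("registration of an image to itself returns near-identity", {
  shape <- c(96, 96)
  img <- texture_image(blob_texture(shape, seed = 5), shape)
  res <- register_affine(img, img)
  expect_equal(res$transform$linear, diag(2), tolerance = 1e-3)
  expect_equal(res$transform$translation, c(0, 0), tolerance = 0.05)
  expect_lt(res$final_mse, 1e-6)
})

test_that("registration recovers known translations and rotations", {
  shape <- c(128, 128)
  f <- blob_texture(shape, seed = 12)
  fixed <- texture_image(f, shape)
  tshift <- affine2d(diag(2), c(7.3, -4.1))
  res <- register_affine(fixed, texture_image(f, shape, xform = tshift))
  expect_equal(res$transform$translation, c(7.3, -4.1), tolerance = 0.5)
  expect_lt(corner_displacement(res$transform, tshift, shape), 1)
  trs <- affine_from_params(rotation_deg = 5, scale = 1.03,
                            center = (shape - 1) / 2)
  res2 <- register_affine(fixed, texture_image(f, shape, xform = trs))
  expect_lt(corner_displacement(res2$transform, trs, shape), 1)
  # accepted objective values never increase
  for (tr in c(res$objective_trace, res2$objective_trace)) {
    expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("registrations compose consistently across image chains", {
  shape <- c(128, 128)
  f <- blob_texture(shape, seed = 23)
  ta <- affine_from_params(shift = c(4, 2), rotation_deg = 3,
                           center = (shape - 1) / 2)
  tb <- affine_from_params(shift = c(-3, 5), rotation_deg = -4, scale = 1.02,
                           center = (shape - 1) / 2)
  A <- texture_image(f, shape)
  B <- texture_image(f, shape, xform = ta)            # B(ta(x)) = A(x)
  C <- texture_image(f, shape, xform = compose_affine(tb, ta))
  ab <- register_affine(A, B)$transform
  bc <- register_affine(B, C)$transform
  ac <- register_affine(A, C)$transform
  expect_lt(corner_displacement(compose_affine(bc, ab), ac, shape), 1)
})

test_that("resampling honors the pull-back convention", {
  shape <- c(48, 48)
  blobs <- blob_texture(shape, seed = 31)
  ctr <- (shape - 1) / 2
  # window the texture so its mass is central and conservation under small
  # warps is not confounded by mass leaving the image domain
  f <- function(r, c) {
    blobs(r, c) * exp(-((r - ctr[1])^2 + (c - ctr[2])^2) / (2 * 12^2))
  }
  img <- texture_image(f, shape, modality = "gcib_lipid")
  same <- resample_channels(img, affine2d(), shape)
  expect_equal(same$values, img$values, tolerance = 1e-12)
  expect_true(all(same$mask))
  # integer translation is an exact pixel shift, no interpolation blur
  shifted <- resample_channels(img, affine2d(diag(2), c(3, 2)), shape)
  expect_equal(shifted$values[1:45, 1:46], img$values[4:48, 3:48])
  expect_false(any(shifted$mask[46:48, ]))
  # total intensity conserved for a smooth image under a small transform
  small <- affine_from_params(shift = c(0.7, -0.4), rotation_deg = 1,
                              center = (shape - 1) / 2)
  warped <- resample_channels(img, small, shape)
  inner <- warped$mask
  expect_equal(sum(warped$values), sum(img$values), tolerance = 0.02)
  # list input: the same transform applies to every channel
  lst <- resample_channels(list(a = img, b = img), affine2d(diag(2), c(1, 0)),
                           shape)
  expect_equal(lst$a$values, lst$b$values)
})

test_that("pixel-size mismatch is reconciled in physical coordinates", {
  shape <- c(96, 96)
  f <- blob_texture(shape, seed = 40)
  fixed <- texture_image(f, shape, pixel_size = 2)
  # moving modality sampled twice as finely over the same physical field
  fine_shape <- c(192, 192)
  g <- grid_coords(fine_shape) / 2
  moving <- channel_image(matrix(f(g[, 1], g[, 2]), fine_shape[1]),
                          pixel_size = 1)
  res <- register_affine(fixed, moving)
  # truth: fixed pixel x maps to moving pixel 2x
  truth <- affine2d(diag(2) * 2, c(0, 0))
  expect_lt(corner_displacement(res$transform, truth, shape) / 2, 1)
  back <- resample_channels(moving, res$transform, shape, pixel_size = 2)
  expect_equal(back$values[10:80, 10:80], fixed$values[10:80, 10:80],
               tolerance = 0.05)
})
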