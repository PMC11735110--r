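# Programmatic fixtures shared across tests.

# Smooth random texture built from a fixed set of Gaussian blobs. Returning a
# closure lets tests evaluate the same continuous scene at arbitrary (warped)
# coordinates, so a "moving" image can be rendered without interpolation.
blob_texture <- function(shape, k = 60, seed = 7) {
  set.seed(seed)
  ctr <- cbind(runif(k, 0, shape[1] - 1), runif(k, 0, shape[2] - 1))
  sd <- runif(k, 4, 14)
  amp <- runif(k, 0.3, 1)
  function(r, c) {
    out <- 0
    for (i in seq_len(k)) {
      out <- out + amp[i] *
        exp(-((r - ctr[i, 1])^2 + (c - ctr[i, 2])^2) / (2 * sd[i]^2))
    }
    out
  }
}

grid_coords <- function(shape) {
  cbind(rep(0:(shape[1] - 1), times = shape[2]),
        rep(0:(shape[2] - 1), each = shape[1]))
}

texture_image <- function(f, shape, xform = NULL, ...) {
  g <- grid_coords(shape)
  if (!is.null(xform)) g <- apply_affine(invert_affine(xform), g)
  channel_image(matrix(f(g[, 1], g[, 2]), shape[1], shape[2]), ...)
}

# A small gridded MSI dataset with a handful of peaks per pixel.
tiny_grid <- function(shape = c(4, 4), seed = 1, empty_pixel = NULL) {
  set.seed(seed)
  n <- prod(shape)
  mz <- vector("list", n)
  intensity <- vector("list", n)
  for (i in seq_len(n)) {
    np <- sample(1:5, 1)
    mz[[i]] <- sort(runif(np, 400, 900))
    intensity[[i]] <- runif(np, 1, 100)
  }
  if (!is.null(empty_pixel)) {
    mz[[empty_pixel]] <- numeric(0)
    intensity[[empty_pixel]] <- numeric(0)
  }
  msi_grid(mz, intensity, shape, pixel_size = 3.125, modality = "gcib_lipid")
}

# Two-disk protein images: disks touch, nuclei are separate, and a membrane
# ridge runs between the cell bodies.
touching_disks <- function(shape = c(64, 64), centers = rbind(c(31, 22),
                                                              c(31, 41)),
                           radius = 10) {
  rr <- 0:(shape[1] - 1)
  cc <- 0:(shape[2] - 1)
  nuclear <- matrix(0, shape[1], shape[2])
  membrane <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+"))
    nuclear <- nuclear + 100 / (1 + exp((d - 0.45 * radius) / 0.6))
    membrane <- membrane + 80 * exp(-((d - radius) / 1.2)^2)
  }
  list(nuclear = channel_image(nuclear, modality = "c60_protein"),
       membrane = channel_image(membrane, modality = "c60_protein"))
}

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Direct-formula Welch t statistic (independent of stats::t.test).
welch_t_oracle <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}
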