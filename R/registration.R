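# From-scratch 2D affine registration of the lipid modality (moving) onto the
# protein modality (fixed): mean-squared-difference metric, analytic gradient
# descent with backtracking, and a coarse-to-fine pyramid. The transform
# follows the pull-back convention used for resampling: it maps fixed-image
# pixel coordinates to moving-image pixel coordinates, so moving channels can
# be transformed into the fixed image space.

#' 2D affine transform
#'
#' Maps 0-based fixed-space pixel coordinates `(row, col)` to moving-space
#' coordinates: `y = linear %*% x + translation` (pull-back convention).
#'
#' @param linear 2x2 matrix (dimensionless).
#' @param translation Length-2 vector, in fixed-image pixels.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(linear = diag(2), translation = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) < 1e-12) stop("affine linear part is singular")
  structure(list(linear = linear, translation = as.numeric(translation)),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> fixed -> moving\n")
  cat(sprintf("  linear: [%.5f %.5f; %.5f %.5f]\n",
              x$linear[1, 1], x$linear[1, 2], x$linear[2, 1], x$linear[2, 2]))
  cat(sprintf("  translation: (%.3f, %.3f) px\n",
              x$translation[1], x$translation[2]))
  invisible(x)
}

#' Build an affine transform from shift, rotation and scale
#'
#' Convenience constructor: rotation (degrees) and isotropic scale about the
#' image center, plus a translation, expressed in the fixed -> moving
#' pull-back convention.
#'
#' @param shift Length-2 `(row, col)` shift in pixels.
#' @param rotation_deg Rotation angle in degrees.
#' @param scale Isotropic scale factor.
#' @param center Length-2 center of rotation, 0-based `(row, col)`.
#' @return An [affine2d()].
#' @export
affine_from_params <- function(shift = c(0, 0), rotation_deg = 0, scale = 1,
                               center = c(0, 0)) {
  th <- rotation_deg * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- as.numeric(center) + as.numeric(shift) - A %*% as.numeric(center)
  affine2d(A, as.numeric(b))
}

#' Apply an affine transform to coordinates
#'
#' @param t An [affine2d()].
#' @param coords 2-column matrix of 0-based `(row, col)` coordinates.
#' @return Transformed 2-column matrix.
#' @export
apply_affine <- function(t, coords) {
  coords <- matrix(as.numeric(coords), ncol = 2)
  sweep(coords %*% t(t$linear), 2, t$translation, "+")
}

#' Compose two affine transforms
#'
#' `compose_affine(t2, t1)` is the transform applying `t1` first:
#' `y = t2(t1(x))`.
#'
#' @param t2,t1 [affine2d()] objects.
#' @return The composed [affine2d()].
#' @export
compose_affine <- function(t2, t1) {
  affine2d(t2$linear %*% t1$linear,
           drop(t2$linear %*% t1$translation) + t2$translation)
}

#' Invert an affine transform
#' @param t An [affine2d()].
#' @return The inverse [affine2d()].
#' @export
invert_affine <- function(t) {
  Ainv <- solve(t$linear)
  affine2d(Ainv, drop(-Ainv %*% t$translation))
}

#' Mean corner displacement between two transforms
#'
#' Mean Euclidean distance between the images of the four fixed-image corners
#' under the two transforms; the standard registration-accuracy summary.
#'
#' @param t1,t2 [affine2d()] objects.
#' @param shape Fixed-image `c(rows, cols)`.
#' @return Mean displacement in pixels.
#' @export
corner_displacement <- function(t1, t2, shape) {
  corners <- rbind(c(0, 0), c(0, shape[2] - 1),
                   c(shape[1] - 1, 0), c(shape[1] - 1, shape[2] - 1))
  d <- apply_affine(t1, corners) - apply_affine(t2, corners)
  mean(sqrt(rowSums(d^2)))
}

#' Serialize an affine transform to JSON
#'
#' @param t An [affine2d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affine2d <- function(t, path) {
  jsonlite::write_json(
    list(linear = unclass(t$linear), translation = t$translation,
         convention = "fixed_to_moving", units = "pixels_fixed"),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read an affine transform from JSON
#' @param path JSON path written by [write_affine2d()].
#' @return An [affine2d()].
#' @export
read_affine2d <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$convention, "fixed_to_moving")) {
    stop("unsupported transform convention: ", x$convention)
  }
  lin <- if (is.matrix(x$linear)) x$linear
         else matrix(unlist(x$linear), 2, 2, byrow = TRUE)
  affine2d(lin, x$translation)
}

#' Normalize an image to the [0, 1] intensity range
#'
#' `(v - min) / (max - min)`; a constant image maps to all zeros.
#'
#' @param image A [channel_image()].
#' @return The normalized [channel_image()].
#' @export
normalize01 <- function(image) {
  v <- image$values
  rng <- range(v)
  image$values <- if (diff(rng) == 0) matrix(0, nrow(v), ncol(v))
                  else (v - rng[1]) / diff(rng)
  image
}

# Bilinear sampling of matrix `m` at 0-based coordinates (r, c); returns
# values and a validity flag (inside the image domain).
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  valid <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
  r <- pmin(pmax(r, 0), nr - 1)
  c <- pmin(pmax(c, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + 1 + c0 * nr  # column-major linear index of (r0, c0)
  v <- (1 - fr) * (1 - fc) * m[i00] +
    fr * (1 - fc) * m[i00 + 1] +
    (1 - fr) * fc * m[i00 + nr] +
    fr * fc * m[i00 + nr + 1]
  list(values = v, valid = valid)
}

#' Mean-squared-difference registration objective
#'
#' Mean over fixed-image pixels, whose pulled-back coordinate falls inside
#' the moving image, of the squared intensity difference between the fixed
#' pixel and the bilinearly interpolated moving image. If fewer than
#' `min_overlap` of the fixed pixels have valid pull-backs, a maximal
#' surrogate value is returned so the optimizer rejects the configuration.
#'
#' @param fixed,moving [channel_image()]s, normalized to `[0, 1]`.
#' @param t An [affine2d()] (fixed -> moving).
#' @param min_overlap Minimum valid fraction of fixed pixels (default 0.25).
#' @return Scalar objective (intensity squared).
#' @export
mse_objective <- function(fixed, moving, t, min_overlap = 0.25) {
  d <- dim(fixed$values)
  coords <- cbind(rep(0:(d[1] - 1), times = d[2]),
                  rep(0:(d[2] - 1), each = d[1]))
  y <- apply_affine(t, coords)
  s <- bilinear_sample(moving$values, y[, 1], y[, 2])
  if (mean(s$valid) < min_overlap) return(.Machine$double.xmax)
  mean((s$values[s$valid] - as.vector(fixed$values)[s$valid])^2)
}

block_downsample <- function(m, factor = 2L) {
  nr <- (nrow(m) %/% factor) * factor
  nc <- (ncol(m) %/% factor) * factor
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  # average factor x factor blocks
  m <- (m[seq(1, nr, by = factor), , drop = FALSE] +
        m[seq(2, nr, by = factor), , drop = FALSE]) / 2
  (m[, seq(1, nc, by = factor), drop = FALSE] +
   m[, seq(2, nc, by = factor), drop = FALSE]) / 2
}

central_gradient <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- m; gc <- m
  gr[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  gr[1, ] <- m[2, ] - m[1, ]; gr[nr, ] <- m[nr, ] - m[nr - 1, ]
  gc[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  gc[, 1] <- m[, 2] - m[, 1]; gc[, nc] <- m[, nc] - m[, nc - 1]
  list(gr = gr, gc = gc)
}

com_0based <- function(m) {
  tot <- sum(m)
  if (tot <= 0) return((dim(m) - 1) / 2)
  c(sum(rowSums(m) * (0:(nrow(m) - 1))), sum(colSums(m) * (0:(ncol(m) - 1)))) /
    tot
}

# One gradient-descent optimization at a single resolution. Parameters are
# the centered form y = A (x - cf) + cm + t; returns (A, t) plus the trace of
# accepted objective values.
gd_level <- function(fv, mv, A, t, max_iters, step_size, tol) {
  d <- dim(fv)
  cf <- (d - 1) / 2
  cm <- (dim(mv) - 1) / 2
  coords <- cbind(rep(0:(d[1] - 1), times = d[2]) - cf[1],
                  rep(0:(d[2] - 1), each = d[1]) - cf[2])
  fvec <- as.vector(fv)
  g <- central_gradient(mv)

  objective <- function(A, t) {
    y <- coords %*% t(A)
    y[, 1] <- y[, 1] + cm[1] + t[1]
    y[, 2] <- y[, 2] + cm[2] + t[2]
    s <- bilinear_sample(mv, y[, 1], y[, 2])
    if (mean(s$valid) < 0.25) return(list(value = .Machine$double.xmax))
    res <- s$values - fvec
    res[!s$valid] <- 0
    list(value = sum(res[s$valid]^2) / sum(s$valid), y = y, res = res,
         valid = s$valid)
  }
  # gradient of the objective in the 6 parameters, plus the diagonal of the
  # Gauss-Newton approximation used as a Jacobi preconditioner (a scaled
  # gradient step; descent direction, monotone under the line search)
  gradient <- function(ob) {
    sr <- bilinear_sample(g$gr, ob$y[, 1], ob$y[, 2])$values
    sc <- bilinear_sample(g$gc, ob$y[, 1], ob$y[, 2])$values
    sr[!ob$valid] <- 0; sc[!ob$valid] <- 0
    wr <- ob$res * sr; wc <- ob$res * sc
    n <- sum(ob$valid)
    grad <- (2 / n) * c(sum(wr * coords[, 1]), sum(wr * coords[, 2]),
                        sum(wc * coords[, 1]), sum(wc * coords[, 2]),
                        sum(wr), sum(wc))
    hdiag <- (2 / n) * c(sum((sr * coords[, 1])^2), sum((sr * coords[, 2])^2),
                         sum((sc * coords[, 1])^2), sum((sc * coords[, 2])^2),
                         sum(sr^2), sum(sc^2))
    hdiag <- pmax(hdiag, max(hdiag) * 1e-8, .Machine$double.eps)
    list(grad = grad, hdiag = hdiag)
  }

  trace <- numeric(0)
  ob <- objective(A, t)
  if (ob$value == .Machine$double.xmax) {
    stop("no usable overlap between images at initialization; ",
         "pre-align manually before registration")
  }
  trace <- ob$value
  eta <- step_size
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iters)) {
    iters <- it
    gr <- gradient(ob)
    dirn <- -gr$grad / gr$hdiag
    improved <- FALSE
    for (bt in 1:30) {
      p <- c(A[1, 1], A[1, 2], A[2, 1], A[2, 2], t) + eta * dirn
      A2 <- matrix(p[1:4], 2, 2, byrow = TRUE)
      t2 <- p[5:6]
      ob2 <- objective(A2, t2)
      if (ob2$value < ob$value) {
        improved <- TRUE
        rel <- (ob$value - ob2$value) / max(ob$value, .Machine$double.eps)
        A <- A2; t <- t2; ob <- ob2
        trace <- c(trace, ob$value)
        eta <- min(eta * 1.5, step_size * 4)
        if (rel < tol) converged <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!improved || converged) {
      converged <- converged || !improved
      break
    }
  }
  list(A = A, t = t, trace = trace, value = ob$value, iters = iters,
       converged = converged)
}

#' Register a moving image onto a fixed image with an affine transform
#'
#' Minimizes the mean squared intensity difference between the fixed image
#' and the affinely pulled-back moving image, by gradient descent on the six
#' affine parameters with backtracking line search (steps are accepted only
#' when the objective decreases). A coarse-to-fine pyramid (block-mean
#' downsampling by 2 per level) precedes full-resolution refinement, and the
#' translation is initialized from the intensity centers of mass. Both images
#' are normalized to `[0, 1]` internally. The method is deterministic.
#'
#' @param fixed,moving Single-[channel_image()]s; choose channels with
#'   tissue-representative morphology in both modalities.
#' @param pyramid_levels Number of resolution levels (default 3).
#' @param max_iters Maximum accepted-step iterations per level (default 200).
#' @param step_size Initial step along the preconditioned gradient
#'   direction (default 1).
#' @param tol Relative objective-decrease convergence threshold
#'   (default 1e-9).
#' @return An object of class `registration_result`: list with `transform`
#'   (an [affine2d()], fixed -> moving), `final_mse`, `n_iters`, `converged`,
#'   and `objective_trace` (list of per-level accepted-objective vectors,
#'   each non-increasing).
#' @export
register_affine <- function(fixed, moving, pyramid_levels = 3,
                            max_iters = 200, step_size = 1, tol = 1e-9) {
  stopifnot(pyramid_levels >= 1, tol > 0)
  # modalities sampled at different pixel sizes: bring the moving image onto
  # the fixed grid spacing (in physical um) first, and fold the scaling back
  # into the returned transform so it maps to original moving pixels
  prescale <- NULL
  if (!isTRUE(all.equal(fixed$pixel_size, moving$pixel_size))) {
    ratio <- fixed$pixel_size / moving$pixel_size
    prescale <- affine2d(diag(2) * ratio, c(0, 0))
    new_shape <- pmax(2L, ceiling(dim(moving$values) / ratio))
    moving <- resample_channels(moving, prescale, new_shape,
                                pixel_size = fixed$pixel_size)
  }
  f0 <- normalize01(fixed)$values
  m0 <- normalize01(moving)$values

  fpyr <- list(f0); mpyr <- list(m0)
  for (l in seq_len(pyramid_levels - 1)) {
    if (min(dim(fpyr[[l]])) < 32 || min(dim(mpyr[[l]])) < 32) break
    fpyr[[l + 1]] <- block_downsample(fpyr[[l]])
    mpyr[[l + 1]] <- block_downsample(mpyr[[l]])
  }
  nlev <- length(fpyr)

  # initialization at the coarsest level: identity linear part, translation
  # from centers of mass (centered parameterization)
  A <- diag(2)
  fc <- fpyr[[nlev]]; mc <- mpyr[[nlev]]
  t <- (com_0based(mc) - (dim(mc) - 1) / 2) -
       (com_0based(fc) - (dim(fc) - 1) / 2)

  traces <- vector("list", nlev)
  total_iters <- 0L
  converged <- TRUE
  value <- NA_real_
  for (l in nlev:1) {
    res <- gd_level(fpyr[[l]], mpyr[[l]], A, t,
                    max_iters = max_iters, step_size = step_size, tol = tol)
    A <- res$A; t <- res$t
    traces[[nlev - l + 1L]] <- res$trace
    total_iters <- total_iters + res$iters
    value <- res$value
    converged <- res$converged
    if (l > 1) t <- t * 2  # centered translation doubles at finer resolution
  }

  cf <- (dim(f0) - 1) / 2
  cm <- (dim(m0) - 1) / 2
  transform <- affine2d(A, drop(cm + t - A %*% cf))
  if (!is.null(prescale)) transform <- compose_affine(prescale, transform)
  structure(
    list(transform = transform, final_mse = value, n_iters = total_iters,
         converged = converged, objective_trace = traces),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> final MSE %.3g after %d iters%s\n",
              x$final_mse, x$n_iters,
              if (x$converged) " (converged)" else ""))
  print(x$transform)
  invisible(x)
}

#' Resample channels into the fixed image space
#'
#' Bilinearly interpolates each moving-modality channel at the pulled-back
#' coordinates `t(x)` for every fixed-image pixel `x`. Pixels whose pull-back
#' falls outside the moving image are set to zero and masked invalid. The
#' same transform is applied identically to every channel.
#'
#' @param channels A [channel_image()] or list of them (moving modality).
#' @param t An [affine2d()] (fixed -> moving).
#' @param fixed_shape Output `c(rows, cols)`.
#' @param pixel_size Pixel size of the fixed grid (default: keep each
#'   channel's own).
#' @return Channels resampled onto the fixed grid (same structure as input).
#' @export
resample_channels <- function(channels, t, fixed_shape, pixel_size = NULL) {
  one <- function(ch) {
    coords <- cbind(rep(0:(fixed_shape[1] - 1), times = fixed_shape[2]),
                    rep(0:(fixed_shape[2] - 1), each = fixed_shape[1]))
    y <- apply_affine(t, coords)
    s <- bilinear_sample(ch$values, y[, 1], y[, 2])
    v <- s$values
    v[!s$valid] <- 0
    channel_image(matrix(v, fixed_shape[1], fixed_shape[2]),
                  pixel_size = pixel_size %||% ch$pixel_size,
                  modality = ch$modality, channel = ch$channel,
                  window = ch$window,
                  mask = matrix(s$valid, fixed_shape[1], fixed_shape[2]))
  }
  if (inherits(channels, "channel_image")) return(one(channels))
  lapply(channels, one)
}
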