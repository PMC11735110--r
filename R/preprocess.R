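# Cross-sample reference-lipid normalization and ratiometric oxPE/PE images.

#' Estimate a cross-sample correction factor from a reference lipid
#'
#' Two MSI datasets acquired in separate runs differ by a global sensitivity
#' factor. A reference lipid assumed biologically invariant between samples
#' (here cholesterol sulfate) is imaged in both; its mean signal is measured
#' in `k` randomly placed square regions of the tissue in each image, and the
#' correction factor is the ratio of the two means. Multiplying sample B by
#' the factor brings it onto sample A's intensity scale.
#'
#' Tissue is defined per image from the reference channel itself, so regions
#' are not drawn from bare substrate: by default the Otsu foreground of the
#' reference image (`tissue_mask = "otsu"`), which also excludes the dim
#' tissue boundary; alternatively all pixels above a global intensity
#' quantile (`tissue_mask = "quantile"`).
#'
#' @param ref_a,ref_b Reference-lipid [channel_image()]s of samples A and B.
#' @param k Number of regions per image (default 13).
#' @param roi_size Region edge length in pixels (default 15).
#' @param seed Integer seed controlling region placement.
#' @param tissue_mask `"otsu"` (default) or `"quantile"`; how the tissue
#'   mask is derived from each reference image.
#' @param tissue_quantile Quantile used when `tissue_mask = "quantile"`.
#' @param method `"ratio_of_means"` (default; robust to near-zero regions) or
#'   `"mean_of_ratios"` (pairs the i-th region of each image).
#' @return An object of class `correction_factor`: list with `value`,
#'   `roi_means_a`, `roi_means_b`, `rois_a`, `rois_b`, `k`, `roi_size`,
#'   `seed`, `method`.
#' @export
estimate_correction_factor <- function(ref_a, ref_b, k = 13, roi_size = 15,
                                       seed = 1,
                                       tissue_mask = c("otsu", "quantile"),
                                       tissue_quantile = 0.25,
                                       method = c("ratio_of_means",
                                                  "mean_of_ratios")) {
  method <- match.arg(method)
  tissue_mask <- match.arg(tissue_mask)
  stopifnot(inherits(ref_a, "channel_image"), inherits(ref_b, "channel_image"))
  mask_of <- function(img) {
    v <- img$values
    if (diff(range(v)) == 0) return(matrix(TRUE, nrow(v), ncol(v)))
    # threshold a smoothed copy so shot noise cannot punch holes in the mask
    s <- EBImage::gblur(v, sigma = 2)
    if (tissue_mask == "otsu") s > otsu_threshold(as.vector(s))
    else s > stats::quantile(s, tissue_quantile)
  }
  rois_a <- sample_rois(ref_a, k = k, size = roi_size, seed = seed,
                        mask = mask_of(ref_a))
  rois_b <- sample_rois(ref_b, k = k, size = roi_size, seed = seed + 1L,
                        mask = mask_of(ref_b))
  means_a <- vapply(rois_a, function(r) roi_mean(ref_a, r), numeric(1))
  means_b <- vapply(rois_b, function(r) roi_mean(ref_b, r), numeric(1))
  value <- if (method == "ratio_of_means") {
    if (mean(means_b) <= 0) stop("reference signal in sample B has zero mean")
    mean(means_a) / mean(means_b)
  } else {
    if (any(means_b <= 0)) stop("zero reference signal in a sample B region")
    mean(means_a / means_b)
  }
  structure(list(value = value, roi_means_a = means_a, roi_means_b = means_b,
                 rois_a = rois_a, rois_b = rois_b, k = k, roi_size = roi_size,
                 seed = seed, method = method),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor> %.4g (%s, %d regions of %dx%d px)\n",
              x$value, x$method, x$k, x$roi_size, x$roi_size))
  invisible(x)
}

#' Apply a correction factor to a set of channels
#'
#' Multiplies every pixel of every channel by the factor; masks are
#' unchanged.
#'
#' @param channels A [channel_image()] or list of them.
#' @param factor A [estimate_correction_factor()] result or a positive
#'   scalar.
#' @return Channels with scaled intensities (same structure as the input).
#' @export
apply_correction <- function(channels, factor) {
  value <- if (inherits(factor, "correction_factor")) factor$value else factor
  if (!is.numeric(value) || value <= 0) stop("correction factor must be > 0")
  scale_one <- function(ch) {
    ch$values <- ch$values * value
    ch
  }
  if (inherits(channels, "channel_image")) return(scale_one(channels))
  lapply(channels, scale_one)
}

#' Ratiometric oxidized/precursor lipid image
#'
#' Computes the pixelwise ratio of an oxidized-lipid channel to its
#' non-oxidized precursor, scaled by `scale_factor` (default 5). Pixels where
#' the precursor is zero are masked out (`zero_policy = "mask"`) or set to
#' zero (`"zero"`). Analysis values stay floating point; the optional
#' bit-depth quantization is a rendering step applied only on export via
#' [quantize_channel()].
#'
#' @param ox Oxidized-species [channel_image()].
#' @param precursor Precursor-species [channel_image()]; same shape and
#'   modality, co-registered.
#' @param scale_factor Multiplicative display scaling (default 5).
#' @param zero_policy `"mask"` or `"zero"`.
#' @return A [channel_image()] of scaled ratios.
#' @export
ratiometric_image <- function(ox, precursor, scale_factor = 5,
                              zero_policy = c("mask", "zero")) {
  zero_policy <- match.arg(zero_policy)
  check_compatible(ox, precursor)
  if (scale_factor <= 0) stop("scale_factor must be positive")
  zero <- precursor$values == 0
  vals <- matrix(0, nrow(ox$values), ncol(ox$values))
  vals[!zero] <- scale_factor * ox$values[!zero] / precursor$values[!zero]
  mask <- ox$mask
  if (zero_policy == "mask") {
    mask <- if (is.null(mask)) !zero else mask & !zero
  }
  channel_image(vals, pixel_size = ox$pixel_size, modality = ox$modality,
                channel = paste0(ox$channel %||% "ox", "/",
                                 precursor$channel %||% "precursor"),
                mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantize a channel image for export
#'
#' Linearly rescales to `[0, 2^bit_depth - 1]` and rounds to integers, the
#' rendering convention for grayscale ratio images. Masked pixels map to 0.
#'
#' @param image A [channel_image()].
#' @param bit_depth 8, 12 or 16.
#' @return An integer matrix.
#' @export
quantize_channel <- function(image, bit_depth = 12) {
  if (!bit_depth %in% c(8, 12, 16)) stop("bit_depth must be 8, 12 or 16")
  v <- image$values
  if (!is.null(image$mask)) v[!image$mask] <- 0
  top <- 2^bit_depth - 1
  rng <- range(v)
  out <- if (diff(rng) == 0) matrix(0L, nrow(v), ncol(v))
         else matrix(as.integer(round((v - rng[1]) / diff(rng) * top)),
                     nrow(v), ncol(v))
  out
}
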