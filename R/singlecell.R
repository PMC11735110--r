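# Single-cell quantification: watershed segmentation from nuclear + membrane
# channels, per-cell channel integration, marker-threshold typing,
# hierarchical clustering, group statistics, and PLS-DA VIP scores.

#' Label map
#'
#' Integer segmentation image: 0 = background, 1..K = cells.
#'
#' @param labels Integer matrix of non-negative labels.
#' @param pixel_size Pixel size in micrometers.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, pixel_size = 1) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be non-negative")
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %dx%d px, %d cells\n", nrow(x$labels),
              ncol(x$labels), n_cells(x)))
  invisible(x)
}

#' Number of cells in a label map
#' @param labels A [label_map()].
#' @return Count of distinct non-zero labels.
#' @export
n_cells <- function(labels) {
  length(setdiff(unique(as.vector(labels$labels)), 0L))
}

#' Segment single cells from nuclear and membrane channels
#'
#' Deterministic seeded-watershed segmentation: the nuclear channel is
#' Gaussian-smoothed and Otsu-thresholded; watershed on the distance
#' transform of the nuclear mask yields one seed per nucleus (splitting
#' touching nuclei); seeds are then grown over a cell mask by Voronoi
#' propagation weighted by the membrane channel, so boundaries settle on
#' membrane ridges. Labels are filtered by area and renumbered in raster
#' order of their centroids.
#'
#' An externally produced segmentation (e.g. from a learned model) can be
#' used instead by constructing a [label_map()] directly and passing it to
#' [integrate_cells()].
#'
#' @param nuclear,membrane [channel_image()]s of the same shape and modality.
#' @param sigma Gaussian smoothing radius in pixels (default 2).
#' @param min_area,max_area Cell area bounds in pixels.
#' @param seed_tolerance Watershed tolerance for seed splitting (default 1).
#' @param lambda Propagation weight between image gradient and Euclidean
#'   distance (default 1e-4; see [EBImage::propagate()]).
#' @return A [label_map()].
#' @export
segment_cells <- function(nuclear, membrane, sigma = 2, min_area = 20,
                          max_area = Inf, seed_tolerance = 1, lambda = 1e-4) {
  check_compatible(nuclear, membrane)
  if (diff(range(nuclear$values)) == 0) {
    warning("blank nuclear channel; returning an empty segmentation")
    return(label_map(matrix(0L, nrow(nuclear$values), ncol(nuclear$values)),
                     pixel_size = nuclear$pixel_size))
  }
  smooth01 <- function(v) {
    s <- EBImage::gblur(v, sigma = sigma)
    rng <- range(s)
    if (diff(rng) == 0) matrix(0, nrow(v), ncol(v))
    else (s - rng[1]) / diff(rng)
  }
  nuc <- smooth01(nuclear$values)
  nucmask <- nuc > EBImage::otsu(EBImage::Image(nuc))
  if (!any(nucmask)) {
    warning("no nuclei above threshold; returning an empty segmentation")
    return(label_map(matrix(0L, nrow(nuc), ncol(nuc)),
                     pixel_size = nuclear$pixel_size))
  }
  dm <- EBImage::distmap(nucmask)
  seeds <- EBImage::watershed(dm, tolerance = seed_tolerance)

  mem <- smooth01(membrane$values)
  body <- smooth01(nuclear$values + membrane$values)
  cellmask <- (body > EBImage::otsu(EBImage::Image(body))) | nucmask
  labels <- EBImage::propagate(EBImage::Image(mem), seeds = seeds,
                               mask = cellmask, lambda = lambda)
  labels <- matrix(as.integer(labels), nrow(nuc), ncol(nuc))

  # area filter + deterministic renumbering in raster order of centroids
  tab <- table(labels[labels > 0])
  keep <- as.integer(names(tab))[tab >= min_area & tab <= max_area]
  labels[!(labels %in% keep)] <- 0L
  if (length(keep) > 0) {
    idx <- which(labels > 0)
    rows <- (idx - 1L) %% nrow(labels)
    cols <- (idx - 1L) %/% nrow(labels)
    cr <- tapply(rows, labels[idx], mean)
    cc <- tapply(cols, labels[idx], mean)
    ord <- order(cr, cc)
    remap <- integer(max(keep))
    remap[as.integer(names(cr))[ord]] <- seq_along(ord)
    labels[idx] <- remap[labels[idx]]
  }
  label_map(labels, pixel_size = nuclear$pixel_size)
}

#' Integrate channel intensities per segmented cell
#'
#' For every cell, sums each channel over the cell's pixels — an exact
#' partition of the labeled pixels, so per-channel totals over all cells
#' equal the channel total over labeled pixels.
#'
#' @param labels A [label_map()].
#' @param channels Named list of [channel_image()]s co-registered with the
#'   label map's image space (mixed modalities are expected here: protein
#'   channels natively, lipid channels after resampling).
#' @return A data.frame with one row per cell: `cell_id`, `centroid_row`,
#'   `centroid_col` (0-based), `area` (pixels), and one column per channel.
#' @export
integrate_cells <- function(labels, channels) {
  stopifnot(inherits(labels, "label_map"))
  if (inherits(channels, "channel_image")) channels <- list(channels)
  nms <- names(channels)
  if (is.null(nms) || any(nms == "")) {
    nms <- vapply(seq_along(channels), function(i) {
      channels[[i]]$channel %||% paste0("channel", i)
    }, character(1))
  }
  lm <- labels$labels
  for (ch in channels) {
    if (!all(dim(ch$values) == dim(lm))) {
      stop("channel shape does not match the label map")
    }
  }
  ids <- setdiff(sort(unique(as.vector(lm))), 0L)
  if (length(ids) == 0L) {
    out <- data.frame(cell_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area = integer(0))
    for (nm in nms) out[[nm]] <- numeric(0)
    return(out)
  }
  idx <- which(lm > 0)
  f <- factor(lm[idx], levels = ids)
  rows <- (idx - 1L) %% nrow(lm)
  cols <- (idx - 1L) %/% nrow(lm)
  out <- data.frame(
    cell_id = ids,
    centroid_row = as.numeric(tapply(rows, f, mean)),
    centroid_col = as.numeric(tapply(cols, f, mean)),
    area = as.integer(table(f))
  )
  for (i in seq_along(channels)) {
    v <- channels[[i]]$values[idx]
    out[[nms[i]]] <- as.numeric(rowsum(v, f))
  }
  rownames(out) <- NULL
  out
}

#' Cell-type classification rule
#'
#' A single marker-threshold rule. Rules are applied in precedence order by
#' [classify_cells()]: the first rule whose condition a cell satisfies
#' assigns its type.
#'
#' @param type Type label assigned when the rule matches (e.g. `"K14+"`).
#' @param marker Channel column name the rule tests.
#' @param comparator `">="` or `"<"`.
#' @param threshold Numeric threshold, or one of `"auto"` (use the
#'   classifier's default auto method), `"otsu"` (bimodal split; right for
#'   markers with positive and negative populations, like K14),
#'   `"half_median"` (half the population median; right for markers
#'   expressed by essentially the whole population, like panCK, where a
#'   bimodal split is meaningless), or `"quantile"`.
#' @return An object of class `cell_type_rule`.
#' @export
cell_type_rule <- function(type, marker, comparator = ">=",
                           threshold = "auto") {
  comparator <- match.arg(comparator, c(">=", "<"))
  structure(list(type = type, marker = marker, comparator = comparator,
                 threshold = threshold),
            class = "cell_type_rule")
}

# 1D Otsu threshold of a numeric vector (maximal between-class variance over
# a 256-bin histogram).
otsu_threshold <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w1 <- cumsum(h)
  mu1 <- cumsum(h * mids)
  total <- w1[nbins]
  mu_t <- mu1[nbins]
  w2 <- total - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, nbins)
  between[valid] <- (mu_t * w1[valid] - total * mu1[valid])^2 /
    (w1[valid] * w2[valid])
  breaks[which.max(between) + 1L]
}

#' Assign cell types from integrated marker signals
#'
#' Applies threshold rules in precedence order to the per-cell integrated
#' protein signals; cells matching no rule are `"unassigned"`. `"auto"`
#' thresholds are computed per marker from the whole cell population.
#'
#' @param records Cell table from [integrate_cells()].
#' @param rules List of [cell_type_rule()]s in precedence order.
#' @param auto_threshold `"otsu"` or `"quantile"` for rules with
#'   `threshold = "auto"`.
#' @param auto_quantile Quantile used when `auto_threshold = "quantile"`.
#' @param normalize_area Divide marker signals by cell area before
#'   thresholding (default TRUE: thresholds on mean intensity, insensitive
#'   to cell size).
#' @return `records` with a `cell_type` column; the applied thresholds are
#'   attached as attribute `"thresholds"`.
#' @export
classify_cells <- function(records, rules,
                           auto_threshold = c("otsu", "quantile"),
                           auto_quantile = 0.5, normalize_area = TRUE) {
  auto_threshold <- match.arg(auto_threshold)
  stopifnot(is.data.frame(records))
  markers <- vapply(rules, function(r) r$marker, character(1))
  missing <- setdiff(markers, names(records))
  if (length(missing) > 0) {
    stop("marker channel(s) absent from records: ",
         paste(missing, collapse = ", "))
  }
  records$cell_type <- rep("unassigned", nrow(records))
  if (nrow(records) == 0L) return(records)
  signal <- function(marker) {
    v <- records[[marker]]
    if (normalize_area) v / records$area else v
  }
  thresholds <- numeric(length(rules))
  assigned <- rep(FALSE, nrow(records))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    v <- signal(r$marker)
    method <- if (is.character(r$threshold)) {
      if (identical(r$threshold, "auto")) auto_threshold else r$threshold
    } else NULL
    th <- if (is.null(method)) r$threshold
    else switch(method,
      otsu = otsu_threshold(v),
      quantile = stats::quantile(v, auto_quantile),
      half_median = stats::median(v) / 2,
      stop("unknown threshold method: ", method))
    thresholds[i] <- th
    hit <- if (r$comparator == ">=") v >= th else v < th
    sel <- hit & !assigned
    records$cell_type[sel] <- r$type
    assigned <- assigned | hit
  }
  names(thresholds) <- vapply(rules, function(r) {
    paste0(r$type, ":", r$marker)
  }, character(1))
  attr(records, "thresholds") <- thresholds
  records
}

#' Hierarchical clustering of per-cell lipid profiles
#'
#' Agglomerative clustering of cells on z-scored channel variables.
#'
#' @param records Cell table from [integrate_cells()].
#' @param variables Channel column names to cluster on.
#' @param k Optional number of clusters to cut the tree at.
#' @param linkage Agglomeration method (default `"ward.D2"`).
#' @param metric Distance metric (default `"euclidean"`).
#' @param normalize_area Divide channel signals by cell area first.
#' @return List with `tree` (an [stats::hclust()] object), `assignments`
#'   (integer vector when `k` given, else `NULL`), `variables`, and the
#'   z-scored matrix `scaled`.
#' @export
cluster_cells <- function(records, variables, k = NULL, linkage = "ward.D2",
                          metric = "euclidean", normalize_area = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L) stop("clustering needs at least 2 cells")
  missing <- setdiff(variables, names(records))
  if (length(missing) > 0) {
    stop("variable(s) absent from records: ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(records[, variables, drop = FALSE])
  if (normalize_area) X <- X / records$area
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0  # constant variables carry no info
  tree <- stats::hclust(stats::dist(Xs, method = metric), method = linkage)
  assignments <- if (!is.null(k)) unname(stats::cutree(tree, k = k)) else NULL
  list(tree = tree, assignments = assignments, variables = variables,
       scaled = Xs)
}

#' Compare a channel between two cell types
#'
#' Two-sided Welch t test on per-cell integrated signals of one channel
#' between two cell-type groups, with group means and standard deviations.
#'
#' @param records Classified cell table (needs a `cell_type` column).
#' @param channel Channel column to compare.
#' @param type_a,type_b Cell-type labels of the two groups.
#' @param normalize_area Divide the channel by cell area before testing.
#' @return An object of class `group_comparison`: list with `channel`,
#'   `type_a`, `type_b`, `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`,
#'   `fold_change` (a over b), `t_statistic`, `p_value`.
#' @export
compare_celltypes <- function(records, channel, type_a, type_b,
                              normalize_area = FALSE) {
  stopifnot(is.data.frame(records), "cell_type" %in% names(records))
  v <- records[[channel]]
  if (normalize_area) v <- v / records$area
  a <- v[records$cell_type == type_a]
  b <- v[records$cell_type == type_b]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 cells (", type_a, ": ", length(a),
         ", ", type_b, ": ", length(b), ")")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  }
  structure(
    list(channel = channel, type_a = type_a, type_b = type_b,
         mean_a = mean(a), mean_b = mean(b),
         sd_a = stats::sd(a), sd_b = stats::sd(b),
         n_a = length(a), n_b = length(b),
         fold_change = mean(a) / mean(b),
         t_statistic = unname(tt$statistic), p_value = tt$p.value),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: %s %.4g +/- %.3g (n=%d) vs %s %.4g +/- %.3g (n=%d)\n",
    x$channel, x$type_a, x$mean_a, x$sd_a, x$n_a,
    x$type_b, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  fold change %.3g, Welch t = %.3g, two-sided p = %.3g\n",
              x$fold_change, x$t_statistic, x$p_value))
  invisible(x)
}

#' PLS-DA with variable importance in projection (VIP)
#'
#' Two-class partial least squares discriminant analysis fitted by NIPALS on
#' the (optionally autoscaled) variable matrix against a centered 0/1 class
#' response, with the standard VIP score per variable:
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)`, where
#' `SSY_a` is the response variance explained by component `a`. VIP scores
#' satisfy `mean(VIP^2) = 1`; variables with VIP > 1 are conventionally
#' called influential.
#'
#' @param X Numeric matrix, cells x variables.
#' @param y Binary group labels (factor, character or two-valued vector).
#' @param n_components Number of PLS components (default 2).
#' @param scale Autoscale the columns of `X` (default TRUE).
#' @return An object of class `vip_result`: list with `scores` (named VIP
#'   vector), `n_components`, `weights`, `x_scores`, `y_loadings`,
#'   `explained_ssy`.
#' @export
plsda_vip <- function(X, y, n_components = 2, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  grp <- as.factor(y)
  if (nlevels(grp) != 2L) {
    stop("plsda_vip needs exactly 2 classes, got ", nlevels(grp))
  }
  yc <- as.numeric(grp == levels(grp)[2])
  yc <- yc - mean(yc)
  Xs <- scale(X, center = TRUE, scale = scale)
  if (scale && any(attr(Xs, "scaled:scale") == 0)) {
    Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  }
  p <- ncol(Xs)
  A <- min(n_components, p, nrow(Xs) - 1L)
  W <- matrix(0, p, A)
  TT <- matrix(0, nrow(Xs), A)
  Q <- numeric(A)
  ssy <- numeric(A)
  Xa <- Xs
  ya <- yc
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      A <- a - 1L
      break
    }
    w <- w / nw
    tt <- drop(Xa %*% w)
    pl <- drop(crossprod(Xa, tt)) / sum(tt^2)
    q <- sum(ya * tt) / sum(tt^2)
    Xa <- Xa - tcrossprod(tt, pl)
    ya <- ya - q * tt
    W[, a] <- w
    TT[, a] <- tt
    Q[a] <- q
    ssy[a] <- q^2 * sum(tt^2)
  }
  if (A < 1L) stop("no usable PLS component (response unrelated to X?)")
  W <- W[, seq_len(A), drop = FALSE]
  TT <- TT[, seq_len(A), drop = FALSE]
  ssy <- ssy[seq_len(A)]
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(X)
  structure(
    list(scores = vip, n_components = A, weights = W, x_scores = TT,
         y_loadings = Q[seq_len(A)], explained_ssy = ssy),
    class = "vip_result"
  )
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("<vip_result> %d components; top variables:\n", x$n_components))
  top <- sort(x$scores, decreasing = TRUE)[seq_len(min(5, length(x$scores)))]
  for (nm in names(top)) cat(sprintf("  %-20s VIP = %.3f\n", nm, top[[nm]]))
  invisible(x)
}
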