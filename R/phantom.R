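# Synthetic dual-modality tissue phantoms with known ground truth: cell
# geometry and types, per-cell lipid abundances, a known affine misalignment
# between the protein (fixed) and lipid (moving) modalities, a known
# cross-sample sensitivity factor, and Poisson counting noise. Everything the
# pipeline estimates downstream is therefore checkable against truth.

#' Phantom specification
#'
#' Study conditions for the synthetic tissue phantom. The defaults emulate a
#' skin-epidermis section imaged by a protein modality (nuclear, membrane,
#' panCK, K14 channels on the fixed grid) and a lipid modality (PE, oxPE and
#' cholesterol-sulfate channels on a misaligned moving grid): round cells
#' with soft edges, a K14+ basal subpopulation among panCK+ keratinocytes, a
#' type- and condition-independent cholesterol-sulfate reference rendered
#' over the whole tissue plateau, per-cell log-normal lipid abundances,
#' 3-fold oxPE enrichment in K14+ cells of the lesional condition, a lipid
#' modality sensitivity of 1/8.6 in the lesional sample (so the estimated
#' correction factor should recover 8.6), and Poisson noise on expected
#' counts.
#'
#' @param image_shape Image `c(rows, cols)` in pixels.
#' @param n_cells Number of cells to place (non-overlapping).
#' @param cell_radius `c(min, max)` cell radius in pixels.
#' @param type_fractions Named fractions for `"K14+"` and `"panCK+K14-"`.
#' @param marker_model Named list per type: per-pixel mean intensities of
#'   `nuclear`, `membrane`, `panCK`, `K14`.
#' @param lipid_model Named list per species: `median` per-pixel expected
#'   count and log-normal `sigma` of the per-cell abundance multiplier.
#'   `"CholS"` is the reference species, rendered type-independently over
#'   the tissue plateau.
#' @param enrichment Multiplier on oxPE species in K14+ cells of the
#'   lesional condition (default 3).
#' @param sensitivity_factor Global gain of the lipid modality in the
#'   lesional condition (default 1/8.6).
#' @param misalignment An [affine2d()] mapping fixed to moving coordinates
#'   (the ground-truth transform registration must recover), or `NULL` for
#'   the default mild misalignment.
#' @param noise `"poisson"` (counting detector) or `"none"`.
#' @param background Expected background counts per pixel in lipid channels.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(256, 256),
                         n_cells = 100,
                         cell_radius = c(4, 7),
                         type_fractions = c("K14+" = 0.3, "panCK+K14-" = 0.7),
                         marker_model = NULL,
                         lipid_model = NULL,
                         enrichment = 3,
                         sensitivity_factor = 1 / 8.6,
                         misalignment = NULL,
                         noise = c("poisson", "none"),
                         background = 0) {
  noise <- match.arg(noise)
  if (abs(sum(type_fractions) - 1) > 1e-8) {
    stop("type fractions must sum to 1")
  }
  if (cell_radius[1] < 2) stop("minimum cell radius must be >= 2 px")
  if (is.null(marker_model)) {
    marker_model <- list(
      "K14+" = c(nuclear = 100, membrane = 80, panCK = 120, K14 = 150),
      "panCK+K14-" = c(nuclear = 100, membrane = 80, panCK = 120, K14 = 6)
    )
  }
  if (is.null(lipid_model)) {
    lipid_model <- list(
      "PE(40:4)" = list(median = 60, sigma = 0.3, oxidized = FALSE),
      "PE(40:4)+2O" = list(median = 12, sigma = 0.3, oxidized = TRUE),
      "PE(38:4)+2O" = list(median = 10, sigma = 0.3, oxidized = TRUE),
      "CholS" = list(median = 80, sigma = 0.1, oxidized = FALSE)
    )
  }
  if (any(vapply(lipid_model, function(m) m$median <= 0, logical(1)))) {
    stop("lipid medians must be positive")
  }
  if (is.null(misalignment)) {
    misalignment <- affine_from_params(shift = c(4.0, -3.0),
                                       rotation_deg = 2, scale = 1.01,
                                       center = (image_shape - 1) / 2)
  }
  structure(
    list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
         cell_radius = cell_radius, type_fractions = type_fractions,
         marker_model = marker_model, lipid_model = lipid_model,
         enrichment = enrichment, sensitivity_factor = sensitivity_factor,
         misalignment = misalignment, noise = noise, background = background),
    class = "phantom_spec"
  )
}

# Place n non-overlapping disks by rejection sampling inside the tissue
# plateau. Returns a data.frame (row, col, radius) in 0-based coordinates.
place_cells <- function(spec, seed) {
  d <- spec$image_shape
  center <- (d - 1) / 2
  rmax_tissue <- 0.40 * min(d)
  n <- spec$n_cells
  if (n == 0) {
    return(data.frame(row = numeric(0), col = numeric(0), radius = numeric(0)))
  }
  with_seed(seed, {
    rows <- numeric(n); cols <- numeric(n); rads <- numeric(n)
    placed <- 0L
    tries <- 0L
    max_tries <- 2000L * n
    while (placed < n && tries < max_tries) {
      tries <- tries + 1L
      rad <- stats::runif(1, spec$cell_radius[1], spec$cell_radius[2])
      # uniform position in the tissue disk, keeping the cell inside it
      ang <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * (rmax_tissue - rad - 2)
      pr <- center[1] + rr * cos(ang)
      pc <- center[2] + rr * sin(ang)
      if (placed > 0) {
        dd <- sqrt((rows[1:placed] - pr)^2 + (cols[1:placed] - pc)^2)
        if (any(dd < rads[1:placed] + rad + 2)) next
      }
      placed <- placed + 1L
      rows[placed] <- pr; cols[placed] <- pc; rads[placed] <- rad
    }
    if (placed < n) {
      stop("could not place ", n, " non-overlapping cells after ", max_tries,
           " attempts; reduce n_cells or cell_radius")
    }
    cells <- data.frame(row = rows, col = cols, radius = rads)
    cells[order(cells$row, cells$col), , drop = FALSE]
  })
}

# Evaluate a cell-based scene on a pixel grid. `profile` maps distance from
# the cell center and the cell radius to a weight in [0, 1]. When `xform` is
# given the scene is rendered in the moving grid: a moving pixel y shows the
# fixed-space scene at x = xform^{-1}(y).
render_scene <- function(shape, cells, amplitudes, profile, xform = NULL,
                         pad = 4) {
  out <- matrix(0, shape[1], shape[2])
  if (nrow(cells) == 0) return(out)
  tinv <- if (!is.null(xform)) invert_affine(xform)
  smax <- if (!is.null(xform)) {
    sqrt(max(eigen(crossprod(xform$linear), only.values = TRUE)$values))
  } else 1
  for (i in seq_len(nrow(cells))) {
    ci <- c(cells$row[i], cells$col[i])
    rad <- cells$radius[i]
    cg <- if (is.null(xform)) ci else drop(apply_affine(xform, rbind(ci)))
    ext <- (rad + pad) * smax
    r0 <- max(0L, floor(cg[1] - ext)); r1 <- min(shape[1] - 1L, ceiling(cg[1] + ext))
    c0 <- max(0L, floor(cg[2] - ext)); c1 <- min(shape[2] - 1L, ceiling(cg[2] + ext))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    if (is.null(xform)) {
      d <- sqrt(outer((rr - ci[1])^2, (cc - ci[2])^2, "+"))
    } else {
      grid <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
      x <- apply_affine(tinv, grid)
      d <- matrix(sqrt((x[, 1] - ci[1])^2 + (x[, 2] - ci[2])^2),
                  length(rr), length(cc))
    }
    out[rr + 1L, cc + 1L] <- out[rr + 1L, cc + 1L] +
      amplitudes[i] * profile(d, rad)
  }
  out
}

profile_disk <- function(edge = 0.8) {
  function(d, radius) 1 / (1 + exp((d - radius) / edge))
}
profile_nucleus <- function(frac = 0.45, edge = 0.6) {
  function(d, radius) 1 / (1 + exp((d - frac * radius) / edge))
}
profile_membrane <- function(width = 1.2) {
  function(d, radius) exp(-((d - radius) / width)^2)
}

# Soft tissue plateau (the "epidermis" region carrying the reference lipid).
tissue_plateau <- function(shape, xform = NULL, edge = 4) {
  center <- (shape - 1) / 2
  rad <- 0.42 * min(shape)
  rr <- 0:(shape[1] - 1); cc <- 0:(shape[2] - 1)
  if (is.null(xform)) {
    d <- sqrt(outer((rr - center[1])^2, (cc - center[2])^2, "+"))
  } else {
    tinv <- invert_affine(xform)
    grid <- cbind(rep(rr, times = shape[2]), rep(cc, each = shape[1]))
    x <- apply_affine(tinv, grid)
    d <- matrix(sqrt((x[, 1] - center[1])^2 + (x[, 2] - center[2])^2),
                shape[1], shape[2])
  }
  1 / (1 + exp((d - rad) / edge))
}

#' Generate a dual-modality tissue phantom
#'
#' Renders one synthetic tissue section in both modalities with full ground
#' truth. Protein channels live on the fixed grid; lipid channels are the
#' same scene observed through the ground-truth affine misalignment and, in
#' the lesional condition, scaled by the sensitivity factor — Poisson noise
#' is applied last. The same seed gives bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param condition `"control"` or `"lesional"`. The lesional condition gets
#'   the oxPE enrichment in K14+ cells and the lipid-modality sensitivity
#'   factor.
#' @param seed Integer seed; all stage randomness (geometry, types,
#'   abundances, noise) derives from it.
#' @return A list with `protein` (named list of fixed-grid
#'   [channel_image()]s: nuclear, membrane, panCK, K14), `lipid` (named list
#'   of moving-grid channels: the species in `spec$lipid_model`), and
#'   `truth` (class `phantom_truth`): `label_map`, `cells` (0-based centers,
#'   radii, `cell_type`), `cell_types`, `true_transform` (fixed -> moving),
#'   `true_abundances` (per cell x species expected totals, fixed space,
#'   before sensitivity scaling), `true_factor` (factor that multiplies this
#'   sample's lipid data onto the control scale), `condition`, `seed`.
#' @export
generate_phantom <- function(spec = phantom_spec(),
                             condition = c("control", "lesional"),
                             seed = 1) {
  condition <- match.arg(condition)
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$image_shape
  cells <- place_cells(spec, seed)
  n <- nrow(cells)
  types <- if (n > 0) {
    with_seed(seed + 1L, sample(names(spec$type_fractions), n, replace = TRUE,
                                prob = spec$type_fractions))
  } else character(0)

  sens <- if (condition == "lesional") spec$sensitivity_factor else 1
  tfm <- spec$misalignment

  # protein channels (fixed grid)
  protein <- list()
  marker_amp <- function(marker) {
    if (n == 0) return(numeric(0))
    vapply(types, function(tp) spec$marker_model[[tp]][[marker]], numeric(1))
  }
  protein$nuclear <- render_scene(d, cells, marker_amp("nuclear"),
                                  profile_nucleus())
  protein$membrane <- render_scene(d, cells, marker_amp("membrane"),
                                   profile_membrane())
  protein$panCK <- render_scene(d, cells, marker_amp("panCK"), profile_disk())
  protein$K14 <- render_scene(d, cells, marker_amp("K14"), profile_disk())

  # per-cell lipid densities (log-normal multipliers around the per-type
  # median; oxidized species get the enrichment in lesional K14+ cells)
  species <- names(spec$lipid_model)
  dens <- matrix(0, max(n, 0), length(species),
                 dimnames = list(NULL, species))
  if (n > 0) {
    mult <- with_seed(seed + 2L, {
      matrix(stats::rlnorm(n * length(species), meanlog = 0,
                           sdlog = vapply(spec$lipid_model,
                                          function(m) m$sigma, numeric(1))[
                             rep(seq_along(species), each = n)]),
             n, length(species))
    })
    for (j in seq_along(species)) {
      m <- spec$lipid_model[[j]]
      base <- m$median
      enr <- if (isTRUE(m$oxidized) && condition == "lesional") {
        ifelse(types == "K14+", spec$enrichment, 1)
      } else rep(1, n)
      dens[, j] <- base * mult[, j] * enr
    }
    # the reference species is deliberately type- and condition-independent
    if ("CholS" %in% species) dens[, "CholS"] <- 0
  }

  disk <- profile_disk()
  lipid <- list()
  for (j in seq_along(species)) {
    sp <- species[j]
    if (sp == "CholS") {
      scene <- spec$lipid_model[[sp]]$median * tissue_plateau(d, xform = tfm)
    } else {
      scene <- render_scene(d, cells, dens[, j], disk, xform = tfm)
      scene <- scene + spec$background
    }
    lam <- sens * scene
    vals <- if (spec$noise == "poisson") {
      with_seed(seed + 10L + j,
                matrix(stats::rpois(length(lam), lam), d[1], d[2]))
    } else lam
    lipid[[sp]] <- channel_image(vals, pixel_size = 1,
                                 modality = "gcib_lipid", channel = sp)
  }

  protein <- lapply(stats::setNames(names(protein), names(protein)),
                    function(nm) {
    lam <- protein[[nm]]
    vals <- if (spec$noise == "poisson") {
      with_seed(seed + 20L + match(nm, c("nuclear", "membrane", "panCK",
                                         "K14")),
                matrix(stats::rpois(length(lam), lam), d[1], d[2]))
    } else lam
    channel_image(vals, pixel_size = 1, modality = "c60_protein",
                  channel = nm)
  })

  # ground truth: hard-disk label map on the fixed grid and expected totals
  lm <- matrix(0L, d[1], d[2])
  true_ab <- matrix(0, max(n, 0), length(species),
                    dimnames = list(NULL, species))
  if (n > 0) {
    for (i in seq_len(n)) {
      ci <- c(cells$row[i], cells$col[i]); rad <- cells$radius[i]
      r0 <- max(0L, floor(ci[1] - rad)); r1 <- min(d[1] - 1L, ceiling(ci[1] + rad))
      c0 <- max(0L, floor(ci[2] - rad)); c1 <- min(d[2] - 1L, ceiling(ci[2] + rad))
      rr <- r0:r1; cc <- c0:c1
      dist <- sqrt(outer((rr - ci[1])^2, (cc - ci[2])^2, "+"))
      block <- lm[rr + 1L, cc + 1L]
      block[dist <= rad] <- i
      lm[rr + 1L, cc + 1L] <- block
      # expected fixed-space totals: density x soft-disk footprint
      w <- disk(dist, rad)
      for (j in seq_along(species)) {
        if (species[j] == "CholS") next
        true_ab[i, j] <- dens[i, j] * sum(w)
      }
    }
  }
  truth <- structure(
    list(label_map = label_map(lm, pixel_size = 1),
         cells = cbind(cells, cell_type = types),
         cell_types = stats::setNames(types, seq_len(n)),
         true_transform = tfm,
         true_abundances = true_ab,
         true_factor = 1 / sens,
         enrichment = if (condition == "lesional") spec$enrichment else 1,
         condition = condition, seed = seed),
    class = "phantom_truth"
  )
  list(protein = protein, lipid = lipid, truth = truth)
}

#' Generate a matched lesional/control phantom pair
#'
#' Two independent tissue sections from the same specification: a control
#' section (unit sensitivity, no enrichment) and a lesional section (oxPE
#' enrichment in K14+ cells, lipid sensitivity factor). The two sections
#' have independent cell geometry, as two real biopsies would.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; the lesional section uses a derived sub-seed.
#' @return List with elements `control` and `lesional`, each as returned by
#'   [generate_phantom()].
#' @export
generate_phantom_pair <- function(spec = phantom_spec(), seed = 1) {
  list(control = generate_phantom(spec, "control", seed = seed),
       lesional = generate_phantom(spec, "lesional", seed = seed + 5000L))
}

#' Generate a synthetic LC-MS peak table
#'
#' One peak per true ion with m/z jittered within `ppm_jitter`, plus decoy
#' peaks placed at least `decoy_min_ppm` from every true ion, so exact-mass
#' matching at tolerances below `decoy_min_ppm` must recover exactly the
#' true ions.
#'
#' @param database An ion database from [build_oxpl_database()] (columns
#'   `name`, `mz`).
#' @param abundances Intensities for the true ions (recycled).
#' @param n_decoys Number of decoy peaks.
#' @param ppm_jitter Maximum |m/z error| of true peaks, ppm.
#' @param snr_range Range the per-peak signal-to-noise ratio is drawn from.
#' @param decoy_min_ppm Minimum distance of decoys from any true ion, ppm.
#' @param seed Integer seed.
#' @return A peak data.frame (`mz`, `rt`, `intensity`, `noise`, `snr`,
#'   `true_species` — `NA` for decoys).
#' @export
generate_peak_table <- function(database, abundances = 1e5, n_decoys = 50,
                                ppm_jitter = 2, snr_range = c(5, 50),
                                decoy_min_ppm = 20, seed = 1) {
  n_true <- nrow(database)
  abundances <- rep_len(abundances, max(n_true, 1L))
  with_seed(seed, {
    true_mz <- if (n_true > 0) {
      database$mz * (1 + stats::runif(n_true, -ppm_jitter, ppm_jitter) * 1e-6)
    } else numeric(0)
    mz_lo <- if (n_true > 0) min(database$mz) * 0.95 else 400
    mz_hi <- if (n_true > 0) max(database$mz) * 1.05 else 900
    decoy_mz <- numeric(0)
    while (length(decoy_mz) < n_decoys) {
      cand <- stats::runif(n_decoys - length(decoy_mz), mz_lo, mz_hi)
      if (n_true > 0) {
        ok <- vapply(cand, function(m) {
          all(abs(m - database$mz) / database$mz * 1e6 >= decoy_min_ppm)
        }, logical(1))
        cand <- cand[ok]
      }
      decoy_mz <- c(decoy_mz, cand)
    }
    mz <- c(true_mz, decoy_mz)
    ntot <- length(mz)
    snr <- stats::runif(ntot, snr_range[1], snr_range[2])
    intensity <- c(abundances[seq_len(n_true)],
                   stats::runif(n_decoys, 0.01, 1) *
                     (if (n_true > 0) mean(abundances) else 1e4))
    data.frame(
      mz = mz,
      rt = stats::runif(ntot, 1, 20),
      intensity = intensity,
      noise = intensity / snr,
      snr = snr,
      true_species = c(as.character(database$name), rep(NA, n_decoys)),
      stringsAsFactors = FALSE
    )
  })
}
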