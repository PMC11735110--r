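# Exact-mass lipid chemistry: molecular formulas, [M-H]- m/z, and the
# combinatorial oxidized-phospholipid database used for LC-MS annotation.

#' Monoisotopic element mass table
#'
#' Monoisotopic atomic masses (Da) of the elements occurring in
#' glycerophospholipids and sterol sulfates, plus the electron mass used when
#' forming ion m/z values.
#'
#' @return An object of class `element_mass_table`: a list with `masses`
#'   (named numeric vector of monoisotopic masses, Da) and `electron_mass`
#'   (Da).
#' @examples
#' element_masses()$masses[["O"]]
#' @export
element_masses <- function() {
  structure(
    list(
      masses = c(
        C = 12.0,
        H = 1.00782503207,
        N = 14.0030740048,
        O = 15.9949146196,
        P = 30.97376163,
        S = 31.97207100,
        Na = 22.9897692809,
        K = 38.96370668
      ),
      electron_mass = 0.00054857991
    ),
    class = "element_mass_table"
  )
}

#' Molecular formula
#'
#' A molecular formula as a bag of element counts.
#'
#' @param ... Named integer element counts, e.g. `molecular_formula(C = 27,
#'   H = 46, O = 4, S = 1)`, or a single named numeric vector.
#' @return An object of class `molecular_formula` (named integer vector).
#' @export
molecular_formula <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    counts <- args[[1]]
  } else {
    counts <- unlist(args)
  }
  if (length(counts) == 0L) {
    return(structure(integer(0), class = "molecular_formula"))
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("all element counts must be named by element symbol")
  }
  if (any(counts < 0)) stop("element counts must be non-negative")
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  structure(counts, class = "molecular_formula")
}

#' @export
format.molecular_formula <- function(x, ...) {
  if (length(x) == 0L) return("(empty formula)")
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula A [molecular_formula()].
#' @param table An [element_masses()] table.
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' formula_mass(molecular_formula(H = 2, O = 1))
#' @export
formula_mass <- function(formula, table = element_masses()) {
  if (length(formula) == 0L) return(0.0)
  unknown <- setdiff(names(formula), names(table$masses))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(table$masses[names(formula)] * as.numeric(formula))
}

#' Lipid species
#'
#' A lipid species at the sum-composition level: class, total acyl carbons,
#' total double bonds, and number of added oxygen atoms (0-3). `"PE"` denotes
#' diacyl phosphatidylethanolamine; `"CholS"` cholesterol sulfate. Naming
#' follows the field convention `PE(C:db)+kO`.
#'
#' @param lipid_class `"PE"` or `"CholS"`.
#' @param acyl_carbons Total acyl-chain carbons (ignored for `"CholS"`).
#' @param double_bonds Total acyl double bonds.
#' @param added_oxygens Number of oxygen atoms added by oxygenation (0-3).
#' @return An object of class `lipid_species`.
#' @examples
#' lipid_species("PE", 40, 4, added_oxygens = 2)
#' @export
lipid_species <- function(lipid_class, acyl_carbons = 0L, double_bonds = 0L,
                          added_oxygens = 0L) {
  lipid_class <- match.arg(lipid_class, c("PE", "CholS"))
  if (added_oxygens < 0 || added_oxygens > 3) {
    stop("added_oxygens must be between 0 and 3")
  }
  if (acyl_carbons < 0 || double_bonds < 0 || double_bonds > acyl_carbons) {
    stop("invalid acyl composition: need 0 <= double_bonds <= acyl_carbons")
  }
  name <- if (lipid_class == "CholS") {
    "cholesterol sulfate"
  } else {
    paste0("PE(", acyl_carbons, ":", double_bonds, ")",
           if (added_oxygens > 0) paste0("+", added_oxygens, "O") else "")
  }
  structure(
    list(lipid_class = lipid_class,
         acyl_carbons = as.integer(acyl_carbons),
         double_bonds = as.integer(double_bonds),
         added_oxygens = as.integer(added_oxygens),
         display_name = name),
    class = "lipid_species"
  )
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species>", x$display_name, "\n")
  invisible(x)
}

#' Molecular formula of a lipid species
#'
#' Diacyl PE with `n` acyl carbons, `d` double bonds and `k` added oxygens has
#' formula C(n+5) H(2n-2d+10) N O(8+k) P (glycerophosphoethanolamine backbone
#' plus two acyl chains). Cholesterol sulfate is C27 H46 O(4+k) S.
#'
#' @param species A [lipid_species()].
#' @return A [molecular_formula()].
#' @examples
#' species_formula(lipid_species("PE", 40, 4))
#' @export
species_formula <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  k <- species$added_oxygens
  switch(species$lipid_class,
    PE = {
      n <- species$acyl_carbons
      d <- species$double_bonds
      molecular_formula(C = n + 5L, H = 2L * n - 2L * d + 10L,
                        N = 1L, O = 8L + k, P = 1L)
    },
    CholS = molecular_formula(C = 27L, H = 46L, O = 4L + k, S = 1L),
    stop("unsupported lipid class: ", species$lipid_class)
  )
}

#' m/z of a lipid ion
#'
#' Monoisotopic m/z of the deprotonated molecular ion: neutral mass minus one
#' hydrogen atom plus one electron (the departing proton takes no electrons).
#'
#' @param species A [lipid_species()].
#' @param adduct Only `"[M-H]-"` is supported (negative-mode deprotonation).
#' @param table An [element_masses()] table.
#' @return m/z in Da (charge 1).
#' @examples
#' ion_mz(lipid_species("CholS"))  # 465.3044
#' @export
ion_mz <- function(species, adduct = "[M-H]-", table = element_masses()) {
  adduct <- match.arg(adduct, "[M-H]-")
  formula_mass(species_formula(species), table) -
    table$masses[["H"]] + table$electron_mass
}

#' Build a combinatorial oxidized-phospholipid ion database
#'
#' Enumerates one `[M-H]-` ion per (class, carbons, double bonds, added
#' oxygens) combination, sorted by m/z. This is the search database used to
#' annotate LC-MS peaks by exact mass.
#'
#' @param classes Lipid classes to enumerate (currently `"PE"`).
#' @param carbon_range Integer vector of total acyl carbons.
#' @param db_range Integer vector of total double bonds.
#' @param oxygens Integer set of added oxygens; must be non-empty.
#' @param include_parent Also include the non-oxygenated (+0O) parent species.
#' @return A data.frame of class `oxpl_database` with columns `name`,
#'   `lipid_class`, `acyl_carbons`, `double_bonds`, `added_oxygens`,
#'   `formula`, `mz`, plus a `species` list-column.
#' @examples
#' db <- build_oxpl_database(carbon_range = 36:38, db_range = 4:5,
#'                           oxygens = 2)
#' db$name
#' @export
build_oxpl_database <- function(classes = "PE",
                                carbon_range = 34:44,
                                db_range = 2:6,
                                oxygens = 1:3,
                                include_parent = FALSE) {
  if (length(oxygens) == 0L) stop("oxygens set must be non-empty")
  if (length(carbon_range) == 0L || length(db_range) == 0L) {
    stop("carbon_range and db_range must be non-empty")
  }
  oxy <- sort(unique(as.integer(oxygens)))
  if (include_parent) oxy <- unique(c(0L, oxy))
  grid <- expand.grid(lipid_class = classes, C = carbon_range,
                      db = db_range, k = oxy,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$db <= grid$C, , drop = FALSE]
  sp <- mapply(function(cl, C, db, k) lipid_species(cl, C, db, k),
               grid$lipid_class, grid$C, grid$db, grid$k, SIMPLIFY = FALSE)
  out <- data.frame(
    name = vapply(sp, function(s) s$display_name, character(1)),
    lipid_class = grid$lipid_class,
    acyl_carbons = as.integer(grid$C),
    double_bonds = as.integer(grid$db),
    added_oxygens = as.integer(grid$k),
    formula = vapply(sp, function(s) format(species_formula(s)), character(1)),
    mz = vapply(sp, ion_mz, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$species <- sp
  stopifnot(!anyDuplicated(out$name))
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("oxpl_database", "data.frame")
  out
}

#' Filter LC-MS peaks by signal-to-noise ratio
#'
#' Retains peaks whose signal-to-noise ratio is strictly greater than
#' `min_snr`, preserving input order.
#'
#' @param peaks A data.frame with at least column `snr`, or columns
#'   `intensity` and `noise` from which `snr` is derived.
#' @param min_snr Strict lower bound on S/N (default 3).
#' @return The retained subset of `peaks` (a subsequence of the input).
#' @export
filter_snr <- function(peaks, min_snr = 3) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L) return(peaks)
  snr <- peak_snr(peaks)
  out <- peaks[!is.na(snr) & snr > min_snr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

peak_snr <- function(peaks) {
  if ("snr" %in% names(peaks)) return(peaks$snr)
  if (all(c("intensity", "noise") %in% names(peaks))) {
    return(ifelse(peaks$noise > 0, peaks$intensity / peaks$noise, NA_real_))
  }
  stop("peak table needs an 'snr' column or 'intensity' and 'noise' columns")
}

#' Match LC-MS peaks against an ion database by exact mass
#'
#' Each peak is assigned the database entry with the smallest absolute ppm
#' error within `ppm_tol`; ppm ties are broken toward the lower-m/z entry so
#' output is deterministic. Optional per-species retention-time windows
#' further restrict candidate matches. Unmatched peaks keep `species = NA`.
#'
#' @param peaks A data.frame with columns `mz` and optionally `rt` (minutes).
#' @param database An [build_oxpl_database()] result (or any data.frame with
#'   `name` and `mz`, sorted by `mz`).
#' @param ppm_tol Match tolerance in ppm (> 0; default 5).
#' @param rt_windows Optional named list `species name -> c(min, max)` RT
#'   window in minutes.
#' @return `peaks` with added columns `species`, `adduct`, `matched_mz`,
#'   `ppm_error`.
#' @export
match_peaks <- function(peaks, database, ppm_tol = 5, rt_windows = NULL) {
  stopifnot(is.data.frame(peaks), is.data.frame(database))
  if (ppm_tol <= 0) stop("ppm_tol must be positive")
  if (is.unsorted(database$mz)) stop("database must be sorted by mz")
  out <- peaks
  out[["species"]] <- rep(NA_character_, nrow(peaks))
  out[["adduct"]] <- rep(NA_character_, nrow(peaks))
  out[["matched_mz"]] <- rep(NA_real_, nrow(peaks))
  out[["ppm_error"]] <- rep(NA_real_, nrow(peaks))
  if (nrow(peaks) == 0L || nrow(database) == 0L) return(out)
  has_rt <- !is.null(rt_windows) && "rt" %in% names(peaks)
  for (i in seq_len(nrow(peaks))) {
    ppm <- (peaks$mz[i] - database$mz) / database$mz * 1e6
    ok <- abs(ppm) <= ppm_tol
    if (has_rt) {
      in_rt <- vapply(database$name, function(nm) {
        w <- rt_windows[[nm]]
        is.null(w) || (peaks$rt[i] >= w[1] && peaks$rt[i] <= w[2])
      }, logical(1))
      ok <- ok & in_rt
    }
    if (!any(ok)) next
    cand <- which(ok)
    # ties in |ppm| resolve to the lower-mz entry (candidates are mz-sorted)
    best <- cand[which.min(abs(ppm[cand]))]
    out$species[i] <- database$name[best]
    out$adduct[i] <- "[M-H]-"
    out$matched_mz[i] <- database$mz[best]
    out$ppm_error[i] <- ppm[best]
  }
  out
}

#' Read an LC-MS peak table from CSV
#'
#' Expects columns `mz`, `rt`, `intensity`, `noise`; an `snr` column is added
#' when absent.
#'
#' @param path CSV file path.
#' @return A data.frame of peaks.
#' @export
read_peak_table <- function(path) {
  peaks <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mz", "intensity")
  if (!all(need %in% names(peaks))) {
    stop("peak table ", path, " lacks required columns: ",
         paste(setdiff(need, names(peaks)), collapse = ", "))
  }
  if (!"snr" %in% names(peaks) && all(c("intensity", "noise") %in% names(peaks))) {
    peaks$snr <- peak_snr(peaks)
  }
  peaks
}

#' Write annotated peaks or an ion database to CSV
#'
#' @param x A data.frame from [match_peaks()] or [build_oxpl_database()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lipid_csv <- function(x, path) {
  x <- as.data.frame(x)
  keep <- !vapply(x, is.list, logical(1))  # drop list-columns (species objects)
  utils::write.csv(x[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
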