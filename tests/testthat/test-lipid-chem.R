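test_that("formula mass sums monoisotopic element masses", {
  expect_equal(formula_mass(molecular_formula(H = 2, O = 1)), 18.0106,
               tolerance = 1e-3)
  expect_identical(formula_mass(molecular_formula()), 0)
  # cholesterol sulfate neutral mass, frozen from the element-mass summation
  expect_equal(formula_mass(molecular_formula(C = 27, H = 46, O = 4, S = 1)),
               466.3117, tolerance = 1e-3)
  expect_error(formula_mass(molecular_formula(Xx = 1)), "Xx")
})

test_that("diacyl PE formula constructor matches sum composition", {
  f <- species_formula(lipid_species("PE", 40, 4))
  expect_identical(format(f), "C45H82NO8P")
  f2 <- species_formula(lipid_species("PE", 40, 4, added_oxygens = 2))
  expect_identical(format(f2), "C45H82NO10P")
  expect_identical(format(species_formula(lipid_species("PE", 36, 4))),
                   "C41H74NO8P")
  expect_identical(format(species_formula(lipid_species("CholS"))),
                   "C27H46O4S")
  expect_error(lipid_species("PE", 36, 40), "double_bonds")
  expect_error(lipid_species("PE", 36, 4, added_oxygens = 4), "added_oxygens")
})

test_that("[M-H]- m/z values reproduce the printed reference values", {
  expect_equal(round(ion_mz(lipid_species("CholS")), 2), 465.30)
  expect_equal(round(ion_mz(lipid_species("PE", 40, 4)), 1), 794.6)
  expect_equal(round(ion_mz(lipid_species("PE", 40, 4, 2)), 1), 826.6)
})

test_that("oxygenation shifts m/z by exact multiples of the oxygen mass", {
  mO <- element_masses()$masses[["O"]]
  for (C in seq(34, 44, by = 2)) {
    for (db in c(2, 4, 6)) {
      base <- ion_mz(lipid_species("PE", C, db))
      for (k in 1:3) {
        expect_equal(ion_mz(lipid_species("PE", C, db, k)) - base, k * mO,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("oxPL database enumerates the requested combinations", {
  db <- build_oxpl_database(carbon_range = 40, db_range = 4, oxygens = 1:3)
  expect_equal(nrow(db), 3)
  db2 <- build_oxpl_database(carbon_range = c(36, 38), db_range = 4:5,
                             oxygens = 2)
  expect_equal(nrow(db2), 4)
  expect_true(all(c("PE(36:4)+2O", "PE(38:4)+2O") %in% db2$name))
  expect_false(is.unsorted(db2$mz))
  # every stored m/z agrees with ion_mz of its own species
  for (i in seq_len(nrow(db2))) {
    expect_equal(db2$mz[i], ion_mz(db2$species[[i]]), tolerance = 1e-12)
  }
  expect_error(build_oxpl_database(oxygens = integer(0)), "non-empty")
})

test_that("S/N filter is strict and order preserving", {
  peaks <- data.frame(mz = c(500, 600, 700), intensity = c(10, 31, 100),
                      noise = c(10, 10, 10), snr = c(1, 3.1, 10))
  kept <- filter_snr(peaks)
  expect_equal(kept$mz, c(600, 700))
  expect_equal(nrow(filter_snr(peaks[0, ])), 0)
  # a peak at exactly S/N = 3 is removed (strictly greater than)
  at3 <- data.frame(mz = 500, intensity = 30, noise = 10, snr = 3.0)
  expect_equal(nrow(filter_snr(at3)), 0)
  # output is a subsequence of the input
  set.seed(4)
  big <- data.frame(mz = runif(50, 400, 900), intensity = 1,
                    noise = 1, snr = runif(50, 0, 10))
  kept <- filter_snr(big)
  expect_true(all(kept$mz %in% big$mz))
  expect_false(is.unsorted(match(kept$mz, big$mz)))
})

test_that("peak matching picks the nearest entry within tolerance", {
  db <- build_oxpl_database(carbon_range = 34:44, db_range = 2:6,
                            oxygens = 1:3)
  expect_equal(nrow(match_peaks(data.frame(mz = numeric(0)), db)), 0)
  target <- db$mz[db$name == "PE(38:4)+2O"]
  hit <- match_peaks(data.frame(mz = target), db, ppm_tol = 5)
  expect_equal(hit$species, "PE(38:4)+2O")
  expect_equal(hit$ppm_error, 0)
  far <- match_peaks(data.frame(mz = target * (1 + 20e-6)), db, ppm_tol = 5)
  expect_true(is.na(far$species))
  expect_error(match_peaks(data.frame(mz = target), db, ppm_tol = 0),
               "ppm_tol")
})

test_that("matching agrees with brute-force nearest neighbor and is order equivariant", {
  db <- build_oxpl_database(carbon_range = 34:44, db_range = 2:6,
                            oxygens = 1:3, include_parent = TRUE)
  set.seed(11)
  peaks <- data.frame(mz = runif(200, min(db$mz) - 1, max(db$mz) + 1))
  tol <- 30
  res <- match_peaks(peaks, db, ppm_tol = tol)
  for (i in seq_len(nrow(peaks))) {
    ppm <- (peaks$mz[i] - db$mz) / db$mz * 1e6
    ok <- which(abs(ppm) <= tol)
    if (length(ok) == 0) {
      expect_true(is.na(res$species[i]))
    } else {
      best <- ok[which.min(abs(ppm[ok]))]
      expect_identical(res$species[i], db$name[best])
    }
  }
  perm <- sample(nrow(peaks))
  res_perm <- match_peaks(peaks[perm, , drop = FALSE], db, ppm_tol = tol)
  expect_identical(res_perm$species, res$species[perm])
})

test_that("retention-time windows veto mass matches outside them", {
  db <- build_oxpl_database(carbon_range = 38, db_range = 4, oxygens = 2)
  peaks <- data.frame(mz = db$mz, rt = c(12))
  win_ok <- list("PE(38:4)+2O" = c(10, 14))
  win_bad <- list("PE(38:4)+2O" = c(1, 5))
  expect_equal(match_peaks(peaks, db, rt_windows = win_ok)$species,
               "PE(38:4)+2O")
  expect_true(is.na(match_peaks(peaks, db, rt_windows = win_bad)$species))
})

test_that("peak tables and annotations round-trip through CSV", {
  db <- build_oxpl_database(carbon_range = 36:40, db_range = 4, oxygens = 2)
  tab <- generate_peak_table(db, abundances = 1e5, n_decoys = 5, seed = 2)
  p <- file.path(tempdir(), "peaks.csv")
  utils::write.csv(tab[c("mz", "rt", "intensity", "noise")], p,
                   row.names = FALSE)
  back <- read_peak_table(p)
  expect_equal(back$mz, tab$mz)
  expect_equal(back$snr, tab$intensity / tab$noise)
  ann <- match_peaks(back, db)
  out <- file.path(tempdir(), "annotated.csv")
  write_lipid_csv(ann, out)
  expect_true(file.exists(out))
  expect_equal(nrow(utils::read.csv(out)), nrow(ann))
})
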