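# MSI dataset I/O: a plain-text internal container (JSON metadata + long-form
# CSV of peaks) and a read-only imzML importer (continuous and processed
# binary modes).

#' Write an MSI grid to the internal container format
#'
#' The container is a pair of text files sharing a stem: `<stem>.json` with
#' grid metadata and `<stem>.csv` with one row per peak (`pixel` row-major
#' 1-based index, `mz`, `intensity`). Pixels with empty spectra are simply
#' absent from the CSV.
#'
#' @param grid An [msi_grid()].
#' @param path Output stem or `<stem>.json` path.
#' @return The metadata path, invisibly.
#' @export
write_msi <- function(grid, path) {
  stopifnot(inherits(grid, "msi_grid"))
  stem <- sub("\\.json$", "", path)
  meta <- list(format = "oxmsi-grid", version = 1L,
               shape = grid$shape, pixel_size = grid$pixel_size,
               modality = grid$modality, n_pixels = prod(grid$shape))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  n <- lengths(grid$mz)
  df <- data.frame(pixel = rep(seq_along(grid$mz), n),
                   mz = unlist(grid$mz, use.names = FALSE),
                   intensity = unlist(grid$intensity, use.names = FALSE))
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  invisible(paste0(stem, ".json"))
}

#' Read an MSI dataset
#'
#' Reads either the internal container written by [write_msi()] (pass the
#' stem or the `.json` path) or an imzML file (pass the `.imzML` path;
#' `format` is auto-detected from the extension).
#'
#' @param path Input path.
#' @param format `"auto"`, `"oxmsi"` or `"imzml"`.
#' @param pixel_size Pixel size override in micrometers (imzML files often
#'   omit it); ignored for the internal container.
#' @param modality Modality tag for imzML input.
#' @return An [msi_grid()].
#' @export
read_msi <- function(path, format = c("auto", "oxmsi", "imzml"),
                     pixel_size = 1, modality = "gcib_lipid") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml"
              else "oxmsi"
  }
  if (format == "imzml") {
    return(read_imzml(path, pixel_size = pixel_size, modality = modality))
  }
  stem <- sub("\\.json$", "", path)
  meta_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, ".csv")
  if (!file.exists(meta_path)) stop("missing container metadata: ", meta_path)
  if (!file.exists(csv_path)) stop("missing container data: ", csv_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "oxmsi-grid")) {
    stop("not an oxmsi grid container: ", meta_path)
  }
  shape <- as.integer(meta$shape)
  df <- utils::read.csv(csv_path)
  n <- prod(shape)
  mz <- rep(list(numeric(0)), n)
  intensity <- rep(list(numeric(0)), n)
  if (nrow(df) > 0) {
    if (any(df$pixel < 1 | df$pixel > n)) {
      stop("corrupt container ", csv_path, ": pixel index out of range at row ",
           which(df$pixel < 1 | df$pixel > n)[1])
    }
    sp <- split(df[c("mz", "intensity")], factor(df$pixel, levels = seq_len(n)))
    for (i in seq_len(n)) {
      o <- order(sp[[i]]$mz)
      mz[[i]] <- sp[[i]]$mz[o]
      intensity[[i]] <- sp[[i]]$intensity[o]
    }
  }
  msi_grid(mz, intensity, shape, pixel_size = meta$pixel_size,
           modality = meta$modality)
}

# --- imzML ------------------------------------------------------------------

imzml_cv <- function(node, accession) {
  xml2::xml_find_first(
    node, sprintf(".//*[local-name()='cvParam'][@accession='%s']", accession))
}

imzml_cv_value <- function(node, accession) {
  p <- imzml_cv(node, accession)
  if (inherits(p, "xml_missing")) NA_character_ else xml2::xml_attr(p, "value")
}

#' Read an imzML mass spectrometry imaging file
#'
#' Supports continuous mode (one shared m/z axis referenced by every
#' spectrum) and processed mode (per-spectrum centroid lists), with 32- or
#' 64-bit float external binary arrays in the sibling `.ibd` file.
#'
#' @param path Path to the `.imzML` XML file.
#' @param pixel_size Pixel size in micrometers (used when the file does not
#'   state one).
#' @param modality Modality tag for the resulting grid.
#' @return An [msi_grid()]. Grid rows correspond to imzML `position y`,
#'   columns to `position x`.
#' @export
read_imzml <- function(path, pixel_size = 1, modality = "gcib_lipid") {
  if (!file.exists(path)) stop("no such file: ", path)
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("missing binary data file: ", ibd_path)
  doc <- xml2::read_xml(path)

  # per-param-group binary encoding (32- vs 64-bit float)
  groups <- xml2::xml_find_all(
    doc, "//*[local-name()='referenceableParamGroup']")
  enc <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    size <- if (!inherits(imzml_cv(g, "MS:1000523"), "xml_missing")) 8L
            else if (!inherits(imzml_cv(g, "MS:1000521"), "xml_missing")) 4L
            else NA_integer_
    kind <- if (!inherits(imzml_cv(g, "MS:1000514"), "xml_missing")) "mz"
            else if (!inherits(imzml_cv(g, "MS:1000515"), "xml_missing"))
              "intensity" else NA_character_
    enc[[id]] <- list(size = size, kind = kind)
  }

  px <- imzml_cv_value(doc, "IMS:1000046")  # pixel size x, when present
  if (!is.na(px) && nzchar(px)) pixel_size <- as.numeric(px)

  ibd <- readBin(ibd_path, "raw", n = file.size(ibd_path))
  read_array <- function(offset, length, size) {
    # offset is 0-based into the ibd file (first 16 bytes are the UUID)
    start <- offset + 1
    readBin(ibd[start:(start + length * size - 1)], "double", n = length,
            size = size)
  }

  spectra <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  if (length(spectra) == 0) stop("malformed imzML (no spectra): ", path)
  xs <- integer(length(spectra)); ys <- integer(length(spectra))
  mzl <- vector("list", length(spectra))
  intl <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    xs[i] <- as.integer(imzml_cv_value(s, "IMS:1000050"))
    ys[i] <- as.integer(imzml_cv_value(s, "IMS:1000051"))
    if (is.na(xs[i]) || is.na(ys[i])) {
      stop("malformed imzML: spectrum ", i, " lacks pixel coordinates")
    }
    arrays <- xml2::xml_find_all(s, ".//*[local-name()='binaryDataArray']")
    for (a in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(
          a, ".//*[local-name()='referenceableParamGroupRef']"), "ref")
      e <- enc[[ref]]
      if (is.null(e) || is.na(e$kind)) {
        stop("malformed imzML: unresolvable binary array group in spectrum ", i)
      }
      offset <- as.numeric(imzml_cv_value(a, "IMS:1000102"))
      alen <- as.integer(imzml_cv_value(a, "IMS:1000103"))
      vals <- if (alen > 0) read_array(offset, alen, e$size) else numeric(0)
      if (e$kind == "mz") mzl[[i]] <- vals else intl[[i]] <- vals
    }
  }
  shape <- c(max(ys), max(xs))
  n <- prod(shape)
  mz <- rep(list(numeric(0)), n)
  intensity <- rep(list(numeric(0)), n)
  for (i in seq_along(spectra)) {
    idx <- (ys[i] - 1L) * shape[2] + xs[i]
    keep <- intl[[i]] != 0  # continuous mode stores dense rows; keep peaks
    mz[[idx]] <- mzl[[i]][keep]
    intensity[[idx]] <- intl[[i]][keep]
  }
  msi_grid(mz, intensity, shape, pixel_size = pixel_size, modality = modality)
}

# Minimal imzML writer (continuous or processed mode). Used to build
# round-trip fixtures in the tests; not part of the public interface.
write_imzml <- function(grid, path, mode = c("processed", "continuous"),
                        mz_size = 8L, int_size = 4L) {
  mode <- match.arg(mode)
  stem <- sub("\\.imzml$", "", path, ignore.case = TRUE)
  ibd_path <- paste0(stem, ".ibd")
  n <- prod(grid$shape)

  con <- file(ibd_path, "wb")
  writeBin(as.raw(rep(0, 16)), con)  # uuid placeholder
  offset <- 16
  entries <- vector("list", n)
  shared_axis <- NULL
  if (mode == "continuous") {
    shared_axis <- sort(unique(unlist(grid$mz)))
    mz_off <- offset; mz_len <- length(shared_axis)
    writeBin(shared_axis, con, size = mz_size)
    offset <- offset + mz_len * mz_size
  }
  for (i in seq_len(n)) {
    if (mode == "continuous") {
      dense <- numeric(length(shared_axis))
      dense[match(grid$mz[[i]], shared_axis)] <- grid$intensity[[i]]
      int_off <- offset; int_len <- length(dense)
      writeBin(dense, con, size = int_size)
      offset <- offset + int_len * int_size
      entries[[i]] <- list(mz_off = mz_off, mz_len = mz_len,
                           int_off = int_off, int_len = int_len)
    } else {
      mo <- offset; ml <- length(grid$mz[[i]])
      writeBin(as.numeric(grid$mz[[i]]), con, size = mz_size)
      offset <- offset + ml * mz_size
      io <- offset; il <- length(grid$intensity[[i]])
      writeBin(as.numeric(grid$intensity[[i]]), con, size = int_size)
      offset <- offset + il * int_size
      entries[[i]] <- list(mz_off = mo, mz_len = ml, int_off = io,
                           int_len = il)
    }
  }
  close(con)

  fmt_group <- function(id, kind_acc, kind_name, size) {
    size_acc <- if (size == 8L) "MS:1000523" else "MS:1000521"
    size_name <- if (size == 8L) "64-bit float" else "32-bit float"
    sprintf(paste0(
      '    <referenceableParamGroup id="%s">\n',
      '      <cvParam cvRef="MS" accession="%s" name="%s" value=""/>\n',
      '      <cvParam cvRef="MS" accession="%s" name="%s" value=""/>\n',
      '    </referenceableParamGroup>\n'),
      id, kind_acc, kind_name, size_acc, size_name)
  }
  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  sp <- character(n)
  for (i in seq_len(n)) {
    e <- entries[[i]]
    row <- (i - 1L) %/% grid$shape[2] + 1L
    col <- (i - 1L) %% grid$shape[2] + 1L
    sp[i] <- sprintf(paste0(
      '      <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">\n',
      '        <scanList count="1">\n',
      '          <scan>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
      '          </scan>\n',
      '        </scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="mzArray"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="intensityArray"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>\n'),
      i, i - 1L, e$mz_len, col, row, e$mz_off, e$mz_len, e$int_off, e$int_len)
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '  <fileDescription>\n',
    '    <fileContent>\n',
    sprintf('      <cvParam cvRef="IMS" accession="%s" name="%s"/>\n',
            mode_acc, mode),
    '    </fileContent>\n',
    '  </fileDescription>\n',
    '  <referenceableParamGroupList count="2">\n',
    fmt_group("mzArray", "MS:1000514", "m/z array", mz_size),
    fmt_group("intensityArray", "MS:1000515", "intensity array", int_size),
    '  </referenceableParamGroupList>\n',
    '  <scanSettingsList count="1">\n',
    '    <scanSettings id="scan1">\n',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%g"/>\n',
            grid$pixel_size),
    '    </scanSettings>\n',
    '  </scanSettingsList>\n',
    '  <run id="run1">\n',
    sprintf('    <spectrumList count="%d">\n', n),
    paste0(sp, collapse = ""),
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}
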