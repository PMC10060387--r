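#' Read MS/MS spectra from a file
#'
#' Reads MGF (`BEGIN IONS`/`END IONS` blocks), MSP (`Name:`/`Num Peaks:`
#' records) or mzML (MS level-2 scans with a selected precursor ion).
#' Metadata keys are lower-cased and harmonised: the precursor m/z is taken
#' from `PEPMASS`, `PRECURSORMZ`, `PRECURSOR_MZ` or `PREC_MZ` dialects, the
#' ionisation mode from an explicit `IONMODE`/`ION_MODE` field or the sign
#' of the charge. Peaks are sorted ascending by m/z. Records without peaks
#' are skipped with a warning.
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"mgf"`, `"msp"`,
#'   `"mzml"`.
#' @return list of [ms2_spectrum] objects.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "msp", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", msp = "msp", mzml = "mzml",
                     stop("cannot infer format from extension: ", ext,
                          call. = FALSE))
  }
  switch(format,
         mgf = read_mgf(path),
         msp = read_msp(path),
         mzml = read_mzml(path))
}

.harmonise_record <- function(meta, mz, intensity, fallback_id) {
  names(meta) <- tolower(names(meta))
  pmz <- NA_real_
  for (k in c("pepmass", "precursormz", "precursor_mz", "prec_mz",
              "precursor m/z")) {
    if (!is.null(meta[[k]])) {
      # PEPMASS may carry "mz intensity"
      pmz <- suppressWarnings(as.numeric(strsplit(trimws(meta[[k]]),
                                                  "[[:space:]]+")[[1]][1]))
      break
    }
  }
  ionmode <- "unknown"
  im <- meta[["ionmode"]] %||% meta[["ion_mode"]] %||% meta[["ion mode"]]
  if (!is.null(im)) {
    im <- tolower(trimws(im))
    if (im %in% c("positive", "pos", "p", "+")) ionmode <- "positive"
    if (im %in% c("negative", "neg", "n", "-")) ionmode <- "negative"
  } else if (!is.null(meta[["charge"]])) {
    ch <- meta[["charge"]]
    if (grepl("-", ch)) ionmode <- "negative"
    else if (grepl("\\+|^[0-9]+$", ch)) ionmode <- "positive"
  }
  id <- meta[["spectrum_id"]] %||% meta[["spectrumid"]] %||%
    meta[["scans"]] %||% meta[["feature_id"]] %||% meta[["title"]] %||%
    meta[["name"]] %||% fallback_id
  grab <- function(k) {
    v <- meta[[k]]
    if (is.null(v) || !nzchar(trimws(v))) NA_character_ else trimws(v)
  }
  extra <- meta[!names(meta) %in%
                  c("pepmass", "precursormz", "precursor_mz", "prec_mz",
                    "ionmode", "ion_mode", "smiles", "inchi", "inchikey",
                    "spectrum_id", "spectrumid")]
  ms2_spectrum(spectrum_id = id, mz = mz, intensity = intensity,
               precursor_mz = pmz, ionmode = ionmode,
               smiles = grab("smiles"), inchi = grab("inchi"),
               inchikey = grab("inchikey"), metadata = extra)
}

#' @rdname read_spectra
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L; n <- length(lines); rec <- 0L
  while (i <= n) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      rec <- rec + 1L
      meta <- list(); mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (i <= n && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (nzchar(ln)) {
          if (grepl("=", ln, fixed = TRUE)) {
            eq <- regexpr("=", ln, fixed = TRUE)
            meta[[substr(ln, 1, eq - 1)]] <- substr(ln, eq + 1, nchar(ln))
          } else {
            parts <- strsplit(ln, "[[:space:]]+")[[1]]
            if (length(parts) >= 2) {
              mz <- c(mz, as.numeric(parts[1]))
              int <- c(int, as.numeric(parts[2]))
            }
          }
        }
        i <- i + 1L
      }
      if (length(mz) == 0) {
        warning("record ", rec, " in ", basename(path),
                " has no peaks; skipped")
      } else {
        out[[length(out) + 1L]] <-
          .harmonise_record(meta, mz, int, sprintf("spectrum_%d", rec))
      }
    }
    i <- i + 1L
  }
  out
}

#' @rdname read_spectra
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L; n <- length(lines); rec <- 0L
  while (i <= n) {
    ln <- trimws(lines[i])
    if (grepl("^name[[:space:]]*:", ln, ignore.case = TRUE)) {
      rec <- rec + 1L
      meta <- list(); mz <- numeric(0); int <- numeric(0)
      repeat {
        ln <- trimws(lines[i])
        if (grepl("^num[[:space:]]?peaks[[:space:]]*:", ln,
                  ignore.case = TRUE)) {
          npk <- as.integer(sub(".*:", "", ln))
          i <- i + 1L
          while (i <= n && length(mz) < npk && nzchar(trimws(lines[i]))) {
            toks <- strsplit(trimws(lines[i]), "[;[:space:]]+")[[1]]
            toks <- toks[nzchar(toks)]
            if (length(toks) >= 2) {
              vals <- suppressWarnings(as.numeric(toks))
              vals <- vals[!is.na(vals)]
              if (length(vals) >= 2) {
                pair_n <- length(vals) %/% 2
                idx <- seq_len(pair_n) * 2 - 1
                mz <- c(mz, vals[idx]); int <- c(int, vals[idx + 1])
              }
            }
            i <- i + 1L
          }
          break
        }
        colon <- regexpr(":", ln, fixed = TRUE)
        if (colon > 0) {
          meta[[trimws(substr(ln, 1, colon - 1))]] <-
            trimws(substr(ln, colon + 1, nchar(ln)))
        }
        i <- i + 1L
        if (i > n) break
      }
      if (length(mz) == 0) {
        warning("record ", rec, " in ", basename(path),
                " has no peaks; skipped")
      } else {
        out[[length(out) + 1L]] <-
          .harmonise_record(meta, mz, int, sprintf("spectrum_%d", rec))
      }
    } else {
      i <- i + 1L
    }
  }
  out
}

.decode_binary_array <- function(node) {
  acc <- xml2::xml_attr(
    xml2::xml_find_all(node, ".//*[local-name()='cvParam']"), "accession")
  raw_b64 <- xml2::xml_text(
    xml2::xml_find_first(node, ".//*[local-name()='binary']"))
  bytes <- jsonlite::base64_dec(gsub("[[:space:]]", "", raw_b64))
  if ("MS:1000574" %in% acc) bytes <- memDecompress(bytes, type = "gzip")
  size <- if ("MS:1000521" %in% acc) 4L else 8L
  vals <- readBin(bytes, what = "double", n = length(bytes) %/% size,
                  size = size, endian = "little")
  kind <- if ("MS:1000514" %in% acc) "mz"
          else if ("MS:1000515" %in% acc) "intensity" else "other"
  list(kind = kind, values = vals)
}

#' @rdname read_spectra
#' @export
read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  specs <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  out <- list(); rec <- 0L
  for (sp in specs) {
    cv <- xml2::xml_find_all(
      sp, "./*[local-name()='cvParam']")
    acc <- xml2::xml_attr(cv, "accession")
    lev <- xml2::xml_attr(cv, "value")[acc == "MS:1000511"]
    if (!length(lev) || lev[1] != "2") next
    rec <- rec + 1L
    pre <- xml2::xml_find_first(
      sp, ".//*[local-name()='selectedIon']/*[local-name()='cvParam'][@accession='MS:1000744']")
    pmz <- suppressWarnings(as.numeric(xml2::xml_attr(pre, "value")))
    mode <- "unknown"
    if ("MS:1000130" %in% acc) mode <- "positive"
    if ("MS:1000129" %in% acc) mode <- "negative"
    arrays <- lapply(
      xml2::xml_find_all(sp, ".//*[local-name()='binaryDataArray']"),
      .decode_binary_array)
    mz <- NULL; int <- NULL
    for (a in arrays) {
      if (a$kind == "mz") mz <- a$values
      if (a$kind == "intensity") int <- a$values
    }
    id <- xml2::xml_attr(sp, "id")
    if (is.na(id)) id <- sprintf("scan_%d", rec)
    if (is.null(mz) || length(mz) == 0) {
      warning("MS2 scan ", id, " has no peaks; skipped")
      next
    }
    out[[length(out) + 1L]] <- ms2_spectrum(
      spectrum_id = id, mz = mz, intensity = int,
      precursor_mz = if (length(pmz) && !is.na(pmz)) pmz else NA_real_,
      ionmode = mode)
  }
  out
}

#' Write spectra to an MGF file
#'
#' Annotations (precursor m/z, ionmode, SMILES, InChI, InChIKey) and extra
#' metadata are written as `KEY=value` headers; peak m/z values keep full
#' double precision.
#'
#' @param spectra list of [ms2_spectrum] objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    lines <- c("BEGIN IONS",
               paste0("SPECTRUM_ID=", s$spectrum_id))
    if (!is.na(s$precursor_mz))
      lines <- c(lines, sprintf("PEPMASS=%.*g", 15, s$precursor_mz))
    lines <- c(lines, paste0("IONMODE=", s$ionmode))
    if (!is.na(s$smiles)) lines <- c(lines, paste0("SMILES=", s$smiles))
    if (!is.na(s$inchi)) lines <- c(lines, paste0("INCHI=", s$inchi))
    if (!is.na(s$inchikey))
      lines <- c(lines, paste0("INCHIKEY=", s$inchikey))
    for (k in names(s$metadata)) {
      lines <- c(lines, paste0(toupper(k), "=", s$metadata[[k]]))
    }
    lines <- c(lines,
               sprintf("%.*g %.*g", 15, s$mz, 15, s$intensity),
               "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}
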