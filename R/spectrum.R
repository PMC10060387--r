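#' Construct an MS/MS spectrum
#'
#' The basic container used throughout the package: a fragment peak list
#' (m/z strictly increasing, intensities aligned and non-negative) plus the
#' precursor m/z, ionisation mode and optional structure annotations
#' (SMILES / InChI / InChIKey).
#'
#' @param spectrum_id unique identifier string.
#' @param mz numeric vector of fragment m/z values in Da. Sorted on input;
#'   peaks sharing an identical m/z are merged by summing their intensities
#'   so the stored m/z vector is strictly increasing.
#' @param intensity numeric vector of non-negative intensities, same length
#'   as `mz`.
#' @param precursor_mz precursor m/z in Da (`NA` if unknown); must be
#'   positive when present.
#' @param ionmode one of `"positive"`, `"negative"`, `"unknown"`.
#' @param smiles,inchi,inchikey optional structure annotations (`NA` when
#'   absent).
#' @param metadata named character list of extra metadata (compound name,
#'   retention time, ...). Keys are lower-cased.
#' @return An object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(spectrum_id, mz, intensity, precursor_mz = NA_real_,
                         ionmode = "unknown", smiles = NA_character_,
                         inchi = NA_character_, inchikey = NA_character_,
                         metadata = list()) {
  .assert(length(mz) == length(intensity),
          "mz and intensity must have equal length")
  .assert(all(is.finite(mz)) && all(is.finite(intensity)),
          "mz and intensity must be finite")
  .assert(all(intensity >= 0), "intensities must be non-negative")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(rowsum(intensity, group = mz))
    mz <- sort(unique(mz))
  }
  if (!is.na(precursor_mz)) {
    .assert(is.numeric(precursor_mz) && precursor_mz > 0,
            "precursor_mz must be positive when present")
  }
  ionmode <- match.arg(ionmode, c("positive", "negative", "unknown"))
  if (length(metadata)) names(metadata) <- tolower(names(metadata))
  structure(list(
    spectrum_id = as.character(spectrum_id),
    mz = as.numeric(mz),
    intensity = as.numeric(intensity),
    precursor_mz = as.numeric(precursor_mz),
    ionmode = ionmode,
    smiles = smiles,
    inchi = inchi,
    inchikey = inchikey,
    metadata = metadata
  ), class = "ms2_spectrum")
}

#' @exportS3Method base::print
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum %s> %d peaks, precursor m/z %s, %s mode%s\n",
              x$spectrum_id, length(x$mz),
              ifelse(is.na(x$precursor_mz), "NA",
                     format(x$precursor_mz, digits = 8)),
              x$ionmode,
              if (is_cleaned(x)) ", cleaned" else ""))
  invisible(x)
}

#' @export
length.ms2_spectrum <- function(x) length(x$mz)

is_cleaned <- function(s) isTRUE(attr(s, "cleaned"))

#' Split spectra by ionisation mode
#'
#' Library building and searching operate on a single ionisation mode;
#' spectra with unknown mode are set aside.
#'
#' @param spectra list of [ms2_spectrum] objects.
#' @return list with components `positive`, `negative` and `dropped`, each a
#'   list of spectra; every input spectrum appears in exactly one component.
#' @export
partition_by_ionmode <- function(spectra) {
  modes <- vapply(spectra, function(s) s$ionmode, character(1))
  list(positive = spectra[modes == "positive"],
       negative = spectra[modes == "negative"],
       dropped  = spectra[!modes %in% c("positive", "negative")])
}

#' Test whether a spectrum is fully annotated
#'
#' A spectrum counts as fully annotated when it carries a SMILES, an InChI
#' and an InChIKey that all look chemically valid: the InChIKey matches the
#' 14-10-1 block pattern, the InChI has the standard prefix and formula
#' layer, and fingerprint computation from the SMILES succeeds.
#'
#' @param s an [ms2_spectrum].
#' @return `TRUE` or `FALSE`.
#' @export
is_fully_annotated <- function(s) {
  ok_str <- function(x) length(x) == 1 && !is.na(x) && nzchar(x)
  if (!ok_str(s$smiles) || !ok_str(s$inchi) || !ok_str(s$inchikey))
    return(FALSE)
  if (!grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", toupper(s$inchikey)))
    return(FALSE)
  if (!grepl("^InChI=1S?/.+", s$inchi)) return(FALSE)
  fp <- tryCatch(compute_fingerprint(s$smiles), error = function(e) NULL)
  !is.null(fp) && sum(fp) > 0
}
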