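#' Clean the peak list of a spectrum
#'
#' Applies the library cleaning rules in a fixed order:
#' 1. peaks above 1000 Da are removed;
#' 2. intensities are normalised to the (remaining) base peak, so the
#'    maximum intensity is 1.0;
#' 3. peaks with a normalised intensity below 0.1% of the base peak
#'    (strictly `< 0.001`; exactly 0.001 is kept) are removed;
#' 4. if more than 500 peaks remain, only the 500 most intense are kept
#'    (ties broken towards lower m/z);
#' 5. spectra left with fewer than 3 peaks are rejected outright.
#'
#' Normalisation is re-applied after step 4 removals so the returned
#' spectrum always has base-peak intensity exactly 1.0. Spectra with an
#' unknown ionisation mode are rejected, since a cleaned library is always
#' single-mode.
#'
#' @param s an [ms2_spectrum] with at least one peak.
#' @return The cleaned spectrum (class `ms2_spectrum`, attribute
#'   `cleaned = TRUE`), or `NULL` when the spectrum is rejected.
#' @export
clean_peaks <- function(s) {
  .assert(inherits(s, "ms2_spectrum"), "s must be an ms2_spectrum")
  .assert(length(s$mz) >= 1, "spectrum has no peaks")
  keep <- s$mz <= 1000
  mz <- s$mz[keep]; int <- s$intensity[keep]
  if (length(mz) == 0 || max(int) <= 0) return(NULL)
  int <- int / max(int)
  keep <- int >= 0.001
  mz <- mz[keep]; int <- int[keep]
  if (length(mz) > 500) {
    # rank by intensity desc, ties towards lower m/z; keep top 500
    o <- order(-int, mz)
    keep_idx <- sort(o[seq_len(500)])
    mz <- mz[keep_idx]; int <- int[keep_idx]
  }
  if (length(mz) < 3) return(NULL)
  if (s$ionmode == "unknown") return(NULL)
  int <- int / max(int)
  out <- s
  out$mz <- mz
  out$intensity <- int
  attr(out, "cleaned") <- TRUE
  out
}

#' Clean a batch of spectra
#'
#' Runs [clean_peaks()] over a list of spectra and separates accepted from
#' rejected records.
#'
#' @param spectra list of [ms2_spectrum] objects.
#' @return list with `cleaned` (list of cleaned spectra) and `rejected`
#'   (data.frame with columns `spectrum_id`, `reason`).
#' @export
clean_spectra <- function(spectra) {
  cleaned <- list(); rej_id <- character(0); rej_why <- character(0)
  for (s in spectra) {
    if (length(s$mz) == 0) {
      rej_id <- c(rej_id, s$spectrum_id); rej_why <- c(rej_why, "no peaks")
      next
    }
    cs <- clean_peaks(s)
    if (is.null(cs)) {
      why <- if (s$ionmode == "unknown") "unknown ionmode"
             else "fewer than 3 peaks after cleaning"
      rej_id <- c(rej_id, s$spectrum_id); rej_why <- c(rej_why, why)
    } else {
      cleaned[[length(cleaned) + 1L]] <- cs
    }
  }
  list(cleaned = cleaned,
       rejected = data.frame(spectrum_id = rej_id, reason = rej_why,
                             stringsAsFactors = FALSE))
}

#' Write a rejected-spectrum report
#'
#' @param rejected data.frame as returned in `clean_spectra()$rejected`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_rejected_csv <- function(rejected, path) {
  utils::write.csv(rejected, path, row.names = FALSE)
  invisible(path)
}
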