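#' Build a searchable spectral library
#'
#' Precomputes everything a search needs so that query time touches no
#' spectral preprocessing: embedding matrices for both similarity roles,
#' a metadata table keyed by spectrum id (precursor m/z first, since it is
#' the only metadata required during scoring), the unique-2D-structure
#' table with representative SMILES/InChI (modal rule) and fingerprints,
#' and the precomputed top-`related_k` related-structure table used by
#' ranker features 4 and 5.
#'
#' @param spectra list of cleaned, fully annotated spectra of a single
#'   ionisation mode.
#' @param primary embedding model with role `primary_similarity` (used for
#'   preselection and feature 4).
#' @param secondary embedding model with role `secondary_similarity`
#'   (feature 1).
#' @param out_path optional directory; when given, the store is written
#'   there with [save_library()].
#' @param related_k neighbours kept per structure (default 10).
#' @param include_self whether a structure is its own first related
#'   neighbour (default TRUE).
#' @param fingerprints optional named list (`inchikey14` ->
#'   `ms2_fingerprint`) overriding fingerprint computation (synthetic
#'   ground truth).
#' @param f4_variant aggregation used for ranker feature 4:
#'   `"structure_mean"` (default; mean of per-structure mean scores),
#'   `"tanimoto_weighted"` (structures weighted by their Tanimoto to the
#'   candidate) or `"spectrum_mean"` (every neighbour spectrum weighted
#'   equally). Recorded in the manifest, so it is part of the parameter
#'   hash a ranker is tied to.
#' @return an `ms2_library` object.
#' @export
build_library <- function(spectra, primary, secondary, out_path = NULL,
                          related_k = 10, include_self = TRUE,
                          fingerprints = NULL,
                          f4_variant = c("structure_mean",
                                         "tanimoto_weighted",
                                         "spectrum_mean")) {
  f4_variant <- match.arg(f4_variant)
  .assert(length(spectra) >= 1, "empty spectrum list")
  .assert(primary$role == "primary_similarity",
          "primary model has wrong role")
  .assert(secondary$role == "secondary_similarity",
          "secondary model has wrong role")
  modes <- unique(vapply(spectra, function(s) s$ionmode, character(1)))
  .assert(length(modes) == 1 && modes %in% c("positive", "negative"),
          paste0("library spectra must share one ionmode, got: ",
                 paste(modes, collapse = ", ")))
  for (s in spectra) {
    if (!is_fully_annotated(s) &&
        is.null(fingerprints[[tryCatch(inchikey14(s$inchikey),
                                       error = function(e) "")]])) {
      stop("spectrum is not fully annotated: ", s$spectrum_id,
           call. = FALSE)
    }
  }
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  .assert(!anyDuplicated(ids), "duplicate spectrum ids")
  spectra <- spectra[order(ids)]          # canonical row order
  ids <- sort(ids)

  emb_p <- embed_matrix(primary, spectra)
  emb_s <- embed_matrix(secondary, spectra)

  structures <- collapse_structures(spectra, fingerprints = fingerprints)
  struct_keys <- vapply(structures, function(s) s$inchikey14, character(1))
  spec_keys <- vapply(spectra, function(s) inchikey14(s$inchikey),
                      character(1))
  struct_index <- match(spec_keys, struct_keys)

  tm <- tanimoto_matrix(structures)
  related <- lapply(struct_keys, function(k)
    top_related_structures(k, structures, k = related_k,
                           include_self = include_self, tm = tm))
  names(related) <- struct_keys

  meta <- data.frame(
    spectrum_id = ids,
    precursor_mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
    inchikey = vapply(spectra, function(s) s$inchikey, character(1)),
    inchikey14 = spec_keys,
    smiles = vapply(spectra, function(s) s$smiles %||% NA_character_,
                    character(1)),
    inchi = vapply(spectra, function(s) s$inchi %||% NA_character_,
                   character(1)),
    compound_name = vapply(spectra, function(s)
      s$metadata[["compound_name"]] %||% s$metadata[["name"]] %||%
        NA_character_, character(1)),
    metadata_json = vapply(spectra, function(s)
      as.character(jsonlite::toJSON(s$metadata, auto_unbox = TRUE)),
      character(1)),
    stringsAsFactors = FALSE)

  manifest <- list(
    format_version = 1L,
    ionmode = modes,
    n_spectra = length(spectra),
    n_structures = length(structures),
    related_k = as.integer(related_k),
    include_self = isTRUE(include_self),
    f4_variant = f4_variant,
    primary_model = c(list(name = primary$name, dim = primary$dim),
                      primary$params),
    secondary_model = c(list(name = secondary$name, dim = secondary$dim),
                        secondary$params))
  manifest$parameter_hash <- .manifest_hash(manifest)
  manifest$build_timestamp <- format(Sys.time(), tz = "UTC",
                                     "%Y-%m-%dT%H:%M:%SZ")

  lib <- structure(list(
    ionmode = modes, meta = meta,
    emb_primary = emb_p, emb_secondary = emb_s,
    structures = structures, struct_keys = struct_keys,
    struct_index = struct_index, related = related,
    primary_model = primary, secondary_model = secondary,
    manifest = manifest), class = "ms2_library")
  lib <- .precompute_related_features(lib)
  if (!is.null(out_path)) save_library(lib, out_path)
  lib
}

# Hash of everything that determines search behaviour (not the timestamp).
.manifest_hash <- function(manifest) {
  manifest$parameter_hash <- NULL
  manifest$build_timestamp <- NULL
  fields <- manifest[order(names(manifest))]
  sprintf("%010.0f", fnv1a(as.character(
    jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA))))
}

# Per-structure aggregation helpers reused by every feature computation:
# the neighbour index list, the mean neighbour Tanimoto (feature 5, a
# constant per structure) and the spectrum counts per structure.
.precompute_related_features <- function(lib) {
  nidx <- lapply(lib$related, function(r)
    match(r$neighbours$inchikey14, lib$struct_keys))
  lib$related_idx <- nidx
  lib$related_f5 <- vapply(lib$related, function(r)
    mean(r$neighbours$tanimoto), numeric(1))
  lib$struct_sizes <- tabulate(lib$struct_index,
                               nbins = length(lib$struct_keys))
  lib
}

#' @exportS3Method base::print
print.ms2_library <- function(x, ...) {
  cat(sprintf(
    "<ms2_library> %d spectra, %d structures, %s mode, models: %s / %s\n",
    nrow(x$meta), length(x$structures), x$ionmode,
    x$primary_model$name, x$secondary_model$name))
  invisible(x)
}

.write_matrix_bin <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(dim(m)), con, size = 4L, endian = "little")
  writeBin(as.numeric(m), con, size = 8L, endian = "little")
  invisible(path)
}

.read_matrix_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  d <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  vals <- readBin(con, "double", n = d[1] * d[2], size = 8L,
                  endian = "little")
  matrix(vals, nrow = d[1], ncol = d[2])
}

#' Write a library store to disk
#'
#' The store is a directory: `spectra.csv` (metadata, precursor m/z
#' column first after the id), `structures.csv` (fingerprints as
#' space-separated set-bit positions), `related.csv`,
#' `embeddings_primary.bin` / `embeddings_secondary.bin` (raw
#' little-endian doubles with a dimension header) and `manifest.json`.
#' Rebuilding from identical inputs reproduces every file byte for byte
#' except the manifest timestamp.
#'
#' @param lib an `ms2_library`.
#' @param path directory to create/populate.
#' @return the path, invisibly.
#' @export
save_library <- function(lib, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta_out <- lib$meta
  # 17 significant digits: doubles survive the text round-trip exactly
  meta_out$precursor_mz <- sprintf("%.17g", meta_out$precursor_mz)
  utils::write.csv(meta_out, file.path(path, "spectra.csv"),
                   row.names = FALSE)
  st <- do.call(rbind, lapply(lib$structures, function(s)
    data.frame(inchikey14 = s$inchikey14,
               representative_smiles = s$representative_smiles,
               representative_inchi = s$representative_inchi,
               n_spectra = length(s$spectrum_ids),
               spectrum_ids = paste(s$spectrum_ids, collapse = " "),
               fingerprint_bits = paste(unclass(s$fingerprint),
                                        collapse = " "),
               nbits = attr(s$fingerprint, "nbits"),
               stringsAsFactors = FALSE)))
  utils::write.csv(st, file.path(path, "structures.csv"),
                   row.names = FALSE)
  write_related_csv(lib$related, file.path(path, "related.csv"))
  .write_matrix_bin(lib$emb_primary,
                    file.path(path, "embeddings_primary.bin"))
  .write_matrix_bin(lib$emb_secondary,
                    file.path(path, "embeddings_secondary.bin"))
  jsonlite::write_json(lib$manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a library store from disk
#'
#' Reference embedding models are rebuilt from the manifest parameters;
#' embeddings themselves are read back, never recomputed.
#'
#' @param path store directory written by [save_library()].
#' @return an `ms2_library`.
#' @export
load_library <- function(path) {
  .assert(dir.exists(path), paste0("no such library store: ", path))
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  meta <- utils::read.csv(file.path(path, "spectra.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(spectrum_id = "character"))
  st <- utils::read.csv(file.path(path, "structures.csv"),
                        stringsAsFactors = FALSE)
  structures <- lapply(seq_len(nrow(st)), function(i) list(
    inchikey14 = st$inchikey14[i],
    representative_smiles = st$representative_smiles[i],
    representative_inchi = st$representative_inchi[i],
    fingerprint = as_fingerprint(
      as.integer(strsplit(st$fingerprint_bits[i], " ")[[1]]),
      nbits = st$nbits[i]),
    spectrum_ids = strsplit(st$spectrum_ids[i], " ")[[1]]))
  struct_keys <- st$inchikey14
  rel <- utils::read.csv(file.path(path, "related.csv"),
                         stringsAsFactors = FALSE)
  related <- lapply(struct_keys, function(k) {
    rows <- rel[rel$inchikey14 == k, , drop = FALSE]
    rows <- rows[order(rows$neighbour_rank), , drop = FALSE]
    list(inchikey14 = k,
         neighbours = data.frame(inchikey14 = rows$neighbour_inchikey14,
                                 tanimoto = rows$tanimoto,
                                 stringsAsFactors = FALSE))
  })
  names(related) <- struct_keys
  emb_p <- .read_matrix_bin(file.path(path, "embeddings_primary.bin"))
  emb_s <- .read_matrix_bin(file.path(path, "embeddings_secondary.bin"))
  rownames(emb_p) <- rownames(emb_s) <- meta$spectrum_id
  primary <- model_from_params(manifest$primary_model,
                               role = "primary_similarity")
  secondary <- model_from_params(manifest$secondary_model,
                                 role = "secondary_similarity")
  .assert(primary$dim == ncol(emb_p) && secondary$dim == ncol(emb_s),
          "embedding matrices do not match manifest dimensions")
  lib <- structure(list(
    ionmode = manifest$ionmode, meta = meta,
    emb_primary = emb_p, emb_secondary = emb_s,
    structures = structures, struct_keys = struct_keys,
    struct_index = match(meta$inchikey14, struct_keys),
    related = related,
    primary_model = primary, secondary_model = secondary,
    manifest = manifest), class = "ms2_library")
  .precompute_related_features(lib)
}

#' Look up precursor m/z values by spectrum id
#'
#' @param lib an `ms2_library`.
#' @param spectrum_ids character vector of ids (all must exist).
#' @return numeric vector of precursor m/z values, in input order.
#' @export
get_precursor_mz <- function(lib, spectrum_ids) {
  idx <- match(spectrum_ids, lib$meta$spectrum_id)
  if (anyNA(idx)) {
    stop("unknown spectrum id(s): ",
         paste(spectrum_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lib$meta$precursor_mz[idx]
}

#' Look up the related-structure entry of an inchikey14
#'
#' @param lib an `ms2_library`.
#' @param key inchikey14 present in the library.
#' @return list with `inchikey14` and `neighbours`.
#' @export
get_related <- function(lib, key) {
  r <- lib$related[[key]]
  if (is.null(r)) stop("unknown inchikey14: ", key, call. = FALSE)
  r
}

#' Look up metadata rows by spectrum id
#'
#' @param lib an `ms2_library`.
#' @param spectrum_ids character vector of ids (all must exist).
#' @return data.frame of metadata rows in input order.
#' @export
get_metadata <- function(lib, spectrum_ids) {
  idx <- match(spectrum_ids, lib$meta$spectrum_id)
  if (anyNA(idx)) {
    stop("unknown spectrum id(s): ",
         paste(spectrum_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lib$meta[idx, , drop = FALSE]
}
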