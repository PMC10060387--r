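#' Chemical-structure handling
#'
#' Library structures are collapsed to unique 2D structures by the first
#' 14 characters of the InChIKey, each carrying a 2048-bit hashed
#' path-based (Daylight-type) fingerprint. Tanimoto scores over these
#' fingerprints serve as the structural-similarity labels for ranker
#' training and for the precomputed top-10 related-structure table.
#'
#' @name chem
NULL

#' First block of an InChIKey
#'
#' The first 14 characters of an InChIKey identify the 2D structure
#' irrespective of stereochemistry and charge.
#'
#' @param inchikey InChIKey string (at least 14 characters).
#' @return upper-cased 14-character string.
#' @export
inchikey14 <- function(inchikey) {
  .assert(is.character(inchikey) && length(inchikey) == 1 &&
            !is.na(inchikey), "inchikey must be a single string")
  .assert(nchar(inchikey) >= 14,
          "inchikey must have at least 14 characters")
  toupper(substr(inchikey, 1, 14))
}

#' Construct a fingerprint object from set-bit positions
#'
#' @param bits integer vector of set-bit positions (1-based).
#' @param nbits total number of bit positions (default 2048).
#' @return object of class `ms2_fingerprint` (sorted unique positions with
#'   an `nbits` attribute).
#' @export
as_fingerprint <- function(bits, nbits = 2048L) {
  bits <- sort(unique(as.integer(bits)))
  .assert(!length(bits) || (min(bits) >= 1 && max(bits) <= nbits),
          "bit positions out of range")
  structure(bits, nbits = as.integer(nbits), class = "ms2_fingerprint")
}

#' @exportS3Method base::print
print.ms2_fingerprint <- function(x, ...) {
  cat(sprintf("<ms2_fingerprint> %d/%d bits set\n", length(unclass(x)),
              attr(x, "nbits")))
  invisible(x)
}

.fp_bits <- function(fp) {
  if (inherits(fp, "ms2_fingerprint")) {
    list(bits = as.integer(unclass(fp)), nbits = attr(fp, "nbits"))
  } else {
    v <- as.numeric(fp)
    .assert(all(v %in% c(0, 1)), "dense fingerprint must be 0/1")
    list(bits = which(v == 1), nbits = length(v))
  }
}

#' Hashed path-based fingerprint of a molecule
#'
#' Enumerates all simple linear paths of 0 to `max_path` bonds in the
#' molecular graph, hashes each canonical path string and sets
#' `bits_per_path` bit positions per path in a `nbits`-wide vector —
#' the classic Daylight-style scheme. Deterministic: the same SMILES
#' always yields the same bits.
#'
#' @param smiles SMILES string (parsed with [parse_smiles()]).
#' @param nbits fingerprint width (default 2048).
#' @param max_path maximum path length in bonds (default 7).
#' @param bits_per_path bits set per distinct path (default 2).
#' @return an `ms2_fingerprint`.
#' @export
compute_fingerprint <- function(smiles, nbits = 2048L, max_path = 7L,
                                bits_per_path = 2L) {
  mol <- parse_smiles(smiles)
  na <- nrow(mol$atoms)
  adj <- vector("list", na)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      f <- mol$bonds$from[b]; t <- mol$bonds$to[b]
      adj[[f]] <- rbind(adj[[f]], c(t, b))
      adj[[t]] <- rbind(adj[[t]], c(f, b))
    }
  }
  atom_label <- ifelse(mol$atoms$aromatic, tolower(mol$atoms$symbol),
                       mol$atoms$symbol)
  chg <- mol$atoms$charge
  atom_label <- paste0(atom_label,
                       ifelse(chg > 0, strrep("+", chg),
                              ifelse(chg < 0, strrep("-", -chg), "")))
  bond_label <- c("1" = "-", "2" = "=", "3" = "#", "4" = "$", "1.5" = ":")
  paths <- character(0)
  # DFS over simple paths from every atom
  walk <- function(path_atoms, path_bonds) {
    labs_a <- atom_label[path_atoms]
    labs_b <- if (length(path_bonds))
      bond_label[as.character(mol$bonds$order[path_bonds])] else character(0)
    fwd <- paste0(labs_a, c(labs_b, ""), collapse = "")
    rev_ <- paste0(rev(labs_a), c(rev(labs_b), ""), collapse = "")
    paths[[length(paths) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    if (length(path_bonds) >= max_path) return()
    last <- path_atoms[length(path_atoms)]
    nb <- adj[[last]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (!nxt %in% path_atoms) {
        walk(c(path_atoms, nxt), c(path_bonds, nb[r, 2]))
      }
    }
  }
  for (a in seq_len(na)) walk(a, integer(0))
  paths <- unique(paths)
  bits <- integer(0)
  for (p in paths) {
    for (k in seq_len(bits_per_path)) {
      bits <- c(bits, as.integer(fnv1a(p, seed = 2166136261 + 97 * k)
                                 %% nbits) + 1L)
    }
  }
  as_fingerprint(bits, nbits = nbits)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A AND B| / |A OR B|` over the set bits; defined as 0 when both
#' fingerprints are empty.
#'
#' @param a,b fingerprints (`ms2_fingerprint` objects or dense 0/1
#'   vectors). Widths must agree.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  fa <- .fp_bits(a); fb <- .fp_bits(b)
  .assert(fa$nbits == fb$nbits, "fingerprint lengths differ")
  u <- length(union(fa$bits, fb$bits))
  if (u == 0) return(0)
  length(intersect(fa$bits, fb$bits)) / u
}

#' Pairwise Tanimoto matrix over structure records
#'
#' @param structures list of structure records as produced by
#'   [collapse_structures()], or a plain list of fingerprints.
#' @return symmetric numeric matrix with unit diagonal (for non-empty
#'   fingerprints), dimnames set to the structure keys when available.
#' @export
tanimoto_matrix <- function(structures) {
  .assert(length(structures) >= 1, "need at least one structure")
  fps <- lapply(structures, function(s)
    if (inherits(s, "ms2_fingerprint")) s else s$fingerprint)
  keys <- vapply(structures, function(s)
    if (is.list(s) && !is.null(s$inchikey14)) s$inchikey14 else NA_character_,
    character(1))
  n <- length(fps)
  nbits <- attr(fps[[1]], "nbits")
  ii <- unlist(lapply(seq_len(n), function(i) rep(i, length(unclass(fps[[i]])))))
  jj <- unlist(lapply(fps, unclass))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, nbits))
  inter <- as.matrix(Matrix::tcrossprod(A))
  sizes <- vapply(fps, function(f) length(unclass(f)), numeric(1))
  un <- outer(sizes, sizes, "+") - inter
  M <- ifelse(un == 0, 0, inter / un)
  if (!anyNA(keys)) dimnames(M) <- list(keys, keys)
  M
}

#' Representative structure of an InChIKey group
#'
#' When several spectra share an inchikey14, the modal InChI within the
#' group is selected and its SMILES/InChI used for the whole group. Ties
#' are broken towards the first-encountered InChI in library order.
#'
#' @param spectra non-empty list of annotated spectra sharing an
#'   inchikey14.
#' @return list with `smiles` and `inchi`.
#' @export
select_representative_structure <- function(spectra) {
  .assert(length(spectra) >= 1, "empty structure group")
  keys <- vapply(spectra, function(s) inchikey14(s$inchikey), character(1))
  .assert(length(unique(keys)) == 1,
          "spectra do not share a single inchikey14")
  inchis <- vapply(spectra, function(s) s$inchi, character(1))
  u <- unique(inchis)                       # first-occurrence order
  counts <- tabulate(match(inchis, u), nbins = length(u))
  best <- u[which.max(counts)]              # first max wins ties
  rep_idx <- which(inchis == best)[1]
  list(smiles = spectra[[rep_idx]]$smiles, inchi = best)
}

#' Collapse annotated spectra into unique 2D structure records
#'
#' Groups spectra by inchikey14 and builds one structure record per group:
#' the representative SMILES/InChI (modal rule), the fingerprint, and the
#' ids of all member spectra. Records are returned sorted by inchikey14.
#'
#' @param spectra list of annotated spectra.
#' @param fingerprints optional named list (`inchikey14` ->
#'   `ms2_fingerprint`) overriding fingerprint computation — used by the
#'   synthetic generator to keep ground-truth chemistry exact.
#' @return list of structure records (`inchikey14`,
#'   `representative_smiles`, `representative_inchi`, `fingerprint`,
#'   `spectrum_ids`).
#' @export
collapse_structures <- function(spectra, fingerprints = NULL) {
  .assert(length(spectra) >= 1, "no spectra")
  keys <- vapply(spectra, function(s) inchikey14(s$inchikey), character(1))
  out <- list()
  for (k in sort(unique(keys))) {
    members <- spectra[keys == k]
    rep_s <- select_representative_structure(members)
    fp <- if (!is.null(fingerprints) && !is.null(fingerprints[[k]])) {
      fingerprints[[k]]
    } else {
      compute_fingerprint(rep_s$smiles)
    }
    out[[length(out) + 1L]] <- list(
      inchikey14 = k,
      representative_smiles = rep_s$smiles,
      representative_inchi = rep_s$inchi,
      fingerprint = fp,
      spectrum_ids = vapply(members, function(s) s$spectrum_id,
                            character(1)))
  }
  out
}

#' Top related structures for one library structure
#'
#' The `k` library structures with the highest Tanimoto score to the
#' target, in descending order. By default the target itself is eligible
#' and, having Tanimoto 1, ranks first; set `include_self = FALSE` to
#' exclude it. Ties are broken lexicographically by inchikey14.
#'
#' @param target inchikey14 of the target structure (must be present).
#' @param structures list of structure records.
#' @param k number of neighbours to keep (default 10).
#' @param include_self whether the target itself may appear (default TRUE).
#' @param tm optional precomputed [tanimoto_matrix()] over `structures`.
#' @return list with `inchikey14` and `neighbours` (data.frame:
#'   `inchikey14`, `tanimoto`, descending).
#' @export
top_related_structures <- function(target, structures, k = 10,
                                   include_self = TRUE, tm = NULL) {
  keys <- vapply(structures, function(s) s$inchikey14, character(1))
  ti <- match(target, keys)
  .assert(!is.na(ti), paste0("target structure not in library: ", target))
  sims <- if (!is.null(tm)) tm[ti, ] else
    vapply(structures, function(s)
      tanimoto(structures[[ti]]$fingerprint, s$fingerprint), numeric(1))
  cand <- seq_along(structures)
  if (!include_self) cand <- cand[cand != ti]
  o <- cand[order(-sims[cand], keys[cand])]
  o <- o[seq_len(min(k, length(o)))]
  list(inchikey14 = target,
       neighbours = data.frame(inchikey14 = keys[o],
                               tanimoto = as.numeric(sims[o]),
                               stringsAsFactors = FALSE))
}

#' Export a related-structure table as CSV
#'
#' @param related list of related-structure entries (as stored in a
#'   library).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_related_csv <- function(related, path) {
  rows <- do.call(rbind, lapply(related, function(r) {
    data.frame(inchikey14 = r$inchikey14,
               neighbour_rank = seq_len(nrow(r$neighbours)),
               neighbour_inchikey14 = r$neighbours$inchikey14,
               tanimoto = sprintf("%.17g", r$neighbours$tanimoto),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
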