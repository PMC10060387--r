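#' Configuration for the synthetic spectral-library generator
#'
#' The generator emulates an annotated MS/MS spectral library with known
#' ground-truth chemistry: clusters of related "structures" whose
#' fingerprints (and hence pairwise Tanimoto scores) are exactly known,
#' several noisy replicate spectra per structure whose spectral
#' similarity tracks chemical similarity, and precursor masses that are a
#' deterministic function of the fingerprint, so chemically similar
#' structures have nearby precursors. Defaults give within-cluster
#' Tanimoto scores of roughly 0.6-0.9 (the analogue regime) at desk
#' scale: 30 clusters x 10 structures x 3 replicates = 900 spectra.
#'
#' @param n_clusters number of structure clusters (default 30).
#' @param structures_per_cluster structures per cluster (default 10).
#' @param spectra_per_structure replicate spectra per structure
#'   (default 3).
#' @param fp_bits fingerprint width (default 2048).
#' @param fp_density fraction of bits set in a cluster centre
#'   (default 0.05).
#' @param mutation_bits bits flipped per cluster member (default 20).
#' @param peak_dropout_prob per-peak dropout probability per replicate
#'   (default 0.1).
#' @param intensity_jitter_sd log-normal intensity jitter sd
#'   (default 0.2).
#' @param noise_peaks_per_spectrum uniform-m/z noise peaks added per
#'   replicate (default 3).
#' @param seed integer master seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 30, structures_per_cluster = 10,
                             spectra_per_structure = 3, fp_bits = 2048,
                             fp_density = 0.05, mutation_bits = 20,
                             peak_dropout_prob = 0.1,
                             intensity_jitter_sd = 0.2,
                             noise_peaks_per_spectrum = 3, seed = 1) {
  cfg <- list(n_clusters = n_clusters,
              structures_per_cluster = structures_per_cluster,
              spectra_per_structure = spectra_per_structure,
              fp_bits = fp_bits, fp_density = fp_density,
              mutation_bits = mutation_bits,
              peak_dropout_prob = peak_dropout_prob,
              intensity_jitter_sd = intensity_jitter_sd,
              noise_peaks_per_spectrum = noise_peaks_per_spectrum,
              seed = as.integer(seed))
  .assert(all(vapply(cfg[1:6], function(x) x >= 1 || x > 0, logical(1))),
          "counts must be >= 1 and densities positive")
  .assert(peak_dropout_prob >= 0 && peak_dropout_prob <= 1 &&
            fp_density > 0 && fp_density <= 1,
          "probabilities must lie in [0, 1]")
  .assert(mutation_bits < fp_bits, "mutation_bits must be < fp_bits")
  structure(cfg, class = "synthetic_config")
}

# Deterministic per-bit constants (independent of any RNG state).
.bit_mass <- function(bit) 0.2 + 2.0 * .hash_frac(bit, salt = 11)
.bit_mz <- function(bit, fp_bits) {
  b <- bit - 1
  50 + 0.95 * (b %% 950) + 0.3 * (b %/% 950) + 0.04 * .hash_frac(b, salt = 3)
}
.bit_intensity <- function(bit) 0.05 + 0.95 * .hash_frac(bit - 1, salt = 5)

.random_key <- function() paste(sample(LETTERS, 14, replace = TRUE),
                                collapse = "")

#' Generate synthetic structures with known fingerprints
#'
#' Cluster centres draw `fp_density * fp_bits` random set bits; each
#' member structure flips `mutation_bits` random bit positions of its
#' centre, so within-cluster Tanimoto is high while between-cluster
#' similarity sits near the random-overlap baseline. The precursor-ready
#' mass is `100 + sum(bit masses)` over set bits, making similar
#' structures have nearby masses. Each structure carries a surrogate
#' SMILES/InChI/InChIKey so annotation plumbing is exercised; the
#' synthetic fingerprint (not one computed from the surrogate SMILES) is
#' the ground truth.
#'
#' @param cfg a [synthetic_config()].
#' @return list of structures: `key` (synthetic inchikey14), `inchikey`,
#'   `inchi`, `smiles`, `fingerprint`, `mass`, `cluster`.
#' @export
generate_structures <- function(cfg) {
  .assert(inherits(cfg, "synthetic_config"), "cfg must be a synthetic_config")
  n_center_bits <- max(1L, round(cfg$fp_density * cfg$fp_bits))
  with_seed(derive_seed(cfg$seed, "structures"), {
    out <- list()
    seen <- character(0)
    for (cl in seq_len(cfg$n_clusters)) {
      center <- sort(sample.int(cfg$fp_bits, n_center_bits))
      for (m in seq_len(cfg$structures_per_cluster)) {
        flips <- sample.int(cfg$fp_bits, cfg$mutation_bits)
        bits <- sort(union(setdiff(center, flips), setdiff(flips, center)))
        if (!length(bits)) bits <- center  # pathological flip-out
        repeat {
          key <- .random_key()
          if (!key %in% seen) break
        }
        seen <- c(seen, key)
        n_c <- 3 + ((cl * cfg$structures_per_cluster + m) %% 8)
        out[[length(out) + 1L]] <- list(
          key = key,
          inchikey = paste0(key, "-UHFFFAOYSA-N"),
          inchi = sprintf("InChI=1S/C%dH%dO/synthetic-%s", n_c,
                          2 * n_c + 2, key),
          smiles = paste0(strrep("C", n_c), "O"),
          fingerprint = as_fingerprint(bits, nbits = cfg$fp_bits),
          mass = 100 + sum(.bit_mass(bits)),
          cluster = cl)
      }
    }
    out
  })
}

#' Generate one replicate spectrum for a synthetic structure
#'
#' Each set fingerprint bit maps deterministically to one peak (m/z in
#' `[50, 953)` Da, base intensity from a per-bit hash); the replicate
#' then drops peaks with `peak_dropout_prob`, jitters intensities
#' log-normally and adds uniform-m/z noise peaks. The precursor m/z is
#' the structure mass plus 1.007 (protonation). The returned record has
#' passed [clean_peaks()].
#'
#' @param structure one structure from [generate_structures()].
#' @param cfg the [synthetic_config()].
#' @param replicate_index replicate number (also salts the seed).
#' @param seed optional explicit seed; defaults to one derived from
#'   `cfg$seed`, the structure key and the replicate index.
#' @return a cleaned `ms2_spectrum`.
#' @export
generate_spectrum <- function(structure, cfg, replicate_index = 1,
                              seed = NULL) {
  bits <- as.integer(unclass(structure$fingerprint))
  .assert(length(bits) >= 1, "structure has no set fingerprint bits")
  if (is.null(seed)) {
    seed <- derive_seed(cfg$seed,
                        paste0("spec:", structure$key, ":", replicate_index))
  }
  mz <- .bit_mz(bits, cfg$fp_bits)
  int <- .bit_intensity(bits)
  with_seed(seed, {
    keep <- stats::runif(length(mz)) >= cfg$peak_dropout_prob
    if (sum(keep) < 3) keep[order(-int)[1:3]] <- TRUE
    mz_k <- mz[keep]
    int_k <- int[keep] *
      stats::rlnorm(sum(keep), 0, cfg$intensity_jitter_sd)
    if (cfg$noise_peaks_per_spectrum > 0) {
      nmz <- stats::runif(cfg$noise_peaks_per_spectrum, 50, 999.5)
      nint <- stats::runif(cfg$noise_peaks_per_spectrum, 0.01, 0.3) *
        max(int_k)
      mz_k <- c(mz_k, nmz); int_k <- c(int_k, nint)
    }
    s <- ms2_spectrum(
      spectrum_id = paste0(structure$key, "-r", replicate_index),
      mz = mz_k, intensity = int_k,
      precursor_mz = structure$mass + 1.007,
      ionmode = "positive",
      smiles = structure$smiles, inchi = structure$inchi,
      inchikey = structure$inchikey,
      metadata = list(compound_name = paste0("synthetic_", structure$key),
                      cluster = as.character(structure$cluster)))
    cs <- clean_peaks(s)
    .assert(!is.null(cs), "synthetic spectrum rejected by cleaning")
    cs
  })
}

#' Generate a complete synthetic library in memory
#'
#' @param cfg a [synthetic_config()].
#' @return list with `spectra` (cleaned, annotated), `structures`,
#'   `fingerprints` (named list, ground-truth override for
#'   [build_library()]) and `truth` (data.frame: spectrum_id,
#'   inchikey14, cluster, mass).
#' @export
generate_synthetic_library <- function(cfg) {
  structures <- generate_structures(cfg)
  spectra <- list()
  for (st in structures) {
    for (r in seq_len(cfg$spectra_per_structure)) {
      spectra[[length(spectra) + 1L]] <- generate_spectrum(st, cfg, r)
    }
  }
  fingerprints <- stats::setNames(lapply(structures, `[[`, "fingerprint"),
                                  vapply(structures, `[[`, character(1),
                                         "key"))
  truth <- data.frame(
    spectrum_id = vapply(spectra, function(s) s$spectrum_id, character(1)),
    inchikey14 = vapply(spectra, function(s) inchikey14(s$inchikey),
                        character(1)),
    cluster = rep(vapply(structures, `[[`, numeric(1), "cluster"),
                  each = cfg$spectra_per_structure),
    mass = rep(vapply(structures, `[[`, numeric(1), "mass"),
               each = cfg$spectra_per_structure),
    stringsAsFactors = FALSE)
  list(spectra = spectra, structures = structures,
       fingerprints = fingerprints, truth = truth)
}

#' Write a ready-to-run synthetic benchmark suite to disk
#'
#' Produces everything the downstream modules need as plain files: an
#' annotated library MGF, a structure-disjoint analogue query MGF (all
#' spectra of held-out structures), an exact-match query MGF (one extra
#' noisy replicate per sampled library structure), a ground-truth CSV
#' (spectrum -> structure key, cluster, role) and a fingerprint CSV.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @param analogue_holdout fraction of structures held out as analogue
#'   queries (default 0.15).
#' @param n_exact_queries number of library structures receiving an
#'   extra replicate query (default: up to 50).
#' @return named list of file paths plus the record counts.
#' @export
generate_benchmark_suite <- function(cfg, out_dir,
                                     analogue_holdout = 0.15,
                                     n_exact_queries = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .assert(dir.exists(out_dir), paste0("cannot create directory ", out_dir))
  gen <- generate_synthetic_library(cfg)
  keys <- vapply(gen$structures, `[[`, character(1), "key")
  n_hold <- max(1L, ceiling(analogue_holdout * length(keys)))
  hold_keys <- with_seed(derive_seed(cfg$seed, "holdout"),
                         sample(keys, n_hold))
  spec_keys <- vapply(gen$spectra, function(s) inchikey14(s$inchikey),
                      character(1))
  library_spectra <- gen$spectra[!spec_keys %in% hold_keys]
  analogue_queries <- gen$spectra[spec_keys %in% hold_keys]
  lib_structures <- gen$structures[!keys %in% hold_keys]
  n_exact <- min(n_exact_queries, length(lib_structures))
  exact_structs <- with_seed(derive_seed(cfg$seed, "exact"),
                             sample(lib_structures, n_exact))
  exact_queries <- lapply(exact_structs, function(st)
    generate_spectrum(st, cfg,
                      replicate_index = cfg$spectra_per_structure + 1L))
  paths <- list(
    library_mgf = file.path(out_dir, "library.mgf"),
    analogue_queries_mgf = file.path(out_dir, "analogue_queries.mgf"),
    exact_queries_mgf = file.path(out_dir, "exact_queries.mgf"),
    ground_truth_csv = file.path(out_dir, "ground_truth.csv"),
    fingerprints_csv = file.path(out_dir, "fingerprints.csv"))
  write_mgf(library_spectra, paths$library_mgf)
  write_mgf(analogue_queries, paths$analogue_queries_mgf)
  write_mgf(exact_queries, paths$exact_queries_mgf)
  role_of <- function(spectra, role) data.frame(
    spectrum_id = vapply(spectra, function(s) s$spectrum_id, character(1)),
    inchikey14 = vapply(spectra, function(s) inchikey14(s$inchikey),
                        character(1)),
    role = role, stringsAsFactors = FALSE)
  truth <- rbind(role_of(library_spectra, "library"),
                 role_of(analogue_queries, "analogue_query"),
                 role_of(exact_queries, "exact_query"))
  truth <- merge(truth,
                 unique(data.frame(
                   inchikey14 = keys,
                   cluster = vapply(gen$structures, `[[`, numeric(1),
                                    "cluster"),
                   mass = vapply(gen$structures, `[[`, numeric(1), "mass"),
                   stringsAsFactors = FALSE)),
                 by = "inchikey14", sort = FALSE)
  truth <- truth[order(truth$role, truth$spectrum_id), ]
  utils::write.csv(truth, paths$ground_truth_csv, row.names = FALSE)
  write_fingerprints_csv(gen$fingerprints, paths$fingerprints_csv)
  c(paths, list(n_library = length(library_spectra),
                n_analogue_queries = length(analogue_queries),
                n_exact_queries = length(exact_queries)))
}

#' Write / read a ground-truth fingerprint table
#'
#' @param fingerprints named list `inchikey14 -> ms2_fingerprint`.
#' @param path CSV path (columns: inchikey14, nbits, bits as
#'   space-separated positions).
#' @return the path / the named fingerprint list.
#' @export
write_fingerprints_csv <- function(fingerprints, path) {
  df <- data.frame(
    inchikey14 = names(fingerprints),
    nbits = vapply(fingerprints, function(f) attr(f, "nbits"), integer(1)),
    bits = vapply(fingerprints, function(f)
      paste(unclass(f), collapse = " "), character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df[order(df$inchikey14), ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints_csv
#' @export
read_fingerprints_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fps <- lapply(seq_len(nrow(df)), function(i)
    as_fingerprint(as.integer(strsplit(df$bits[i], " ")[[1]]),
                   nbits = df$nbits[i]))
  stats::setNames(fps, df$inchikey14)
}
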