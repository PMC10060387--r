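#' Candidate preselection by primary-embedding similarity
#'
#' Scores the query against every library spectrum by cosine similarity
#' of the primary embeddings — deliberately with no precursor-m/z
#' prefilter, so analogues with large mass shifts stay reachable — and
#' returns the `n` best. The full score vector is kept because features
#' 4 of the ranker reuses these same scores.
#'
#' @param query a cleaned [ms2_spectrum] with ionmode matching the
#'   library.
#' @param lib an `ms2_library`.
#' @param n preselection size (default 2000); if the library is smaller,
#'   all spectra are returned.
#' @return list with `spectrum_ids`, `scores` (descending), `rows`
#'   (library row indices), `all_scores` (full library score vector) and
#'   `query_embedding` (the primary embedding of the query).
#' @export
preselect_candidates <- function(query, lib, n = 2000) {
  .assert(nrow(lib$meta) >= 1, "empty library")
  .assert(query$ionmode == lib$ionmode,
          sprintf("query ionmode (%s) does not match library (%s)",
                  query$ionmode, lib$ionmode))
  q <- embed_spectrum(lib$primary_model, query)
  qn <- sqrt(sum(q^2))
  .assert(qn > 0, "query has a zero primary embedding")
  rn <- sqrt(rowSums(lib$emb_primary^2))
  all_scores <- as.numeric(lib$emb_primary %*% q) / (rn * qn)
  all_scores <- pmax(-1, pmin(1, all_scores))
  o <- order(-all_scores, lib$meta$spectrum_id)
  o <- o[seq_len(min(n, length(o)))]
  list(spectrum_ids = lib$meta$spectrum_id[o],
       scores = all_scores[o], rows = o, all_scores = all_scores,
       query_embedding = q)
}

# Mean primary score per structure, then per-structure neighbourhood
# average: the heart of features 4 and 5.
.structure_means <- function(lib, all_scores) {
  as.numeric(rowsum(all_scores, group = lib$struct_index,
                    reorder = TRUE)) / lib$struct_sizes
}

# Feature-4 aggregation over a structure's related neighbourhood. The
# default averages the per-structure means; the documented alternatives
# weight structures by their Tanimoto to the candidate, or weight every
# spectrum equally (pooled mean).
.f4_aggregate <- function(lib, sm, t_idx) {
  nb <- lib$related_idx[[t_idx]]
  variant <- lib$manifest$f4_variant %||% "structure_mean"
  switch(variant,
         structure_mean = mean(sm[nb]),
         tanimoto_weighted = {
           w <- lib$related[[t_idx]]$neighbours$tanimoto
           sum(w * sm[nb]) / sum(w)
         },
         spectrum_mean = {
           n <- lib$struct_sizes[nb]
           sum(n * sm[nb]) / sum(n)
         },
         stop("unknown f4_variant: ", variant, call. = FALSE))
}

#' Feature vector for one query-candidate pair
#'
#' The five ranker inputs, in fixed order:
#' \describe{
#'   \item{f1_secondary_similarity}{secondary-embedding cosine between
#'     query and candidate spectrum.}
#'   \item{f2_query_precursor_mz}{the query's precursor m/z in Da.}
#'   \item{f3_precursor_mz_difference}{absolute precursor m/z difference
#'     in Da.}
#'   \item{f4_avg_primary_similarity_related}{mean, over the candidate
#'     structure's (up to 10) related structures, of the mean primary
#'     similarity between the query and all spectra of that structure;
#'     preselection-time primary scores are reused.}
#'   \item{f5_avg_tanimoto_related}{mean Tanimoto between the candidate
#'     structure and its related structures.}
#' }
#'
#' @param query cleaned query spectrum.
#' @param candidate_id library spectrum id (must be in the preselection).
#' @param lib an `ms2_library`.
#' @param preselection result of [preselect_candidates()] for this query.
#' @return named numeric vector of length 5.
#' @export
compute_feature_vector <- function(query, candidate_id, lib,
                                   preselection) {
  .assert(candidate_id %in% preselection$spectrum_ids,
          "candidate is not in the preselection")
  row <- match(candidate_id, lib$meta$spectrum_id)
  t_idx <- lib$struct_index[row]
  nb <- lib$related_idx[[t_idx]]
  .assert(!is.null(nb), "missing related-structure entry")
  sm <- .structure_means(lib, preselection$all_scores)
  q_sec <- embed_spectrum(lib$secondary_model, query)
  f1 <- embedding_similarity(q_sec, lib$emb_secondary[row, ])
  f3 <- abs(query$precursor_mz - lib$meta$precursor_mz[row])
  c(f1_secondary_similarity = f1,
    f2_query_precursor_mz = query$precursor_mz,
    f3_precursor_mz_difference = f3,
    f4_avg_primary_similarity_related = .f4_aggregate(lib, sm, t_idx),
    f5_avg_tanimoto_related = lib$related_f5[[t_idx]])
}

# Vectorised feature computation for all preselected candidates.
# `sec_scores` is the secondary-similarity vector against the whole
# library (query row of emb_secondary %*% q); computed here if missing.
.feature_matrix <- function(lib, preselection, query_precursor,
                            sec_scores) {
  rows <- preselection$rows
  sm <- .structure_means(lib, preselection$all_scores)
  f4_struct <- vapply(seq_along(lib$related_idx), function(t)
    .f4_aggregate(lib, sm, t), numeric(1))
  t_idx <- lib$struct_index[rows]
  cbind(f1_secondary_similarity = sec_scores[rows],
        f2_query_precursor_mz = rep(query_precursor, length(rows)),
        f3_precursor_mz_difference =
          abs(query_precursor - lib$meta$precursor_mz[rows]),
        f4_avg_primary_similarity_related = f4_struct[t_idx],
        f5_avg_tanimoto_related = lib$related_f5[t_idx])
}

.secondary_scores <- function(lib, q_sec) {
  qn <- sqrt(sum(q_sec^2))
  rn <- sqrt(rowSums(lib$emb_secondary^2))
  pmax(-1, pmin(1, as.numeric(lib$emb_secondary %*% q_sec) / (rn * qn)))
}

#' Generate ranker training pairs from a library
#'
#' Draws a query pool from the library itself: all spectra of a random
#' `inchikey_fraction` of unique structures, plus a random
#' `spectrum_fraction` of the remaining spectra (counts rounded up so
#' small libraries still yield a pool). Each pooled spectrum is paired
#' with the `top_n` library spectra of highest primary-embedding score
#' (itself included); the label is the Tanimoto score between the two
#' structures.
#'
#' @param lib an `ms2_library`.
#' @param inchikey_fraction fraction of unique structures pooled
#'   (default 1/40).
#' @param spectrum_fraction fraction of the remaining spectra pooled
#'   (default 1/40).
#' @param top_n pairs per pooled spectrum (default 100).
#' @param seed integer seed for the pool sampling.
#' @return data.frame with columns `query_spectrum_id`,
#'   `library_spectrum_id`, the five features and `label`.
#' @export
generate_training_pairs <- function(lib, inchikey_fraction = 1 / 40,
                                    spectrum_fraction = 1 / 40,
                                    top_n = 100, seed = 1) {
  n_spec <- nrow(lib$meta)
  n_struct <- length(lib$struct_keys)
  n_pick_struct <- ceiling(n_struct * inchikey_fraction)
  pool <- with_seed(seed, {
    picked <- sample.int(n_struct, n_pick_struct)
    rows1 <- which(lib$struct_index %in% picked)
    remaining <- setdiff(seq_len(n_spec), rows1)
    n_pick_spec <- ceiling(length(remaining) * spectrum_fraction)
    rows2 <- if (length(remaining))
      sort(sample(remaining, n_pick_spec)) else integer(0)
    sort(unique(c(rows1, rows2)))
  })
  if (!length(pool)) {
    stop("empty training pool; increase the sampling fractions for this ",
         "library size", call. = FALSE)
  }
  tm <- tanimoto_matrix(lib$structures)
  rn_p <- sqrt(rowSums(lib$emb_primary^2))
  rn_s <- sqrt(rowSums(lib$emb_secondary^2))
  out <- vector("list", length(pool))
  for (j in seq_along(pool)) {
    i <- pool[j]
    qi <- lib$emb_primary[i, ]
    all_scores <- pmax(-1, pmin(1, as.numeric(lib$emb_primary %*% qi) /
                                  (rn_p * rn_p[i])))
    o <- order(-all_scores, lib$meta$spectrum_id)
    o <- o[seq_len(min(top_n, length(o)))]
    presel <- list(rows = o, all_scores = all_scores)
    sec_scores <- pmax(-1, pmin(1,
      as.numeric(lib$emb_secondary %*% lib$emb_secondary[i, ]) /
        (rn_s * rn_s[i])))
    fm <- .feature_matrix(lib, presel, lib$meta$precursor_mz[i],
                          sec_scores)
    lab <- tm[lib$struct_index[i], lib$struct_index[o]]
    out[[j]] <- data.frame(
      query_spectrum_id = lib$meta$spectrum_id[i],
      library_spectrum_id = lib$meta$spectrum_id[o],
      fm, label = as.numeric(lab), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.FEATURE_NAMES <- c("f1_secondary_similarity", "f2_query_precursor_mz",
                    "f3_precursor_mz_difference",
                    "f4_avg_primary_similarity_related",
                    "f5_avg_tanimoto_related")

#' Train the re-ranking model
#'
#' Fits the random-forest regressor (squared-error loss, 250 trees, max
#' depth 5 by default) that predicts the Tanimoto score between query and
#' candidate structures from the five features. Deterministic given
#' `seed`.
#'
#' @param pairs training pairs from [generate_training_pairs()] (at least
#'   100 rows).
#' @param n_estimators trees (default 250).
#' @param max_depth maximum depth (default 5).
#' @param seed integer seed.
#' @param library_hash optional parameter hash of the library the pairs
#'   came from; recorded so that [search()] can refuse a mismatched
#'   store/model combination.
#' @return an `ms2_ranker`.
#' @export
train_ranker <- function(pairs, n_estimators = 250, max_depth = 5,
                         seed = 1, library_hash = NULL) {
  .assert(nrow(pairs) >= 100,
          "need at least 100 training pairs")
  X <- as.matrix(pairs[, .FEATURE_NAMES])
  bad <- which(!stats::complete.cases(X) | !is.finite(pairs$label))
  if (length(bad)) {
    stop("non-finite feature or label in training pair ",
         pairs$query_spectrum_id[bad[1]], " / ",
         pairs$library_spectrum_id[bad[1]], call. = FALSE)
  }
  rf <- rf_fit(X, pairs$label, n_estimators = n_estimators,
               max_depth = max_depth, seed = seed)
  structure(list(rf = rf, feature_names = .FEATURE_NAMES,
                 seed = as.integer(seed),
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 library_hash = library_hash),
            class = "ms2_ranker")
}

#' @exportS3Method base::print
print.ms2_ranker <- function(x, ...) {
  cat(sprintf("<ms2_ranker> %d trees, depth %d, seed %d\n",
              x$n_estimators, x$max_depth, x$seed))
  invisible(x)
}

#' Save / load a ranker model
#'
#' The model file is JSON: a manifest (feature order, seed, settings,
#' library hash) plus the tree arrays.
#'
#' @param ranker an `ms2_ranker`.
#' @param path file path.
#' @return the path (`save_ranker`) or the ranker (`load_ranker`).
#' @export
save_ranker <- function(ranker, path) {
  obj <- list(feature_names = ranker$feature_names, seed = ranker$seed,
              n_estimators = ranker$n_estimators,
              max_depth = ranker$max_depth,
              library_hash = ranker$library_hash,
              rf = rf_to_list(ranker$rf))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ranker
#' @export
load_ranker <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  structure(list(rf = rf_from_list(obj$rf),
                 feature_names = obj$feature_names,
                 seed = as.integer(obj$seed),
                 n_estimators = as.integer(obj$n_estimators),
                 max_depth = as.integer(obj$max_depth),
                 library_hash = obj$library_hash),
            class = "ms2_ranker")
}

#' Score and rank all preselected candidates for one query
#'
#' Runs preselection, computes the five features for every candidate,
#' applies the ranker and sorts by descending score (ties broken by
#' preselection score, then spectrum id). Scores are clipped to `[0, 1]`.
#'
#' @param query cleaned query spectrum (precursor m/z required).
#' @param lib an `ms2_library`.
#' @param ranker an `ms2_ranker` trained against a library with the same
#'   parameter hash.
#' @param n_preselect preselection size (default 2000).
#' @return data.frame, one row per candidate, with ids, `rf_score`, the
#'   five features, the preselection score and candidate metadata.
#' @export
rank_candidates <- function(query, lib, ranker, n_preselect = 2000) {
  .assert(inherits(ranker, "ms2_ranker"), "ranker must be an ms2_ranker")
  if (!is.null(ranker$library_hash) &&
      !identical(ranker$library_hash, lib$manifest$parameter_hash)) {
    stop("ranker was trained against a different library configuration ",
         "(parameter hash mismatch)", call. = FALSE)
  }
  .assert(!is.na(query$precursor_mz), "query precursor m/z is required")
  presel <- preselect_candidates(query, lib, n = n_preselect)
  q_sec <- embed_spectrum(lib$secondary_model, query)
  sec_scores <- .secondary_scores(lib, q_sec)
  fm <- .feature_matrix(lib, presel, query$precursor_mz, sec_scores)
  rf_score <- pmax(0, pmin(1, predict(ranker$rf, fm)))
  o <- order(-rf_score, -presel$scores, presel$spectrum_ids)
  rows <- presel$rows[o]
  data.frame(query_id = query$spectrum_id,
             library_spectrum_id = lib$meta$spectrum_id[rows],
             rf_score = rf_score[o],
             preselect_score = presel$scores[o],
             fm[o, , drop = FALSE],
             smiles = lib$meta$smiles[rows],
             inchikey = lib$meta$inchikey[rows],
             inchikey14 = lib$meta$inchikey14[rows],
             compound_name = lib$meta$compound_name[rows],
             precursor_mz = lib$meta$precursor_mz[rows],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Search a library for analogues and exact matches
#'
#' For each query, candidates are preselected by primary-embedding
#' similarity and re-ranked by the random forest. The best candidate is
#' returned when its score reaches `threshold` (default 0.633, the
#' operating point corresponding to 35% recall on the reference analogue
#' benchmark); otherwise the query yields no match. Matches with an
#' absolute precursor m/z difference below 1 Da are labelled
#' `exact_match_candidate`, others `analogue`.
#'
#' @param queries list of cleaned query spectra.
#' @param lib an `ms2_library`.
#' @param ranker an `ms2_ranker`.
#' @param threshold minimal random-forest score (default 0.633).
#' @param top_k matches returned per query (default 1).
#' @param n_preselect preselection size (default 2000).
#' @return data.frame with one row per returned match (possibly zero
#'   rows): query id and precursor, match id, score, features, candidate
#'   metadata and the `decision` column.
#' @export
search <- function(queries, lib, ranker, threshold = 0.633, top_k = 1,
                   n_preselect = 2000) {
  out <- list()
  for (q in queries) {
    ranked <- tryCatch(
      rank_candidates(q, lib, ranker, n_preselect = n_preselect),
      error = function(e) {
        warning("query ", q$spectrum_id, " skipped: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(ranked)) next
    hits <- ranked[ranked$rf_score >= threshold, , drop = FALSE]
    if (nrow(hits) == 0) next
    hits <- hits[seq_len(min(top_k, nrow(hits))), , drop = FALSE]
    hits$query_precursor_mz <- q$precursor_mz
    hits$decision <- ifelse(hits$f3_precursor_mz_difference < 1,
                            "exact_match_candidate", "analogue")
    out[[length(out) + 1L]] <- hits
  }
  if (!length(out)) {
    return(data.frame(query_id = character(0),
                      library_spectrum_id = character(0),
                      rf_score = numeric(0),
                      preselect_score = numeric(0),
                      f1_secondary_similarity = numeric(0),
                      f2_query_precursor_mz = numeric(0),
                      f3_precursor_mz_difference = numeric(0),
                      f4_avg_primary_similarity_related = numeric(0),
                      f5_avg_tanimoto_related = numeric(0),
                      smiles = character(0), inchikey = character(0),
                      inchikey14 = character(0),
                      compound_name = character(0),
                      precursor_mz = numeric(0),
                      query_precursor_mz = numeric(0),
                      decision = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Write search results to CSV
#'
#' One row per returned match: query id and precursor m/z, random-forest
#' score (6 decimal places), matched library spectrum id and precursor
#' m/z, the precursor m/z difference, candidate structure annotations and
#' the analogue/exact-match decision.
#'
#' @param results data.frame from [search()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_results_csv <- function(results, path) {
  df <- data.frame(
    query_id = results$query_id,
    query_precursor_mz = results$query_precursor_mz,
    rf_score = sprintf("%.6f", results$rf_score),
    match_spectrum_id = results$library_spectrum_id,
    match_precursor_mz = results$precursor_mz,
    precursor_mz_difference = results$f3_precursor_mz_difference,
    smiles = results$smiles,
    inchikey = results$inchikey,
    compound_name = results$compound_name,
    decision = results$decision,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
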