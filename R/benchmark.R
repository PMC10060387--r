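#' Structure-disjoint analogue folds
#'
#' Splits the unique 2D structures of a library into `k` equal groups and
#' builds one fold per group: the group's spectra form the test set, all
#' remaining spectra the training library. No inchikey14 occurs on both
#' sides of a fold, and every structure tests exactly once across folds.
#'
#' @param spectra list of annotated cleaned spectra.
#' @param k number of folds (default 20; use fewer for small synthetic
#'   libraries).
#' @param seed integer seed for the structure shuffle.
#' @return list of `k` folds, each `list(train, test, test_keys)`.
#' @export
make_analogue_folds <- function(spectra, k = 20, seed = 1) {
  keys <- vapply(spectra, function(s) inchikey14(s$inchikey), character(1))
  ustruct <- sort(unique(keys))
  .assert(length(ustruct) >= k,
          sprintf("need at least k=%d unique structures, have %d", k,
                  length(ustruct)))
  shuffled <- with_seed(seed, sample(ustruct))
  grp <- rep(seq_len(k), length.out = length(shuffled))
  folds <- lapply(seq_len(k), function(i) {
    test_keys <- shuffled[grp == i]
    test <- spectra[keys %in% test_keys]
    train <- spectra[!keys %in% test_keys]
    train_keys <- unique(keys[!keys %in% test_keys])
    .assert(length(intersect(test_keys, train_keys)) == 0,
            "fold leaks a structure between train and test")
    list(train = train, test = test, test_keys = test_keys)
  })
  all_test <- unlist(lapply(folds, `[[`, "test_keys"))
  .assert(!anyDuplicated(all_test) && setequal(all_test, ustruct),
          "test structures do not partition the library")
  folds
}

#' Spectrum-disjoint exact-match test sets
#'
#' For each of `k` sets: every structure with at least two spectra
#' contributes one randomly chosen spectrum to the test set, the rest
#' stay in the library. Sets differ only in the random pick.
#'
#' @param spectra list of annotated cleaned spectra.
#' @param k number of test sets (default 20).
#' @param seed integer seed; pick `j` uses a seed derived from
#'   `(seed, j)`.
#' @return list of `k` sets, each `list(library, test)`.
#' @export
make_exact_match_testsets <- function(spectra, k = 20, seed = 1) {
  keys <- vapply(spectra, function(s) inchikey14(s$inchikey), character(1))
  multi <- names(which(table(keys) >= 2))
  .assert(length(multi) >= 1,
          "no structure has two or more spectra; exact-match sets need ",
          "replicates")
  lapply(seq_len(k), function(j) {
    picks <- with_seed(derive_seed(seed, paste0("exact", j)), {
      vapply(multi, function(kk) {
        rows <- which(keys == kk)
        rows[sample.int(length(rows), 1)]
      }, integer(1))
    })
    test <- spectra[picks]
    library <- spectra[-picks]
    lib_keys <- keys[-picks]
    .assert(all(keys[picks] %in% lib_keys),
            "a test structure lost all library spectra")
    list(library = library, test = test)
  })
}

#' Best-match baseline search for one query
#'
#' The classical search strategies the re-ranking pipeline is compared
#' against: best cosine or modified-cosine score over library spectra
#' within a precursor m/z prefilter, or best primary-embedding similarity
#' within the same kind of prefilter. Ties go to the lowest spectrum id.
#'
#' @param method one of `"cosine"`, `"modified_cosine"`,
#'   `"primary_embedding"`.
#' @param query cleaned query spectrum.
#' @param library list of cleaned library spectra (cosine methods) or an
#'   `ms2_library` (primary embedding).
#' @param prefilter_da maximal absolute precursor m/z difference
#'   (default `Inf` = no prefilter).
#' @param tolerance fragment tolerance in Da for the cosine methods
#'   (default 0.05).
#' @return list with `spectrum_id`, `score`, `inchikey14`,
#'   `precursor_mz`, or `NULL` when no library spectrum passes the
#'   prefilter.
#' @export
baseline_search <- function(method = c("cosine", "modified_cosine",
                                       "primary_embedding"),
                            query, library, prefilter_da = Inf,
                            tolerance = 0.05) {
  method <- match.arg(method)
  if (method == "primary_embedding") {
    .assert(inherits(library, "ms2_library"),
            "primary_embedding baseline needs an ms2_library")
    keep <- which(abs(library$meta$precursor_mz - query$precursor_mz) <=
                    prefilter_da)
    if (!length(keep)) return(NULL)
    q <- embed_spectrum(library$primary_model, query)
    qn <- sqrt(sum(q^2))
    rn <- sqrt(rowSums(library$emb_primary[keep, , drop = FALSE]^2))
    scores <- unname(as.numeric(
      library$emb_primary[keep, , drop = FALSE] %*% q) / (rn * qn))
    o <- order(-scores, library$meta$spectrum_id[keep])[1]
    row <- keep[o]
    return(list(spectrum_id = library$meta$spectrum_id[row],
                score = scores[o],
                inchikey14 = library$meta$inchikey14[row],
                precursor_mz = library$meta$precursor_mz[row]))
  }
  pmzs <- vapply(library, function(s) s$precursor_mz, numeric(1))
  keep <- which(abs(pmzs - query$precursor_mz) <= prefilter_da)
  if (!length(keep)) return(NULL)
  scorer <- if (method == "cosine") cosine_greedy else modified_cosine
  scores <- vapply(keep, function(i)
    scorer(query, library[[i]], tolerance = tolerance)$score, numeric(1))
  ids <- vapply(library[keep], function(s) s$spectrum_id, character(1))
  o <- order(-scores, ids)[1]
  best <- library[[keep[o]]]
  list(spectrum_id = best$spectrum_id, score = scores[o],
       inchikey14 = if (!is.na(best$inchikey)) inchikey14(best$inchikey)
                    else NA_character_,
       precursor_mz = best$precursor_mz)
}

# One (score, predicted structure) per query for a given method.
.method_predictions <- function(method, queries, library_spectra,
                                lib = NULL, ranker = NULL,
                                prefilter_da = Inf, tolerance = 0.05,
                                n_preselect = 2000) {
  res <- lapply(queries, function(q) {
    if (method == "rerank") {
      ranked <- rank_candidates(q, lib, ranker, n_preselect = n_preselect)
      list(score = ranked$rf_score[1], key = ranked$inchikey14[1])
    } else {
      hit <- baseline_search(method, q,
                             if (method == "primary_embedding") lib
                             else library_spectra,
                             prefilter_da = prefilter_da,
                             tolerance = tolerance)
      if (is.null(hit)) list(score = -Inf, key = NA_character_)
      else list(score = hit$score, key = hit$inchikey14)
    }
  })
  data.frame(score = vapply(res, `[[`, numeric(1), "score"),
             key = vapply(res, `[[`, character(1), "key"),
             stringsAsFactors = FALSE)
}

.curve_from_predictions <- function(preds, quality_fun, thresholds) {
  pts <- lapply(thresholds, function(t) {
    keep <- which(preds$score >= t)
    data.frame(threshold = t,
               recall = length(keep) / nrow(preds),
               quality = if (length(keep)) quality_fun(keep) else NaN,
               n_returned = length(keep))
  })
  do.call(rbind, pts)
}

#' Analogue-mode benchmark curve for one method
#'
#' Every query's true structure must be absent from the library
#' (structure-disjoint regime). For each threshold on the method's score,
#' recall is the fraction of queries with a returned match and quality is
#' the mean Tanimoto between the query's true structure and the predicted
#' structure over returned matches. The embedding and modified-cosine
#' baselines apply a 100-Da precursor prefilter; the re-ranking pipeline
#' applies none.
#'
#' @param method `"rerank"`, `"primary_embedding"`,
#'   `"modified_cosine"` or `"cosine"`.
#' @param queries cleaned annotated query spectra.
#' @param library_spectra cleaned library spectra (used by the cosine
#'   baselines).
#' @param fingerprints named list `inchikey14 -> ms2_fingerprint`
#'   covering query and library structures (ground truth for quality).
#' @param thresholds threshold grid (default 101 points in `[0, 1]`).
#' @param lib `ms2_library` built from `library_spectra` (needed for
#'   `rerank` and `primary_embedding`).
#' @param ranker `ms2_ranker` (needed for `rerank`).
#' @param prefilter_da baseline precursor prefilter (default 100 Da).
#' @param n_preselect preselection size for `rerank`.
#' @return data.frame with columns `method`, `threshold`, `recall`,
#'   `quality`, `n_returned`.
#' @export
evaluate_analogue_curve <- function(method, queries, library_spectra,
                                    fingerprints,
                                    thresholds = seq(0, 1, length.out = 101),
                                    lib = NULL, ranker = NULL,
                                    prefilter_da = 100,
                                    n_preselect = 2000) {
  lib_keys <- unique(vapply(library_spectra, function(s)
    inchikey14(s$inchikey), character(1)))
  q_keys <- vapply(queries, function(s) inchikey14(s$inchikey),
                   character(1))
  leaked <- intersect(unique(q_keys), lib_keys)
  .assert(length(leaked) == 0,
          paste0("analogue regime violated; query structures present in ",
                 "library: ", paste(leaked, collapse = ", ")))
  preds <- .method_predictions(
    method, queries, library_spectra, lib = lib, ranker = ranker,
    prefilter_da = if (method == "rerank") Inf else prefilter_da)
  quality_fun <- function(keep) {
    mean(vapply(keep, function(i)
      tanimoto(fingerprints[[q_keys[i]]],
               fingerprints[[preds$key[i]]]), numeric(1)))
  }
  cbind(method = method,
        .curve_from_predictions(preds, quality_fun, thresholds))
}

#' Exact-match benchmark curve for one method
#'
#' Every query must have at least one library spectrum of the same 2D
#' structure. Quality is the fraction of returned matches whose
#' inchikey14 equals the query's. The embedding and cosine baselines
#' prefilter the library at 0.25 Da precursor difference; the re-ranking
#' pipeline uses the same settings as the analogue search (no prefilter).
#'
#' @inheritParams evaluate_analogue_curve
#' @param prefilter_da baseline precursor prefilter (default 0.25 Da).
#' @return data.frame with columns `method`, `threshold`, `recall`,
#'   `quality`, `n_returned`.
#' @export
evaluate_exact_match_curve <- function(method, queries, library_spectra,
                                       thresholds = seq(0, 1,
                                                        length.out = 101),
                                       lib = NULL, ranker = NULL,
                                       prefilter_da = 0.25,
                                       n_preselect = 2000) {
  lib_keys <- unique(vapply(library_spectra, function(s)
    inchikey14(s$inchikey), character(1)))
  q_keys <- vapply(queries, function(s) inchikey14(s$inchikey),
                   character(1))
  .assert(all(q_keys %in% lib_keys),
          "every exact-match query needs a library spectrum of the same ",
          "structure")
  preds <- .method_predictions(
    method, queries, library_spectra, lib = lib, ranker = ranker,
    prefilter_da = if (method == "rerank") Inf else prefilter_da)
  quality_fun <- function(keep)
    mean(preds$key[keep] == q_keys[keep], na.rm = TRUE)
  cbind(method = method,
        .curve_from_predictions(preds, quality_fun, thresholds))
}

#' Read a curve's quality off at a matched recall
#'
#' Linear interpolation of quality against recall, used to compare
#' methods at the same fraction of answered queries.
#'
#' @param curve data.frame from one of the `evaluate_*_curve` functions.
#' @param recall target recall in `[0, 1]`.
#' @return interpolated quality (clamped to the observed recall range).
#' @export
quality_at_recall <- function(curve, recall) {
  ok <- is.finite(curve$quality)
  .assert(any(ok), "curve has no returned matches at any threshold")
  if (length(unique(curve$recall[ok])) < 2) {
    return(mean(curve$quality[ok]))
  }
  stats::approx(curve$recall[ok], curve$quality[ok], xout = recall,
                rule = 2, ties = mean)$y
}

#' Run the full k-fold benchmark on an annotated spectrum set
#'
#' Orchestrates the complete evaluation protocol at synthetic desk scale:
#' builds structure-disjoint analogue folds (or spectrum-disjoint
#' exact-match sets), trains a ranker per fold on the fold's library, and
#' evaluates the requested methods over a threshold grid. Reported
#' summaries are mean-of-fold-means with standard deviation.
#'
#' @param spectra annotated cleaned spectra.
#' @param mode `"analogue"` or `"exact"`.
#' @param methods methods to evaluate (default the re-ranking pipeline +
#'   primary_embedding; add the cosine baselines for small libraries
#'   only — they score spectrum pairs directly and dominate run time).
#' @param k folds / test sets (default 5 at synthetic scale).
#' @param seed integer seed controlling folds, training-pair sampling and
#'   ranker training.
#' @param fingerprints optional ground-truth fingerprint override (named
#'   by inchikey14).
#' @param primary,secondary embedding models (defaults: the reference
#'   binned embedders at 1 Da / 0.1 Da).
#' @param thresholds threshold grid.
#' @param out_dir optional directory for per-method curve CSVs and a
#'   summary CSV.
#' @param n_preselect preselection size.
#' @param train_top_n pairs per pooled training spectrum.
#' @return list with `curves` (per fold, per method) and `summary`
#'   (data.frame: method, fold, recall/quality summaries).
#' @export
run_benchmark <- function(spectra, mode = c("analogue", "exact"),
                          methods = c("rerank", "primary_embedding"),
                          k = 5, seed = 1, fingerprints = NULL,
                          primary = reference_binned_embedder(
                            1.0, role = "primary_similarity"),
                          secondary = reference_binned_embedder(
                            0.1, role = "secondary_similarity"),
                          thresholds = seq(0, 1, length.out = 101),
                          out_dir = NULL, n_preselect = 2000,
                          train_top_n = 100) {
  mode <- match.arg(mode)
  folds <- if (mode == "analogue") {
    make_analogue_folds(spectra, k = k, seed = seed)
  } else {
    lapply(make_exact_match_testsets(spectra, k = k, seed = seed),
           function(x) list(train = x$library, test = x$test))
  }
  curves <- list()
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    lib <- build_library(fold$train, primary, secondary,
                         fingerprints = fingerprints)
    ranker <- NULL
    if ("rerank" %in% methods) {
      pairs <- generate_training_pairs(
        lib, top_n = train_top_n, seed = derive_seed(seed, paste0("tp", i)))
      ranker <- train_ranker(pairs,
                             seed = derive_seed(seed, paste0("rf", i)),
                             library_hash = lib$manifest$parameter_hash)
    }
    for (m in methods) {
      cv <- if (mode == "analogue") {
        evaluate_analogue_curve(m, fold$test, fold$train, fingerprints,
                                thresholds = thresholds, lib = lib,
                                ranker = ranker,
                                n_preselect = n_preselect)
      } else {
        evaluate_exact_match_curve(m, fold$test, fold$train,
                                   thresholds = thresholds, lib = lib,
                                   ranker = ranker,
                                   n_preselect = n_preselect)
      }
      cv$fold <- i
      curves[[length(curves) + 1L]] <- cv
    }
  }
  all_curves <- do.call(rbind, curves)
  agg <- stats::aggregate(
    cbind(recall, quality) ~ method + threshold,
    data = all_curves, FUN = mean, na.action = stats::na.pass)
  sdq <- stats::aggregate(
    quality ~ method + threshold, data = all_curves,
    FUN = stats::sd, na.action = stats::na.pass)
  names(sdq)[3] <- "quality_sd"
  summary <- merge(agg, sdq, by = c("method", "threshold"))
  summary <- summary[order(summary$method, summary$threshold), ]
  row.names(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in unique(all_curves$method)) {
      utils::write.csv(all_curves[all_curves$method == m, ],
                       file.path(out_dir, paste0("curve_", m, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  list(curves = all_curves, summary = summary,
       aggregation = "per-fold curves; summary is mean over folds per threshold with sd of quality")
}
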