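test_that("preselection truncates, ranks exact copies first, matches the sort oracle", {
  w <- small_world()
  q <- w$gen$spectra[[10]]          # a library spectrum used as query
  pre <- preselect_candidates(q, w$lib, n = 2000)
  expect_length(pre$spectrum_ids, nrow(w$lib$meta))  # library < n
  expect_equal(pre$spectrum_ids[1], q$spectrum_id)
  expect_equal(pre$scores[1], 1.0, tolerance = 1e-9)
  expect_true(all(diff(pre$scores) <= 1e-12))
  # brute-force oracle: embed everything directly and full-sort
  qv <- embed_spectrum(w$models$primary, q)
  sims <- vapply(seq_len(nrow(w$lib$meta)), function(i)
    embedding_similarity(qv, w$lib$emb_primary[i, ]), numeric(1))
  oracle <- oracle_top_k(sims, w$lib$meta$spectrum_id, 25)
  pre25 <- preselect_candidates(q, w$lib, n = 25)
  expect_equal(pre25$spectrum_ids, w$lib$meta$spectrum_id[oracle])
  expect_equal(pre25$scores, sims[oracle], tolerance = 1e-9)
  wrong <- q; wrong$ionmode <- "negative"
  expect_error(preselect_candidates(wrong, w$lib), "ionmode")
})

test_that("single-pair features match the vectorised path and the naive loop", {
  w <- small_world()
  q <- generate_spectrum(w$gen$structures[[3]], w$cfg, replicate_index = 50)
  pre <- preselect_candidates(q, w$lib, n = 2000)
  q_sec <- embed_spectrum(w$lib$secondary_model, q)
  sec_scores <- ms2search:::.secondary_scores(w$lib, q_sec)
  fm <- ms2search:::.feature_matrix(w$lib, pre, q$precursor_mz, sec_scores)
  for (j in c(1, 17, 60)) {
    fv <- compute_feature_vector(q, pre$spectrum_ids[j], w$lib, pre)
    expect_equal(unname(fv), unname(fm[j, ]), tolerance = 1e-12)
  }
  # naive recomputation of f4/f5 for one candidate from raw spectra
  cand <- pre$spectrum_ids[4]
  row <- match(cand, w$lib$meta$spectrum_id)
  rel <- get_related(w$lib, w$lib$meta$inchikey14[row])
  qv <- embed_spectrum(w$models$primary, q)
  per_struct <- vapply(rel$neighbours$inchikey14, function(k) {
    st <- w$lib$structures[[match(k, w$lib$struct_keys)]]
    mean(vapply(st$spectrum_ids, function(id) {
      s <- w$gen$spectra[[match(id, vapply(w$gen$spectra, function(x)
        x$spectrum_id, character(1)))]]
      embedding_similarity(qv, embed_spectrum(w$models$primary, s))
    }, numeric(1)))
  }, numeric(1))
  fv <- compute_feature_vector(q, cand, w$lib, pre)
  expect_equal(unname(fv["f4_avg_primary_similarity_related"]),
               mean(per_struct), tolerance = 1e-9)
  expect_equal(unname(fv["f5_avg_tanimoto_related"]),
               mean(rel$neighbours$tanimoto), tolerance = 1e-12)
  expect_equal(unname(fv["f2_query_precursor_mz"]), q$precursor_mz)
})

test_that("f3 is the absolute precursor difference", {
  w <- small_world()
  q <- w$gen$spectra[[1]]
  q$precursor_mz <- 300.0
  pre <- preselect_candidates(q, w$lib, n = 5)
  cand <- pre$spectrum_ids[1]
  truth <- abs(300.0 - get_precursor_mz(w$lib, cand))
  fv <- compute_feature_vector(q, cand, w$lib, pre)
  expect_equal(unname(fv["f3_precursor_mz_difference"]), truth)
  expect_gte(truth, 0)
})

test_that("training-pair generation obeys the counting rules", {
  w <- small_world()
  pairs <- generate_training_pairs(w$lib, top_n = 25, seed = 5)
  pool_ids <- unique(pairs$query_spectrum_id)
  expect_equal(nrow(pairs), length(pool_ids) * 25)
  expect_true(all(pairs$label >= 0 & pairs$label <= 1))
  self <- pairs[pairs$query_spectrum_id == pairs$library_spectrum_id, ]
  expect_gt(nrow(self), 0)
  expect_true(all(self$label == 1))
  # top_n larger than the library: every pool spectrum pairs with all
  pairs_all <- generate_training_pairs(w$lib, top_n = 1e6, seed = 5)
  expect_equal(nrow(pairs_all),
               length(unique(pairs_all$query_spectrum_id)) *
                 nrow(w$lib$meta))
  # pool arithmetic: ceiling(40/40) = 1 structure + ceiling of the rest
  n_struct_pool <- length(unique(
    w$lib$meta$inchikey14[match(pool_ids, w$lib$meta$spectrum_id)]))
  expect_gte(n_struct_pool, 1)
  expect_identical(generate_training_pairs(w$lib, top_n = 25, seed = 5),
                   pairs)
})

test_that("ranker training validates inputs and is deterministic", {
  w <- small_world()
  pairs <- generate_training_pairs(w$lib, top_n = 40, seed = 6)
  expect_error(train_ranker(pairs[1:50, ]), "at least 100")
  bad <- pairs
  bad$f1_secondary_similarity[3] <- NaN
  expect_error(train_ranker(bad), bad$query_spectrum_id[3], fixed = TRUE)
  r1 <- train_ranker(pairs, n_estimators = 50, seed = 8)
  r2 <- train_ranker(pairs, n_estimators = 50, seed = 8)
  X <- as.matrix(pairs[, r1$feature_names])
  expect_identical(predict(r1$rf, X), predict(r2$rf, X))
  expect_gt(cor(predict(r1$rf, X), pairs$label), 0.5)
})

test_that("ranker files round-trip and mismatched stores are refused", {
  w <- small_world()
  pairs <- generate_training_pairs(w$lib, top_n = 40, seed = 6)
  rk <- train_ranker(pairs, n_estimators = 50, seed = 8,
                     library_hash = w$lib$manifest$parameter_hash)
  path <- withr::local_tempfile(fileext = ".json")
  save_ranker(rk, path)
  rk2 <- load_ranker(path)
  X <- as.matrix(pairs[, rk$feature_names])
  # JSON decimal round-trip can differ in the final ulp
  expect_equal(predict(rk2$rf, X), predict(rk$rf, X), tolerance = 1e-12)
  expect_equal(rk2$library_hash, rk$library_hash)
  other <- build_library(w$gen$spectra, new_models()$primary,
                         reference_binned_embedder(
                           0.2, role = "secondary_similarity"),
                         fingerprints = w$gen$fingerprints)
  q <- w$gen$spectra[[2]]
  expect_error(rank_candidates(q, other, rk), "hash mismatch")
})

test_that("ranking scores every preselected candidate within [0,1]", {
  w <- small_world()
  pairs <- generate_training_pairs(w$lib, top_n = 40, seed = 6)
  rk <- train_ranker(pairs, n_estimators = 60, seed = 8)
  q <- generate_spectrum(w$gen$structures[[7]], w$cfg, replicate_index = 51)
  ranked <- rank_candidates(q, w$lib, rk, n_preselect = 30)
  expect_equal(nrow(ranked), 30)
  expect_true(all(ranked$rf_score >= 0 & ranked$rf_score <= 1))
  expect_true(all(diff(ranked$rf_score) <= 1e-12))
  full <- rank_candidates(q, w$lib, rk)
  expect_equal(nrow(full), nrow(w$lib$meta))
})

test_that("search thresholds bound the result set and label decisions", {
  w <- small_world()
  pairs <- generate_training_pairs(w$lib, top_n = 40, seed = 6)
  rk <- train_ranker(pairs, n_estimators = 60, seed = 8)
  queries <- lapply(w$gen$structures[1:6], function(st)
    generate_spectrum(st, w$cfg, replicate_index = 60))
  none <- ms2search::search(queries, w$lib, rk, threshold = 1.01)
  expect_equal(nrow(none), 0)
  all_hits <- ms2search::search(queries, w$lib, rk, threshold = 0)
  expect_equal(nrow(all_hits), length(queries))
  expect_true(all(all_hits$decision %in%
                    c("analogue", "exact_match_candidate")))
  expect_true(all((all_hits$f3_precursor_mz_difference < 1) ==
                    (all_hits$decision == "exact_match_candidate")))
  # raising the threshold never returns more matches
  grid <- seq(0, 1, by = 0.1)
  counts <- vapply(grid, function(t)
    nrow(ms2search::search(queries, w$lib, rk, threshold = t)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  # top-k reporting
  top3 <- ms2search::search(queries[1], w$lib, rk, threshold = 0,
                            top_k = 3)
  expect_equal(nrow(top3), 3)
})

test_that("results CSV round-trips scores at 6 decimal places", {
  w <- small_world()
  pairs <- generate_training_pairs(w$lib, top_n = 40, seed = 6)
  rk <- train_ranker(pairs, n_estimators = 60, seed = 8)
  queries <- lapply(w$gen$structures[1:4], function(st)
    generate_spectrum(st, w$cfg, replicate_index = 61))
  res <- ms2search::search(queries, w$lib, rk, threshold = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res, path)
  expect_equal(length(readLines(path)), nrow(res) + 1)
  back <- read.csv(path, colClasses = c(rf_score = "character"))
  expect_equal(back$rf_score, sprintf("%.6f", res$rf_score))
  expect_equal(back$decision, res$decision)
  empty <- ms2search::search(queries, w$lib, rk, threshold = 1.01)
  write_results_csv(empty, path)
  expect_equal(length(readLines(path)), 1)
})

test_that("search output is deterministic end to end", {
  w <- small_world()
  run_once <- function() {
    pairs <- generate_training_pairs(w$lib, top_n = 40, seed = 6)
    rk <- train_ranker(pairs, n_estimators = 60, seed = 8)
    queries <- lapply(w$gen$structures[1:5], function(st)
      generate_spectrum(st, w$cfg, replicate_index = 70))
    path <- withr::local_tempfile(fileext = ".csv")
    write_results_csv(ms2search::search(queries, w$lib, rk,
                                        threshold = 0), path)
    readLines(path)
  }
  expect_identical(run_once(), run_once())
})

test_that("feature-4 variants aggregate the neighbourhood as documented", {
  w <- small_world()
  m <- new_models()
  variants <- list(
    structure_mean = build_library(w$gen$spectra, m$primary, m$secondary,
                                   fingerprints = w$gen$fingerprints),
    tanimoto_weighted = build_library(
      w$gen$spectra, new_models()$primary, new_models()$secondary,
      fingerprints = w$gen$fingerprints, f4_variant = "tanimoto_weighted"),
    spectrum_mean = build_library(
      w$gen$spectra, new_models()$primary, new_models()$secondary,
      fingerprints = w$gen$fingerprints, f4_variant = "spectrum_mean"))
  q <- generate_spectrum(w$gen$structures[[9]], w$cfg,
                         replicate_index = 90)
  f4 <- lapply(variants, function(lib) {
    pre <- preselect_candidates(q, lib, n = 2000)
    compute_feature_vector(q, pre$spectrum_ids[2], lib,
                           pre)[["f4_avg_primary_similarity_related"]]
  })
  # manual recomputation of the weighted variant
  lib <- variants$tanimoto_weighted
  pre <- preselect_candidates(q, lib, n = 2000)
  row <- match(pre$spectrum_ids[2], lib$meta$spectrum_id)
  t_idx <- lib$struct_index[row]
  sm <- ms2search:::.structure_means(lib, pre$all_scores)
  wgt <- lib$related[[t_idx]]$neighbours$tanimoto
  nb <- lib$related_idx[[t_idx]]
  expect_equal(f4$tanimoto_weighted, sum(wgt * sm[nb]) / sum(wgt),
               tolerance = 1e-12)
  # with equal per-structure spectrum counts, spectrum_mean equals
  # structure_mean; the Tanimoto weighting genuinely differs
  expect_equal(f4$spectrum_mean, f4$structure_mean, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f4$tanimoto_weighted,
                                f4$structure_mean, tolerance = 1e-6)))
  # variant participates in the manifest hash: rankers do not transfer
  expect_false(identical(variants$structure_mean$manifest$parameter_hash,
                         lib$manifest$parameter_hash))
})

test_that("feature 4 tracks true chemical similarity for analogue queries", {
  w <- small_world()
  # a query whose structure is excluded from consideration: correlate
  # candidate-level f4 with the true Tanimoto of the candidate structure
  q <- generate_spectrum(w$gen$structures[[5]], w$cfg,
                         replicate_index = 91)
  pre <- preselect_candidates(q, w$lib, n = 2000)
  sm <- ms2search:::.structure_means(w$lib, pre$all_scores)
  f4_struct <- vapply(seq_along(w$lib$related_idx), function(t)
    ms2search:::.f4_aggregate(w$lib, sm, t), numeric(1))
  truth <- vapply(w$lib$struct_keys, function(k)
    tanimoto(w$gen$fingerprints[[w$gen$structures[[5]]$key]],
             w$gen$fingerprints[[k]]), numeric(1))
  other <- w$lib$struct_keys != w$gen$structures[[5]]$key
  expect_gt(cor(f4_struct[other], truth[other], method = "spearman"), 0)
})
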