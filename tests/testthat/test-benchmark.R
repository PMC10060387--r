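test_that("analogue folds partition structures with no leakage", {
  cfg <- synthetic_config(n_clusters = 8, structures_per_cluster = 5,
                          spectra_per_structure = 2, seed = 3)
  gen <- generate_synthetic_library(cfg)    # 40 structures
  folds <- make_analogue_folds(gen$spectra, k = 20, seed = 4)
  expect_length(folds, 20)
  expect_true(all(vapply(folds, function(f) length(f$test_keys),
                         numeric(1)) == 2))
  all_test <- unlist(lapply(folds, `[[`, "test_keys"))
  expect_equal(sort(all_test),
               sort(unique(vapply(gen$spectra, function(s)
                 inchikey14(s$inchikey), character(1)))))
  for (f in folds[1:5]) {
    train_keys <- vapply(f$train, function(s) inchikey14(s$inchikey),
                         character(1))
    test_keys <- vapply(f$test, function(s) inchikey14(s$inchikey),
                        character(1))
    expect_length(intersect(train_keys, test_keys), 0)
    expect_equal(length(f$train) + length(f$test), length(gen$spectra))
  }
  expect_error(make_analogue_folds(gen$spectra, k = 100), "at least")
})

test_that("exact-match sets pick one spectrum per multi-spectrum structure", {
  cfg <- synthetic_config(n_clusters = 3, structures_per_cluster = 4,
                          spectra_per_structure = 5, seed = 9)
  gen <- generate_synthetic_library(cfg)
  sets <- make_exact_match_testsets(gen$spectra, k = 20, seed = 10)
  expect_length(sets, 20)
  for (s in sets[1:4]) {
    test_keys <- vapply(s$test, function(x) inchikey14(x$inchikey),
                        character(1))
    lib_keys <- vapply(s$library, function(x) inchikey14(x$inchikey),
                       character(1))
    expect_false(anyDuplicated(test_keys) > 0)  # one pick per structure
    expect_true(all(test_keys %in% lib_keys))   # library keeps the rest
    test_ids <- vapply(s$test, function(x) x$spectrum_id, character(1))
    lib_ids <- vapply(s$library, function(x) x$spectrum_id, character(1))
    expect_length(intersect(test_ids, lib_ids), 0)
  }
  # picks vary across sets: a 5-replicate structure sees >= 2 selections
  key1 <- inchikey14(gen$spectra[[1]]$inchikey)
  picks <- vapply(sets, function(s) {
    ids <- vapply(s$test, function(x) x$spectrum_id, character(1))
    keys <- vapply(s$test, function(x) inchikey14(x$inchikey),
                   character(1))
    ids[match(key1, keys)]
  }, character(1))
  expect_gte(length(unique(picks)), 2)
  single <- lapply(seq_along(gen$spectra), function(i) {
    s <- gen$spectra[[i]]
    s$inchikey <- paste0(substr(ms2search:::.random_key(), 1, 14),
                         "-UHFFFAOYSA-N")
    s
  })
  set.seed(1)
  expect_error(make_exact_match_testsets(single, k = 2), "two or more")
})

test_that("baseline_search equals the exhaustive loop oracle", {
  w <- small_world()
  spectra <- w$gen$spectra[1:40]
  q <- generate_spectrum(w$gen$structures[[2]], w$cfg,
                         replicate_index = 80)
  for (m in c("cosine", "modified_cosine")) {
    hit <- baseline_search(m, q, spectra, prefilter_da = 100)
    scorer <- if (m == "cosine") cosine_greedy else modified_cosine
    keep <- which(abs(vapply(spectra, function(s) s$precursor_mz,
                             numeric(1)) - q$precursor_mz) <= 100)
    scores <- vapply(keep, function(i)
      scorer(q, spectra[[i]])$score, numeric(1))
    ids <- vapply(spectra[keep], function(s) s$spectrum_id, character(1))
    best <- keep[order(-scores, ids)[1]]
    expect_equal(hit$spectrum_id, spectra[[best]]$spectrum_id)
    expect_equal(hit$score, max(scores), tolerance = 1e-12)
  }
  # embedding baseline against the store, unfiltered equals full argmax
  hit <- baseline_search("primary_embedding", q, w$lib,
                         prefilter_da = Inf)
  pre <- preselect_candidates(q, w$lib, n = 1)
  expect_equal(hit$spectrum_id, pre$spectrum_ids[1])
  expect_equal(hit$score, pre$scores[1], tolerance = 1e-12)
  # zero-width prefilter with no matching precursor: no match
  q2 <- q; q2$precursor_mz <- 1.5
  expect_null(baseline_search("cosine", q2, spectra, prefilter_da = 0))
})

test_that("curves behave at threshold extremes and interpolate", {
  w <- small_world()
  fold <- make_analogue_folds(w$gen$spectra, k = 5, seed = 44)[[1]]
  m <- new_models()
  lib <- build_library(fold$train, m$primary, m$secondary,
                       fingerprints = w$gen$fingerprints)
  curve <- evaluate_analogue_curve(
    "primary_embedding", fold$test[1:10], fold$train, w$gen$fingerprints,
    thresholds = c(0, 0.5, 2), lib = lib)
  expect_equal(curve$recall[1], 1.0)
  expect_equal(curve$recall[3], 0.0)
  expect_true(is.nan(curve$quality[3]))
  expect_true(all(diff(curve$recall) <= 0))
  expect_true(all(curve$quality[is.finite(curve$quality)] >= 0 &
                    curve$quality[is.finite(curve$quality)] <= 1))
  q35 <- quality_at_recall(curve, 0.35)
  expect_true(is.finite(q35))
  # leaking a query structure into the library is refused
  expect_error(evaluate_analogue_curve(
    "primary_embedding", fold$train[1], fold$train, w$gen$fingerprints,
    lib = lib), "analogue regime")
})

test_that("exact-match curves score structure identity", {
  w <- small_world()
  sets <- make_exact_match_testsets(w$gen$spectra, k = 2, seed = 12)
  s <- sets[[1]]
  m <- new_models()
  lib <- build_library(s$library, m$primary, m$secondary,
                       fingerprints = w$gen$fingerprints)
  curve <- evaluate_exact_match_curve(
    "primary_embedding", s$test[1:12], s$library,
    thresholds = c(0, 0.9), lib = lib)
  expect_true(all(curve$quality[is.finite(curve$quality)] >= 0 &
                    curve$quality[is.finite(curve$quality)] <= 1))
  expect_true(all(diff(curve$recall) <= 0))
  # a replicate query finds its own structure at low threshold
  expect_gt(curve$quality[1], 0.5)
})
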