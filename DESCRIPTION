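Package: ms2search
Title: Analogue and Exact-Match Searching of MS/MS Spectral Libraries
Version: 0.1.0
Authors@R:
    person("Open", "Metabolomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A library-search engine for MS/MS fragmentation spectra that
    retrieves both exact matches and structural analogues from an annotated
    spectral library. Candidate spectra are preselected by cosine similarity
    of precomputed spectral embeddings over the whole library (no precursor
    m/z prefilter), then re-ranked by a random-forest regressor trained to
    predict the Tanimoto chemical similarity between query and candidate
    structures from five features, including the average embedding score
    over chemically related library structures. Includes spectrum cleaning
    and annotation filters, MGF/MSP/mzML readers, an on-disk library store
    with precomputed embeddings and a related-structure table,
    structure-disjoint benchmarking utilities, and a seeded synthetic
    spectral-library generator with known ground-truth chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
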