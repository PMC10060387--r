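# Shared small synthetic worlds, built once per test run.

new_models <- function() {
  list(primary = reference_binned_embedder(1.0,
                                           role = "primary_similarity"),
       secondary = reference_binned_embedder(0.1,
                                             role = "secondary_similarity"))
}

# A small annotated world: 8 clusters x 5 structures x 3 replicates.
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_clusters = 8, structures_per_cluster = 5,
                              seed = 42)
      gen <- generate_synthetic_library(cfg)
      m <- new_models()
      lib <- build_library(gen$spectra, m$primary, m$secondary,
                           fingerprints = gen$fingerprints)
      cache <<- list(cfg = cfg, gen = gen, lib = lib, models = m)
    }
    cache
  }
})

# Hand-built annotated spectrum for io/cleaning tests.
toy_annotated_spectrum <- function(id = "toy1", pmz = 181.07,
                                   ionmode = "positive") {
  ms2_spectrum(id, mz = c(57.03, 85.03, 127.04, 163.06),
               intensity = c(0.3, 1.0, 0.45, 0.8),
               precursor_mz = pmz, ionmode = ionmode,
               smiles = "OCC(O)C(O)C(O)C(O)CO",
               inchi = "InChI=1S/C6H14O6/c7-1-3(9)5(11)6(12)4(10)2-8/h3-12H,1-2H2",
               inchikey = "FBPFZTCFMRRESA-KVTDHHQDSA-N",
               metadata = list(compound_name = "mannitol"))
}
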