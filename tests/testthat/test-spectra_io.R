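test_that("MGF reading finds one spectrum per block and harmonises keys", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "TITLE=first", "PEPMASS=301.2 1234.5", "CHARGE=1+",
    "SMILES=CCO", "150.0 5.0", "100.0 10.0", "END IONS", "",
    "BEGIN IONS", "TITLE=second", "PRECURSORMZ=402.1", "IONMODE=negative",
    "80.1 1", "90.2 2", "END IONS"), path)
  specs <- read_spectra(path, format = "mgf")
  expect_length(specs, 2)
  # unsorted peaks are reordered ascending
  expect_equal(specs[[1]]$mz, c(100.0, 150.0))
  expect_equal(specs[[1]]$intensity, c(10.0, 5.0))
  # PEPMASS dialect with trailing intensity; charge-sign ionmode
  expect_equal(specs[[1]]$precursor_mz, 301.2)
  expect_equal(specs[[1]]$ionmode, "positive")
  expect_equal(specs[[1]]$smiles, "CCO")
  expect_equal(specs[[2]]$precursor_mz, 402.1)
  expect_equal(specs[[2]]$ionmode, "negative")
})

test_that("records without peaks are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=empty", "PEPMASS=100", "END IONS",
               "BEGIN IONS", "PEPMASS=100", "50 1", "60 2", "END IONS"),
             path)
  expect_warning(specs <- read_spectra(path), "no peaks")
  expect_length(specs, 1)
  expect_error(read_spectra(file.path(tempdir(), "does_not_exist.mgf")),
               "not found")
})

test_that("MSP records parse with Num Peaks and key: value metadata", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c(
    "Name: compound one", "PrecursorMZ: 250.1", "Ion_mode: P",
    "SMILES: CCO", "Num Peaks: 3", "100.0 10.0", "110.5 5.5; 120.2 2.2",
    "", "Name: compound two", "PrecursorMZ: 300.5", "Ion_mode: N",
    "Num Peaks: 2", "90.0\t4.0", "95.0\t2.0"), path)
  specs <- read_spectra(path, format = "msp")
  expect_length(specs, 2)
  expect_equal(specs[[1]]$mz, c(100.0, 110.5, 120.2))
  expect_equal(specs[[1]]$precursor_mz, 250.1)
  expect_equal(specs[[1]]$ionmode, "positive")
  expect_equal(specs[[2]]$ionmode, "negative")
  expect_equal(specs[[2]]$intensity, c(4.0, 2.0))
})

test_that("mzML MS2 scans parse, including zlib-compressed arrays", {
  enc <- function(v, compress = FALSE) {
    bytes <- writeBin(as.numeric(v), raw(), size = 8, endian = "little")
    if (compress) bytes <- memCompress(bytes, type = "gzip")
    jsonlite::base64_enc(bytes)
  }
  arr <- function(v, acc, compress = FALSE) paste0(
    '<binaryDataArray encodedLength="0">',
    '<cvParam accession="MS:1000523" name="64-bit float"/>',
    sprintf('<cvParam accession="%s" name="array"/>',
            acc),
    if (compress) '<cvParam accession="MS:1000574" name="zlib"/>' else
      '<cvParam accession="MS:1000576" name="no compression"/>',
    "<binary>", enc(v, compress), "</binary></binaryDataArray>")
  scan <- function(id, mz, int, pmz, compress = FALSE) paste0(
    sprintf('<spectrum id="%s" index="0" defaultArrayLength="%d">',
            id, length(mz)),
    '<cvParam accession="MS:1000511" name="ms level" value="2"/>',
    '<cvParam accession="MS:1000130" name="positive scan"/>',
    "<precursorList count=\"1\"><precursor><selectedIonList count=\"1\">",
    sprintf('<selectedIon><cvParam accession="MS:1000744" value="%g"/></selectedIon>',
            pmz),
    "</selectedIonList></precursor></precursorList>",
    '<binaryDataArrayList count="2">',
    arr(mz, "MS:1000514", compress), arr(int, "MS:1000515", compress),
    "</binaryDataArrayList></spectrum>")
  path <- withr::local_tempfile(fileext = ".mzml")
  writeLines(paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml"><run><spectrumList count="3">',
    '<spectrum id="ms1" index="9"><cvParam accession="MS:1000511" value="1"/></spectrum>',
    scan("s1", c(100.5, 200.25), c(10, 20), 305.5),
    scan("s2", c(90.1, 95.2, 99.3), c(1, 2, 3), 210.0, compress = TRUE),
    "</spectrumList></run></mzML>"), path)
  specs <- read_spectra(path, format = "mzml")
  expect_length(specs, 2)          # the MS1 scan is ignored
  expect_equal(specs[[1]]$mz, c(100.5, 200.25))
  expect_equal(specs[[1]]$precursor_mz, 305.5)
  expect_equal(specs[[1]]$ionmode, "positive")
  expect_equal(specs[[2]]$mz, c(90.1, 95.2, 99.3))
  expect_equal(specs[[2]]$intensity, c(1, 2, 3))
})

test_that("MGF round-trip preserves a synthetic library", {
  w <- small_world()
  subset <- w$gen$spectra[seq(1, 60, by = 3)]
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(subset, path)
  back <- read_spectra(path)
  expect_length(back, length(subset))
  for (i in seq_along(subset)) {
    expect_equal(back[[i]]$spectrum_id, subset[[i]]$spectrum_id)
    expect_equal(back[[i]]$mz, subset[[i]]$mz, tolerance = 1e-12)
    expect_equal(back[[i]]$intensity, subset[[i]]$intensity,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$precursor_mz, subset[[i]]$precursor_mz,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$inchikey, subset[[i]]$inchikey)
  }
})

test_that("partition_by_ionmode puts every spectrum in exactly one bin", {
  mk <- function(mode, id) ms2_spectrum(id, c(100, 110, 120), c(1, 2, 3),
                                        precursor_mz = 200, ionmode = mode)
  spectra <- c(lapply(1:3, function(i) mk("positive", paste0("p", i))),
               lapply(1:2, function(i) mk("negative", paste0("n", i))),
               lapply(1:2, function(i) mk("unknown", paste0("u", i))))
  p <- partition_by_ionmode(spectra)
  expect_length(p$positive, 3)
  expect_length(p$negative, 2)
  expect_length(p$dropped, 2)
  expect_equal(length(p$positive) + length(p$negative) + length(p$dropped),
               length(spectra))
  all_unknown <- partition_by_ionmode(lapply(1:4, function(i)
    mk("unknown", paste0("x", i))))
  expect_length(all_unknown$positive, 0)
  expect_length(all_unknown$dropped, 4)
})

test_that("is_fully_annotated requires all three valid annotations", {
  s <- toy_annotated_spectrum()
  expect_true(is_fully_annotated(s))
  s2 <- s; s2$inchikey <- NA_character_
  expect_false(is_fully_annotated(s2))
  s3 <- s; s3$smiles <- "not_a_smiles"
  expect_false(is_fully_annotated(s3))
  s4 <- s; s4$inchikey <- "TOOSHORT"
  expect_false(is_fully_annotated(s4))
  s5 <- s; s5$inchi <- "nope"
  expect_false(is_fully_annotated(s5))
})
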