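test_that("ppm errors are signed and gate the 50 ppm tolerance", {
  expect_equal(ppm_error(1105.575, 1105.575), 0)
  expect_gt(abs(ppm_error(1105.6303, 1105.575)), 50)
  expect_lt(abs(ppm_error(1105.6302, 1105.575)), 50)
  expect_error(ppm_error(-1, 1000), "positive")
})

test_that("protein acceptance needs two distinct matching peptides", {
  prot <- read_fasta(zoomsel_extdata("proteins_synthetic.fasta"))
  lib <- build_mass_library(prot)
  col1 <- dplyr::filter(lib, protein_id == "CO1A1_SYNBOV", n_deam == 0)
  two_seqs <- col1[!duplicated(col1$sequence), ][1:2, ]

  peaks <- tibble::tibble(mz = two_seqs$mz, intensity = 10, snr = 10)
  m <- match_library(peaks, lib)
  expect_true(all(m$accepted[m$protein_id == "CO1A1_SYNBOV"]))

  kerat <- dplyr::filter(lib, protein_id == "K1C10_SYNHUM")[1, ]
  m1 <- match_library(tibble::tibble(mz = kerat$mz, intensity = 5, snr = 5), lib)
  expect_false(any(m1$accepted[m1$protein_id == "K1C10_SYNHUM"]))

  expect_equal(nrow(match_library(tibble::tibble(mz = double(),
                                                 intensity = double(),
                                                 snr = double()), lib)), 0)
  expect_error(match_library(peaks, lib[0, ]), "empty")
})

test_that("tightening the ppm tolerance never adds matches", {
  prot <- read_fasta(zoomsel_extdata("proteins_synthetic.fasta"))
  lib <- build_mass_library(prot)
  set.seed(3)
  peaks <- tibble::tibble(
    mz = sample(lib$mz, 20) * (1 + runif(20, -4e-5, 4e-5)),
    intensity = 10, snr = 10
  )
  n <- vapply(c(50, 30, 20, 10, 5), function(tol) {
    nrow(match_library(peaks, lib, ppm_tol = tol))
  }, integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("a simulated large-bovid spectrum is assigned to Bison/Bos", {
  db <- fixture_markers()
  sp <- simulate_spectrum(db, "Bos sp.", seed = 7, snr = 10)
  peaks <- select_monoisotopic(pick_peaks(sp))
  asg <- assign_taxon(peaks, db, exclude = "Ovibos moschatus",
                      merge_rules = default_merge_rules())
  expect_equal(asg$status, "identified")
  expect_equal(asg$clade, "Bison sp./Bos sp.")
  expect_true(all(abs(asg$evidence$ppm) <= 50))
  # the musk ox alternative matched but is excluded on biogeographic grounds
  expect_true("Ovibos moschatus" %in% asg$excluded$taxon)
})

test_that("empty and noise-only spectra are unidentifiable", {
  db <- fixture_markers()
  empty <- tibble::tibble(mz = double(), intensity = double(), snr = double())
  expect_equal(assign_taxon(empty, db)$status, "unidentifiable")
  ns <- simulate_noise_spectrum(seed = 4)
  asg <- assign_taxon(select_monoisotopic(pick_peaks(ns)), db)
  expect_equal(asg$status, "unidentifiable")
  expect_true(is.na(asg$clade))
})

test_that("a single matched marker is insufficient for a call", {
  db <- fixture_markers()
  one <- tibble::tibble(mz = 1208.642, intensity = 10, snr = 10)
  asg <- assign_taxon(one, db, merge_rules = default_merge_rules())
  expect_equal(asg$status, "unidentifiable")
})

test_that("taxon assignment is deterministic", {
  db <- fixture_markers()
  sp <- simulate_spectrum(db, "Rangifer tarandus", seed = 21, snr = 8)
  peaks <- select_monoisotopic(pick_peaks(sp))
  a1 <- assign_taxon(peaks, db, merge_rules = default_merge_rules())
  a2 <- assign_taxon(peaks, db, merge_rules = default_merge_rules())
  expect_identical(a1$clade, a2$clade)
  expect_identical(a1$evidence, a2$evidence)
  expect_equal(a1$clade, "Rangifer tarandus")
})

test_that("tidy and glance summarise an assignment", {
  db <- fixture_markers()
  sp <- simulate_spectrum(db, "Bos sp.", seed = 2, snr = 10)
  asg <- assign_taxon(select_monoisotopic(pick_peaks(sp)), db,
                      merge_rules = default_merge_rules())
  expect_s3_class(tidy(asg), "tbl_df")
  g <- glance(asg)
  expect_equal(g$n_markers, nrow(asg$evidence))
})

test_that("contamination screen classifies protein classes and flags transfer", {
  matches <- tibble::tibble(
    peak_mz = 1:6, protein_id = c("CO1A1_SYNBOV", "CO1A1_SYNBOV",
                                  "TRYP_SYNPIG", "K1C10_SYNHUM",
                                  "ALBU_SYNBOV", "ALBU_SYNBOV"),
    taxon = c("Bos taurus", "Bos taurus", "Sus scrofa", "Homo sapiens",
              "Bos taurus", "Bos taurus"),
    sequence = letters[1:6], n_hyd = 0L, n_deam = 0L,
    library_mz = 1:6, ppm = 0, n_peptides = c(2L, 2L, 2L, 2L, 2L, 2L),
    accepted = TRUE
  )
  scr <- contamination_screen(matches)
  expect_equal(
    scr$class[match(c("CO1A1_SYNBOV", "TRYP_SYNPIG", "K1C10_SYNHUM",
                      "ALBU_SYNBOV"), scr$protein_id)],
    c("endogenous-candidate", "known-process-contaminant",
      "known-process-contaminant", "usage-derived-candidate")
  )
  expect_true(scr$flagged[scr$protein_id == "ALBU_SYNBOV"])
  expect_false(any(scr$flagged[scr$protein_id != "ALBU_SYNBOV"]))
  # empty accepted set -> empty report
  expect_equal(nrow(contamination_screen(matches[matches$accepted == FALSE, ])), 0)
})
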