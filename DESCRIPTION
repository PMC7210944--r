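Package: zoomsel
Title: Collagen Peptide Mass Fingerprinting and Bayesian Rib-Selection
    Analysis for Bone Artifacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for taxonomic identification of bone artifacts by
    Zooarchaeology by Mass Spectrometry (ZooMS) and for testing whether rib
    blanks were selected opportunistically or by body size. Includes in
    silico tryptic digestion of collagen and contaminant proteins into
    peptide mass libraries, MALDI-TOF spectrum reading (plain text and a
    minimal mzML subset), robust noise estimation and peak picking,
    deamidation-aware monoisotopic peak selection, marker-database matching
    with clade-level assignment and a contamination screen, glutamine
    deamidation estimation by non-negative isotope-envelope fitting, and a
    Bayesian posterior-odds comparison of a multinomial (opportunistic) and
    a Dirichlet-multinomial (size-selective) model of rib selection. A
    seeded synthetic-data module generates faunal assemblages and MALDI
    spectra so the full pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
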