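# zoomsel

Taxonomic identification of bone artifacts by collagen peptide mass
fingerprinting (ZooMS), and a Bayesian test of whether rib blanks for bone
tools were selected opportunistically or by body size.

Middle Paleolithic *lissoirs* (rib smoothing tools) are too modified for
morphological species identification, but their collagen type I carries
taxon-diagnostic tryptic peptide masses that a MALDI-TOF fingerprint can
read — even from non-destructive extractions off the plastic boxes the
artifacts were stored in. `zoomsel` implements the full computational
chain:

- **mass core** — monoisotopic peptide masses from a fixed residue table,
  counted modifications (hydroxyproline +15.994915 Da, deamidation
  +0.984016 Da), protonated m/z, nominal marker labels, and isotope
  envelopes by per-element convolution;
- **digest** — in silico tryptic digestion (K/R, not before P, missed
  cleavages) of reference FASTA into a peptide mass library;
- **spectra** — two-column text and minimal mzML input, windowed-MAD
  noise estimation, S/N > 3 peak picking, and deamidation-aware
  monoisotopic selection (a +0.984 Da neighbour is a deamidated peptide,
  not an isotope);
- **identify** — 50 ppm marker matching, clade-level assignment with
  merge rules ("Bison sp./Bos sp.") and biogeographic exclusions, the
  two-peptide protein acceptance rule, and a contamination screen
  (endogenous collagen vs. process contaminants vs. usage-derived
  transfer proteins);
- **deamidation** — the extent of deamidation of peptide P1105
  (GVQGPPGPAGPR) by non-negative isotope-envelope mixture fitting
  (1.0 = pristine collagen, lower = degraded);
- **selectivity** — the rib-selection hypothesis test;
- **synthetic data** — seeded simulators for MALDI fingerprints and
  faunal assemblages, plus packaged assemblage fixtures.

## The selection test

The evidence `E` is the vector of identified rib-blank counts per taxon
category. Support for strategic versus opportunistic selection is the
posterior odds

```
P(E | H_A) / P(E | H_0) * P(H_A) / P(H_0)
```

with `P(E | H_0)` a multinomial likelihood at the assemblage's relative
rib frequencies `p_i = ribs_i / sum(ribs)`, and `P(E | H_A)` a
Dirichlet-multinomial likelihood with concentrations
`alpha_i = c * ln(mass_i)` (log body mass as the selectivity weight, with
a strong and a weak rescaling of `c`). Odds above 1 favour strategic
selection.

## Worked example

Simulate a non-destructive fingerprint of a large bovid, identify it, and
run the selection test on the packaged Layer L-3B assemblage with three
large-bovid rib blanks:

```r
library(zoomsel)

db <- read_marker_db(zoomsel_extdata("marker_db_synthetic.tsv"))
sp <- simulate_spectrum(db, "Bos sp.", seed = 7, snr = 10)
peaks <- select_monoisotopic(pick_peaks(sp))
assign_taxon(peaks, db, exclude = "Ovibos moschatus",
             merge_rules = default_merge_rules())
#> ZooMS taxon assignment
#>   status: identified
#>   clade:  Bison sp./Bos sp.
#>   markers matched: 5 (|ppm| max 13.5)
#>   excluded: Ovibos moschatus
```

Five markers match the large-bovid series within 13.5 ppm; musk ox, which
shares every marker below the 2500 m/z cutoff, is excluded because it is
not part of the regional fauna, leaving the merged bison/aurochs clade
(the markers cannot separate the two species).

```r
asm <- read_assemblage(zoomsel_extdata("assemblage_abri_peyrony.tsv"),
                       layer = "L-3B")
masses <- readr::read_tsv(zoomsel_extdata("body_masses_synthetic.tsv"),
                          show_col_types = FALSE)
res <- run_selection_test(asm, c("large bovid" = 3), masses)
res
#> Rib-selection hypothesis test
#>   observations: large bovid:3, medium ungulate:0 (n = 3)
#>   P(E | H0) = 0.000864  (opportunistic, multinomial)
#>   strong variant: P(E | HA) = 0.227, posterior odds = 262.4 (reported 262.4)
#>   weak variant: P(E | HA) = 0.211, posterior odds = 243.8 (reported 243.8)
#>   strategic (size-selective) selection is better supported
```

Three large-bovid blanks from an assemblage whose ribs are over 90%
medium ungulate are very unlikely under opportunistic selection
(P ≈ 0.00086, which prints as 0.0009) and far better supported under the
size-selective model — posterior odds of a few hundred under the packaged
illustrative body-mass table and concentration scalings (`c_strong = 1`,
`c_weak = 2`; both are configuration parameters, and the odds depend on
them). `tidy(res)` returns the per-variant table, `glance(res)` a one-row
summary, `autoplot(res)` a bar chart of the odds.

For the single blank of Layer L-3A, where large bovids are well
represented (rib frequency 0.6), the same call gives `P(E | H0) = 0.6`
and odds below 1: one draw from a large-bovid-rich assemblage carries no
evidence for deliberate size selection.

Deamidation of P1105 from a simulated spectrum with 55% deamidated
signal:

```r
glance(fit_deamidation(simulate_spectrum(db, "Bos sp.", seed = 21,
                                         snr = 15,
                                         deamidation_fraction = 0.55)))
#> # A tibble: 1 × 5
#>   sequence     value status residual n_points
#>   <chr>        <dbl> <chr>     <dbl>    <int>
#> 1 GVQGPPGPAGPR 0.512 ok         3.60      156
```

The recovered value 0.51 (true 0.45 for this single seed; across 100
seeds the estimator is unbiased within 0.02) indicates degraded, ancient
collagen — a value of 1.0 would instead point to modern contamination.

A configuration-driven end-to-end run (`run_pipeline()`, or the thin CLI
wrapper in `inst/scripts/zoomsel.R`) chains digestion, peak picking,
assignment, the contamination screen, deamidation and the selection test,
writing JSON reports and a parameter log.

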