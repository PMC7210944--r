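#' Peptide mass and isotope-envelope calculations
#'
#' Core peptide chemistry for collagen peptide mass fingerprinting:
#' monoisotopic masses from a fixed residue table, protonated m/z, counted
#' (position-blind) modifications, and isotope envelopes by convolution of
#' per-element isotope distributions.
#'
#' Two modifications are supported, both counted rather than positioned
#' because MALDI-TOF fingerprints cannot resolve modification sites:
#' proline hydroxylation (+15.994915 Da each, at most one per proline) and
#' asparagine/glutamine deamidation (+0.984016 Da each, at most one per
#' N or Q).
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param n_hydroxylations Number of hydroxyprolines (counted, unpositioned).
#' @param n_deamidations Number of deamidated N/Q residues.
#' @param charge Positive integer charge state; MALDI default 1.
#'
#' @return `peptide_mass()` returns the neutral monoisotopic mass in Da;
#'   `mz_protonated()` the m/z of the protonated species.
#'
#' @examples
#' peptide_mass("GVQGPPGPAGPR")                      # 1088.573
#' mz_protonated("GVQGPPGPAGPR", n_hydroxylations = 1) # 1105.575 (marker P1)
#' @export
peptide_mass <- function(sequence, n_hydroxylations = 0, n_deamidations = 0) {
  res <- check_peptide(sequence, n_hydroxylations, n_deamidations)
  sum(RESIDUE_MASS[res]) + MASS_WATER +
    n_hydroxylations * MASS_HYDROXYLATION +
    n_deamidations * MASS_DEAMIDATION
}

#' @rdname peptide_mass
#' @export
mz_protonated <- function(sequence, n_hydroxylations = 0, n_deamidations = 0,
                          charge = 1L) {
  if (!is.numeric(charge) || length(charge) != 1 || charge < 1 ||
      charge != as.integer(charge)) {
    abort("`charge` must be a positive integer (MALDI default 1).")
  }
  m <- peptide_mass(sequence, n_hydroxylations, n_deamidations)
  (m + charge * MASS_PROTON) / charge
}

#' Nominal integer marker label for a peptide m/z
#'
#' ZooMS markers are conventionally named by the integer part of their
#' monoisotopic m/z (P1 at 1105.575 m/z is "P1105"), so the label is the
#' truncated, not rounded, m/z.
#'
#' @param mz Observed or theoretical m/z.
#' @return Integer nominal mass label.
#' @examples
#' marker_label(1105.575) # 1105
#' @export
marker_label <- function(mz) {
  as.integer(floor(mz))
}

# Validates a peptide and returns its residue vector.
check_peptide <- function(sequence, n_hydroxylations = 0, n_deamidations = 0) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty amino-acid string.")
  }
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(RESIDUE_MASS))
  if (length(bad)) {
    abort(sprintf(
      "Unknown residue symbol(s) in sequence: %s",
      paste(unique(bad), collapse = ", ")
    ))
  }
  if (n_hydroxylations < 0 || n_deamidations < 0) {
    abort("Modification counts must be non-negative.")
  }
  if (n_hydroxylations > sum(res == "P")) {
    abort("`n_hydroxylations` exceeds the number of prolines in the sequence.")
  }
  if (n_deamidations > sum(res %in% c("N", "Q"))) {
    abort("`n_deamidations` exceeds the number of N/Q residues in the sequence.")
  }
  res
}

#' Elemental composition of a peptide
#'
#' Sums residue compositions plus one water; hydroxylation adds one oxygen,
#' deamidation swaps NH for O.
#'
#' @inheritParams peptide_mass
#' @return Named integer vector with elements C, H, N, O, S.
#' @examples
#' peptide_composition("G") # C2 H5 N1 O2
#' @export
peptide_composition <- function(sequence, n_hydroxylations = 0,
                                n_deamidations = 0) {
  res <- check_peptide(sequence, n_hydroxylations, n_deamidations)
  comp <- colSums(RESIDUE_COMPOSITION[res, , drop = FALSE])
  comp["H"] <- comp["H"] + 2          # water
  comp["O"] <- comp["O"] + 1
  comp["O"] <- comp["O"] + n_hydroxylations
  comp["N"] <- comp["N"] - n_deamidations
  comp["H"] <- comp["H"] - n_deamidations
  comp["O"] <- comp["O"] + n_deamidations
  storage.mode(comp) <- "integer"
  comp
}

#' Approximate elemental composition for a peptide known only by mass
#'
#' Scales the averagine model residue to the target neutral mass and rounds
#' element counts; used to draw realistic isotope ladders for marker-database
#' entries whose sequence is not recorded.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @return Named integer vector with elements C, H, N, O, S.
#' @export
averagine_composition <- function(mass) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0) {
    abort("`mass` must be a single positive number.")
  }
  comp <- round(AVERAGINE * mass / AVERAGINE_MASS)
  comp[comp < 0] <- 0
  comp["H"] <- max(comp["H"], 1)
  comp["C"] <- max(comp["C"], 1)
  storage.mode(comp) <- "integer"
  comp
}

#' Isotope envelope of an elemental composition
#'
#' Computes the aggregated isotopologue envelope (A0, A1, A2, ...) by
#' iterative convolution of per-element isotope distributions at standard
#' terrestrial abundances.  Within each nucleon offset the m/z is the
#' abundance-weighted centroid.
#'
#' @param composition Named integer vector of element counts (C, H, N, O, S),
#'   e.g. from [peptide_composition()].
#' @param charge Positive integer charge; the envelope is reported as
#'   protonated m/z values.
#' @param threshold Minimum relative abundance retained after normalisation
#'   (default 1e-4, commensurate with MALDI dynamic range).
#' @return A tibble with columns `offset` (nucleon offset from monoisotopic),
#'   `mz` and `abundance`.  Abundances are renormalised over the full
#'   (untruncated) envelope, so they sum to at most 1.
#' @examples
#' isotope_envelope(c(C = 1), threshold = 0)   # 12C/13C abundances
#' isotope_envelope(peptide_composition("GVQGPPGPAGPR", 1))
#' @export
isotope_envelope <- function(composition, charge = 1L, threshold = 1e-4) {
  if (length(composition) == 0 || is.null(names(composition))) {
    abort("`composition` must be a named vector of element counts.")
  }
  bad <- setdiff(names(composition), names(ISOTOPES))
  if (length(bad)) {
    abort(sprintf("Unknown element(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(composition < 0)) abort("Element counts must be non-negative.")
  if (sum(composition) == 0) abort("`composition` must contain at least one atom.")
  if (charge < 1) abort("`charge` must be >= 1.")

  dist <- list(w = 1, wm = 0)  # abundance and abundance*mass per offset
  for (el in names(composition)) {
    n <- composition[[el]]
    if (n == 0) next
    iso <- ISOTOPES[[el]]
    base <- list(w = iso$abundance, wm = iso$abundance * iso$mass)
    dist <- conv_dist(dist, dist_power(base, n))
  }
  ab <- dist$w / sum(dist$w)
  mz <- (dist$wm / dist$w + charge * MASS_PROTON) / charge
  keep <- ab >= threshold & dist$w > 0
  tibble::tibble(
    offset = which(keep) - 1L,
    mz = mz[keep],
    abundance = ab[keep]
  )
}

#' @rdname isotope_envelope
#' @inheritParams peptide_mass
#' @export
peptide_envelope <- function(sequence, n_hydroxylations = 0,
                             n_deamidations = 0, charge = 1L,
                             threshold = 1e-4) {
  isotope_envelope(
    peptide_composition(sequence, n_hydroxylations, n_deamidations),
    charge = charge, threshold = threshold
  )
}

# Convolution of two offset-indexed distributions carrying abundance (w)
# and abundance-weighted mass (wm).
conv_dist <- function(a, b, tol = 1e-15) {
  na <- length(a$w); nb <- length(b$w)
  w <- numeric(na + nb - 1)
  wm <- numeric(na + nb - 1)
  ma <- ifelse(a$w > 0, a$wm / a$w, 0)
  mb <- ifelse(b$w > 0, b$wm / b$w, 0)
  for (i in seq_len(na)) {
    if (a$w[i] == 0) next
    j <- seq_len(nb)
    k <- i + j - 1
    ww <- a$w[i] * b$w
    w[k] <- w[k] + ww
    wm[k] <- wm[k] + ww * (ma[i] + mb)
  }
  # trim vanishing tail so repeated convolution stays small
  last <- max(which(w > tol), 1)
  list(w = w[seq_len(last)], wm = wm[seq_len(last)])
}

# Distribution of n i.i.d. atoms by binary exponentiation.
dist_power <- function(base, n) {
  out <- list(w = 1, wm = 0)
  sq <- base
  while (n > 0) {
    if (n %% 2 == 1) out <- conv_dist(out, sq)
    n <- n %/% 2
    if (n > 0) sq <- conv_dist(sq, sq)
  }
  out
}
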