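#' Simulate a MALDI-TOF collagen fingerprint spectrum
#'
#' Generates a profile spectrum containing the marker series of one taxon:
#' a Gaussian isotope ladder at each marker m/z (envelope from the marker's
#' peptide sequence when recorded in the database, otherwise from an
#' averagine-model composition), optional deamidated satellites at
#' +0.984016 Da, suppression of markers above a high-mass cutoff (the
#' low-mass bias typical of non-destructive extraction), and an additive
#' noise floor.  Identical configuration and seed give identical arrays.
#'
#' The noise floor is bounded uniform chatter on `[0, noise_scale]`.  Its
#' MAD-based level (what [pick_peaks()] estimates) is about
#' `0.371 * noise_scale`, and no noise-only local maximum can exceed
#' S/N ~2.7, so an S/N > 3 picker stays silent on empty spectra — the
#' behaviour expected of blank extractions.  The `snr` of a marker is
#' defined against that estimated level, so a marker simulated at
#' `snr = 10` is picked at approximately S/N 10.
#'
#' @param markers Marker database tibble (see [read_marker_db()]), with
#'   optional `sequence` and `n_hyd` columns giving peptide provenance.
#' @param taxon Taxon whose marker series is simulated.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param snr Apex signal-to-noise of each marker's monoisotopic peak.
#' @param deamidation_fraction Fraction of each sequence-backed marker's
#'   signal carried by its deamidated form (0 = pristine).
#' @param mass_cutoff Markers above this m/z are suppressed (default 2500,
#'   matching the observed absence of heavy peptides in triboelectric
#'   extracts); `Inf` disables the truncation.
#' @param mz_range,step Sampled m/z grid (defaults 1000-3500 Da, 0.05 Da).
#' @param resolving_power Instrument resolving power (FWHM = m/z / R,
#'   default 5000, a plausible linear-mode MALDI-TOF width).
#' @param noise_scale Upper bound of the uniform noise floor.
#' @param decay_scale Optional exponential intensity decay length in Da;
#'   `NULL` (default) applies no decay.
#' @return A [new_spectrum()] tibble.
#' @export
simulate_spectrum <- function(markers, taxon, seed = 1L, snr = 10,
                              deamidation_fraction = 0,
                              mass_cutoff = 2500,
                              mz_range = c(1000, 3500), step = 0.05,
                              resolving_power = 5000, noise_scale = 1,
                              decay_scale = NULL) {
  check_marker_db(markers)
  mk <- dplyr::filter(markers, .data$taxon == !!taxon)
  if (nrow(mk) == 0) abort(sprintf("Taxon '%s' not in marker database.", taxon))
  if (snr < 0) abort("`snr` must be non-negative.")
  if (!is.infinite(mass_cutoff) && mass_cutoff <= 1000) {
    abort("`mass_cutoff` must exceed 1000 m/z.")
  }

  mz <- seq(mz_range[1], mz_range[2], by = step)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  noise <- stats::runif(length(mz), 0, noise_scale)
  noise_level <- mad(noise)           # what the picker will estimate
  intensity <- noise

  for (i in seq_len(nrow(mk))) {
    m0 <- mk$mz[i]
    if (m0 > mass_cutoff) next
    amp <- snr * noise_level
    if (!is.null(decay_scale)) {
      amp <- amp * exp(-(m0 - mz_range[1]) / decay_scale)
    }
    if (amp <= 0) next
    seqn <- if ("sequence" %in% names(mk)) mk$sequence[i] else NA_character_
    nh <- if ("n_hyd" %in% names(mk) && !is.na(mk$n_hyd[i])) mk$n_hyd[i] else 0L
    if (!is.na(seqn) && nzchar(seqn)) {
      env0 <- peptide_envelope(seqn, nh, 0)
      has_nq <- sum(strsplit(seqn, "")[[1]] %in% c("N", "Q")) > 0
      comps <- if (has_nq && deamidation_fraction > 0) {
        list(
          list(env = env0, w = 1 - deamidation_fraction),
          list(env = peptide_envelope(seqn, nh, 1), w = deamidation_fraction)
        )
      } else {
        list(list(env = env0, w = 1))
      }
    } else {
      env0 <- isotope_envelope(averagine_composition(m0 - MASS_PROTON))
      env0$mz <- env0$mz - env0$mz[1] + m0  # anchor at the database m/z
      comps <- list(list(env = env0, w = 1))
    }
    sigma <- m0 / resolving_power / 2.3548  # FWHM -> sd
    for (comp in comps) {
      env <- comp$env
      scale <- amp * comp$w / env$abundance[1]
      for (j in seq_len(nrow(env))) {
        sel <- abs(mz - env$mz[j]) <= 5 * sigma
        if (!any(sel)) next
        intensity[sel] <- intensity[sel] +
          scale * env$abundance[j] * exp(-(mz[sel] - env$mz[j])^2 / (2 * sigma^2))
      }
    }
  }
  sp <- new_spectrum(mz, intensity,
                     metadata = sprintf("simulated %s seed %d", taxon, seed))
  attr(sp, "noise_level") <- noise_level
  sp
}

#' Simulate pure noise (an empty extraction)
#'
#' @inheritParams simulate_spectrum
#' @return A [new_spectrum()] tibble with no peptide signal.
#' @export
simulate_noise_spectrum <- function(seed = 1L, mz_range = c(1000, 3500),
                                    step = 0.05, noise_scale = 1) {
  mz <- seq(mz_range[1], mz_range[2], by = step)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  new_spectrum(mz, stats::runif(length(mz), 0, noise_scale),
               metadata = sprintf("simulated noise seed %d", seed))
}

#' Simulate a faunal assemblage and rib-blank observations
#'
#' Rib counts are drawn multinomially from the specified true frequencies;
#' the rib-blank (tool) observations are drawn either under the
#' opportunistic null (multinomial at the same frequencies) or under the
#' size-selective alternative (a Dirichlet draw with the supplied
#' concentrations, then a multinomial).
#'
#' @param groups Tibble with columns `group`, `freq` (true rib frequencies
#'   summing to 1).
#' @param n_ribs Total number of rib specimens in the assemblage.
#' @param n_obs Number of rib-blank observations to draw.
#' @param hypothesis `"h0"` (opportunistic) or `"ha"` (selective).
#' @param alpha Named concentration vector for `"ha"` (one per group).
#' @param seed Integer seed.
#' @return List with `assemblage` (tibble usable by [rib_profile()]), `obs`
#'   (named count vector) and `p_obs` (the category probabilities the
#'   observations were drawn with).
#' @export
simulate_assemblage <- function(groups, n_ribs, n_obs,
                                hypothesis = c("h0", "ha"), alpha = NULL,
                                seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  if (abs(sum(groups$freq) - 1) > 1e-8) abort("`freq` must sum to 1.")
  if (any(groups$freq < 0)) abort("`freq` must be non-negative.")
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ribs <- as.integer(rmultinom(1, n_ribs, groups$freq))
  p_obs <- groups$freq
  if (hypothesis == "ha") {
    if (is.null(alpha)) abort("`alpha` is required under the selective hypothesis.")
    alpha <- alpha[match(groups$group, names(alpha))]
    if (anyNA(alpha)) abort("`alpha` must be named by group and cover all groups.")
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    p_obs <- g / sum(g)
  }
  obs <- as.integer(rmultinom(1, n_obs, p_obs))
  list(
    assemblage = tibble::tibble(
      taxon = groups$group, nisp = ribs, ribs = ribs, group = groups$group
    ),
    obs = setNames(obs, groups$group),
    p_obs = setNames(p_obs, groups$group)
  )
}

#' Paths to the packaged fixture tables
#'
#' The package ships small plain-text fixtures: the faunal assemblage
#' tables of the two sites (NISP and rib tallies per taxon and layer, with
#' the category grouping used by the selection test), a body-mass table,
#' a compact synthetic marker database, and synthetic protein sequences for
#' digestion examples.  Rib tallies are the smallest integer counts
#' consistent with the published rib percentages; body masses and marker
#' series other than P1 are labelled synthetic in the files themselves.
#'
#' @param file Fixture file name; empty to list available fixtures.
#' @return Full path to the fixture.
#' @examples
#' zoomsel_extdata()
#' read_assemblage(zoomsel_extdata("assemblage_abri_peyrony.tsv"), "L-3A")
#' @export
zoomsel_extdata <- function(file = "") {
  if (!nzchar(file)) {
    return(dir(system.file("extdata", package = "zoomsel")))
  }
  path <- system.file("extdata", file, package = "zoomsel")
  if (!nzchar(path)) abort(sprintf("No packaged fixture '%s'.", file))
  path
}

#' Default clade-merge rules for the packaged marker database
#'
#' Aurochs and bison cannot be separated on the available collagen markers;
#' their rule yields the merged clade label "Bison sp./Bos sp.".
#'
#' @return List of character vectors of mutually indistinguishable taxa.
#' @export
default_merge_rules <- function() {
  list(c("Bison sp.", "Bos sp."))
}

# Save/restore the RNG state so seeded simulators do not disturb the
# caller's random stream.
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
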