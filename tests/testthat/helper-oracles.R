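# Independent oracles and small builders used across the test files.

# Isotope-distribution tables duplicated here so the oracle does not share
# constants with the implementation path it checks.
oracle_isotopes <- list(
  C = list(offset = c(0, 1), p = c(0.9893, 0.0107)),
  H = list(offset = c(0, 1), p = c(0.999885, 0.000115)),
  N = list(offset = c(0, 1), p = c(0.99636, 0.00364)),
  O = list(offset = c(0, 1, 2), p = c(0.99757, 0.00038, 0.00205)),
  S = list(offset = c(0, 1, 2, 4), p = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# Brute-force isotopologue envelope: enumerates, per element, every way of
# distributing n atoms over its isotopes (multinomial probabilities), and
# accumulates abundance by total nucleon offset.  Exponential in the number
# of isotopes, usable for compositions up to ~60 atoms.
oracle_envelope <- function(composition, max_offset = 10) {
  dist <- c(1, numeric(max_offset))  # index 1 = offset 0
  for (el in names(composition)) {
    n <- composition[[el]]
    if (n == 0) next
    iso <- oracle_isotopes[[el]]
    k <- length(iso$p)
    # enumerate counts over heavy isotopes (positions 2..k)
    grid <- expand.grid(rep(list(0:n), k - 1))
    el_dist <- numeric(max_offset + 1)
    for (r in seq_len(nrow(grid))) {
      heavy <- as.integer(grid[r, ])
      if (sum(heavy) > n) next
      counts <- c(n - sum(heavy), heavy)
      off <- sum(heavy * iso$offset[-1])
      if (off > max_offset) next
      el_dist[off + 1] <- el_dist[off + 1] + dmultinom(counts, prob = iso$p)
    }
    new <- numeric(max_offset + 1)
    for (i in seq_along(dist)) {
      if (dist[i] == 0) next
      j <- seq_len(max_offset + 2 - i)
      new[i + j - 1] <- new[i + j - 1] + dist[i] * el_dist[j]
    }
    dist <- new
  }
  dist
}

# Gaussian profile spectrum from envelope components, built independently
# of simulate_spectrum (used for noise-free deamidation cases).
profile_from_envelopes <- function(components, mz_range, step = 0.01,
                                   sigma = 0.094, noise = 0) {
  mz <- seq(mz_range[1], mz_range[2], by = step)
  y <- rep(noise, length(mz))
  for (comp in components) {
    env <- comp$env
    for (j in seq_len(nrow(env))) {
      y <- y + comp$weight * env$abundance[j] *
        exp(-(mz - env$mz[j])^2 / (2 * sigma^2))
    }
  }
  new_spectrum(mz, y)
}

# All count vectors of length k summing to n (for likelihood normalisation).
compositions_of <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- NULL
  for (i in 0:n) {
    rest <- compositions_of(n - i, k - 1)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

fixture_markers <- function() {
  read_marker_db(zoomsel_extdata("marker_db_synthetic.tsv"))
}

fixture_assemblage <- function(layer) {
  read_assemblage(zoomsel_extdata("assemblage_abri_peyrony.tsv"), layer)
}
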