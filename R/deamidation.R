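#' Estimate the extent of deamidation of a peptide from its envelope
#'
#' Collagen degradation deamidates glutamine/asparagine, shifting part of a
#' peptide's signal +0.984016 Da and overlapping its isotope envelope.  The
#' extent is estimated by non-negative mixture fitting: theoretical isotope
#' envelopes are built for 0, 1, ..., k deamidations (k = number of N/Q
#' residues), each is rendered as a Gaussian profile template with a peak
#' width estimated from the tallest peak in the envelope region, the local
#' background (median intensity in the signal-free gap just below the
#' monoisotopic peak) is subtracted, and the template weights `w` are
#' fitted to the observed profile by non-negative least squares.  Fitting
#' the whole profile rather than a handful of integrated apex positions
#' averages the noise over the full envelope region and keeps the estimate
#' stable when the deamidated ladder overlaps the +1 isotope ladder
#' (0.984 vs. 1.003 Da spacing).
#'
#' The reported value is `w0 / sum(w)`: 1.0 means fully non-deamidated
#' (fresh, potentially modern collagen), values well below 1 indicate
#' degraded, ancient collagen.
#'
#' By default the assessed peptide is P1105 (GVQGPPGPAGPR with one
#' hydroxyproline, one glutamine), the marker conventionally used for this
#' purpose because it is shared across mammals.
#'
#' @param spectrum A [new_spectrum()] tibble covering the envelope region.
#' @param sequence Peptide sequence (default `"GVQGPPGPAGPR"`).
#' @param n_hydroxylations Hydroxyproline count of the assessed species
#'   (default 1, giving the 1105.575 m/z base peak).
#' @param charge Charge state (default 1).
#' @param min_snr Minimum apex signal-to-noise in the envelope region; below
#'   it the result is withheld as `"insufficient signal"` (default 3).
#' @param noise_window Window width for noise estimation (default 100 Da).
#' @param sigma Gaussian peak width (standard deviation, Da) of the profile
#'   templates; `NULL` (default) estimates it from the tallest peak in the
#'   envelope region.
#' @return One-row tibble of class `deamidation_fit` with columns
#'   `sequence`, `value`, `residual`, `n_points`, `status` and a `weights`
#'   list-column of the fitted component weights.
#' @export
fit_deamidation <- function(spectrum, sequence = "GVQGPPGPAGPR",
                            n_hydroxylations = 1L, charge = 1L,
                            min_snr = 3, noise_window = 100, sigma = NULL) {
  res <- check_peptide(sequence, n_hydroxylations, 0)
  k <- sum(res %in% c("N", "Q"))
  if (k == 0) {
    abort("`sequence` has no N/Q residue; deamidation is undefined.")
  }
  envs <- purrr::map(0:k, function(d) {
    peptide_envelope(sequence, n_hydroxylations, d, charge = charge)
  })
  base_mz <- envs[[1]]$mz[1]
  hi <- max(purrr::map_dbl(envs, ~ max(.x$mz)))
  if (min(spectrum$mz) > base_mz - 1 || max(spectrum$mz) < hi) {
    abort(sprintf(
      "Spectrum does not cover the envelope region [%.2f, %.2f].",
      base_mz - 1, hi
    ))
  }

  region <- which(spectrum$mz >= base_mz - 0.3 & spectrum$mz <= hi + 0.5)
  x <- spectrum$mz[region]
  y <- spectrum$intensity[region]

  out <- function(value, residual, status, w) {
    fit <- tibble::tibble(
      sequence = sequence, value = value, residual = residual,
      n_points = length(region), status = status, weights = list(w)
    )
    class(fit) <- c("deamidation_fit", class(fit))
    fit
  }

  noise <- point_noise(spectrum, noise_window)
  apex_i <- region[which.max(y)]
  apex_snr <- if (noise[apex_i] > 0) {
    spectrum$intensity[apex_i] / noise[apex_i]
  } else if (spectrum$intensity[apex_i] > 0) Inf else 0
  if (apex_snr < min_snr) {
    return(out(NA_real_, NA_real_, "insufficient signal", numeric(0)))
  }

  # rough background (for width estimation only): median intensity in the
  # signal-free gap below the monoisotopic peak
  bg_sel <- spectrum$mz >= base_mz - 0.85 & spectrum$mz <= base_mz - 0.35
  background <- if (any(bg_sel)) median(spectrum$intensity[bg_sel]) else 0
  b <- y - background

  # peak width from the second moment of the tallest peak (+/- 0.25 Da)
  if (is.null(sigma)) {
    apex_mz <- spectrum$mz[apex_i]
    wsel <- abs(x - apex_mz) <= 0.25 & b > 0
    sigma <- if (sum(wsel) >= 3) {
      mu <- sum(x[wsel] * b[wsel]) / sum(b[wsel])
      sqrt(sum(b[wsel] * (x[wsel] - mu)^2) / sum(b[wsel]))
    } else {
      apex_mz / 5000 / 2.3548  # nominal MALDI-TOF width
    }
  }
  sigma <- max(sigma, 1e-3)

  # design: one profile template per deamidation state plus a constant
  # column absorbing the flat background (all weights constrained >= 0)
  A <- vapply(envs, function(e) {
    rowSums(vapply(seq_len(nrow(e)), function(j) {
      e$abundance[j] * exp(-(x - e$mz[j])^2 / (2 * sigma^2))
    }, numeric(length(x))))
  }, numeric(length(x)))
  A <- cbind(A, 1)

  if (sum(pmax(b, 0)) <= 0) {
    return(out(NA_real_, NA_real_, "insufficient signal", numeric(0)))
  }
  fit <- pracma::lsqnonneg(A, y)
  w <- head(fit$x, -1)            # drop the background coefficient
  rss <- sqrt(fit$resid.norm)
  # detection limit: a component whose weight is within noise of zero is
  # not reported (counters the positive bias of the >= 0 constraint)
  dof <- length(y) - ncol(A)
  if (dof > 0 && rss > 0) {
    sd_res <- rss / sqrt(dof)
    se <- tryCatch(
      sd_res * sqrt(diag(solve(crossprod(A)))),
      error = function(e) rep(0, ncol(A))
    )
    w[w < 1.5 * head(se, -1)] <- 0
  }
  if (sum(w) <= 0) {
    return(out(NA_real_, rss, "insufficient signal", w))
  }
  out(w[1] / sum(w), rss, "ok", w)
}

#' @exportS3Method generics::glance
glance.deamidation_fit <- function(x, ...) {
  tibble::tibble(
    sequence = x$sequence, value = x$value, status = x$status,
    residual = x$residual, n_points = x$n_points
  )
}
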