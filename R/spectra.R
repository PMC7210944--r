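#' Construct a mass spectrum
#'
#' A spectrum is a tibble with ascending `mz` (Da) and non-negative
#' `intensity` columns; free-text metadata is carried in the `"metadata"`
#' attribute.
#'
#' @param mz,intensity Equal-length numeric vectors; `mz` strictly
#'   increasing, `intensity` >= 0.
#' @param metadata Optional free-text metadata (instrument, source file).
#' @return A tibble of class `zooms_spectrum`.
#' @export
new_spectrum <- function(mz, intensity, metadata = character()) {
  if (length(mz) != length(intensity) || length(mz) < 2) {
    abort("`mz` and `intensity` must have equal length >= 2.")
  }
  bad <- which(diff(mz) <= 0)
  if (length(bad)) {
    abort(sprintf("`mz` must be strictly increasing (first violation at index %d).",
                  bad[1] + 1L))
  }
  if (any(intensity < 0)) abort("Intensities must be non-negative.")
  out <- tibble::tibble(mz = as.numeric(mz), intensity = as.numeric(intensity))
  attr(out, "metadata") <- metadata
  class(out) <- c("zooms_spectrum", class(out))
  out
}

#' Read a mass spectrum from disk
#'
#' Two formats are supported: two-column text (whitespace- or
#' comma-separated m/z and intensity per line, `#` comments ignored) and a
#' minimal mzML subset (first spectrum of a single run, read through
#' \pkg{mzR}).  Format is inferred from the file extension unless given.
#'
#' @param path File path.
#' @param format `"auto"`, `"text"` or `"mzml"`.
#' @return A [new_spectrum()] tibble.
#' @export
read_spectrum <- function(path, format = c("auto", "text", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "text"
  }
  if (format == "mzml") {
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh), add = TRUE)
    if (length(fh) < 1) abort(sprintf("No spectra found in mzML file '%s'.", path))
    pk <- mzR::peaks(fh, 1)
    return(new_spectrum(pk[, 1], pk[, 2], metadata = basename(path)))
  }
  lines <- readLines(path)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("No data lines in '%s'.", path))
  parts <- stringr::str_split(lines, "[,\\s]+")
  vals <- suppressWarnings(purrr::map(parts, as.numeric))
  if (any(purrr::map_int(vals, length) < 2) || anyNA(unlist(vals))) {
    abort(sprintf("Malformed m/z-intensity line in '%s'.", path))
  }
  new_spectrum(
    purrr::map_dbl(vals, 1), purrr::map_dbl(vals, 2),
    metadata = basename(path)
  )
}

#' Write a spectrum as two-column text or minimal mzML
#'
#' The mzML writer emits a single centroid/profile spectrum with
#' uncompressed 64-bit little-endian arrays; it exists so that simulated
#' spectra can exercise the mzML reading path.
#'
#' @param spectrum A [new_spectrum()] tibble.
#' @param path Output path; `write_spectrum_mzml()` should end in `.mzML`.
#' @return The path, invisibly.
#' @export
write_spectrum_text <- function(spectrum, path) {
  writeLines(
    c("# m/z intensity", sprintf("%.6f %.6f", spectrum$mz, spectrum$intensity)),
    path
  )
  invisible(path)
}

#' @rdname write_spectrum_text
#' @export
write_spectrum_mzml <- function(spectrum, path) {
  enc <- function(x) {
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  }
  b_mz <- enc(spectrum$mz)
  b_it <- enc(spectrum$intensity)
  arr <- function(b, acc, nm) {
    paste0(
      '      <binaryDataArray encodedLength="', nchar(b), '">\n',
      '        <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '        <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '        <cvParam cvRef="MS" accession="', acc, '" name="', nm, '" value=""/>\n',
      '        <binary>', b, '</binary>\n',
      '      </binaryDataArray>'
    )
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://psi.hupo.org"/></cvList>\n',
    '  <run id="run1">\n',
    '    <spectrumList count="1" defaultDataProcessingRef="dp">\n',
    '      <spectrum index="0" id="scan=1" defaultArrayLength="', nrow(spectrum), '">\n',
    '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
    '        <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>\n',
    '        <binaryDataArrayList count="2">\n',
    arr(b_mz, "MS:1000514", "m/z array"), '\n',
    arr(b_it, "MS:1000515", "intensity array"), '\n',
    '        </binaryDataArrayList>\n',
    '      </spectrum>\n',
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n'
  )
  cat(xml, file = path)
  invisible(path)
}

#' Robust windowed noise estimation
#'
#' Tiles the m/z range with fixed-width windows and estimates the noise
#' level in each as 1.4826 times the median absolute deviation of the
#' intensities (consistent for Gaussian noise, insensitive to sparse
#' peaks).
#'
#' @param spectrum A [new_spectrum()] tibble.
#' @param window Window width in Da (default 100).
#' @return Tibble with columns `mz_lo`, `mz_hi`, `noise`.
#' @export
estimate_noise <- function(spectrum, window = 100) {
  if (window <= 0) abort("`window` must be positive.")
  lo <- floor(min(spectrum$mz) / window) * window
  hi <- max(spectrum$mz)
  starts <- seq(lo, hi, by = window)
  idx <- pmin(findInterval(spectrum$mz, starts), length(starts))
  noise <- vapply(
    seq_along(starts),
    function(i) {
      x <- spectrum$intensity[idx == i]
      if (!length(x)) return(NA_real_)
      mad(x)  # stats::mad already applies the 1.4826 consistency factor
    },
    numeric(1)
  )
  tibble::tibble(mz_lo = starts, mz_hi = starts + window, noise = noise)
}

# Per-point noise lookup used by the peak picker.
point_noise <- function(spectrum, window = 100) {
  nz <- estimate_noise(spectrum, window)
  idx <- pmin(findInterval(spectrum$mz, nz$mz_lo), nrow(nz))
  nz$noise[idx]
}

#' Pick peaks above a signal-to-noise threshold
#'
#' Local maxima whose apex intensity exceeds `snr_threshold` times the
#' windowed noise level are reported; the centroid is the intensity-weighted
#' mean m/z over the contiguous run of samples above half maximum (at
#' least the apex +/- 2 samples).  If the median point spacing exceeds
#' 0.1 Da the input is treated as already centroided and only thresholded.
#'
#' @param spectrum A [new_spectrum()] tibble.
#' @param snr_threshold Minimum apex signal-to-noise ratio (default 3,
#'   the conventional picking threshold for ZooMS fingerprints).
#' @param noise_window Noise-estimation window width in Da.
#' @param min_separation Minimum m/z distance between reported apexes
#'   (default 0.3 Da): a local maximum is only reported if it is the
#'   largest sample within that distance, which suppresses noise
#'   sub-maxima on peak flanks while keeping the ~1 Da isotopologue
#'   spacing resolvable.
#' @return Tibble of class `zooms_peaks` with columns `mz`, `intensity`,
#'   `snr`, sorted by `mz`.
#' @export
pick_peaks <- function(spectrum, snr_threshold = 3, noise_window = 100,
                       min_separation = 0.3) {
  if (snr_threshold <= 0) abort("`snr_threshold` must be positive.")
  noise <- point_noise(spectrum, noise_window)
  y <- spectrum$intensity
  n <- length(y)
  centroided <- median(diff(spectrum$mz)) > 0.1
  if (centroided) {
    apex <- which(y > 0)
  } else {
    interior <- seq(2L, n - 1L)
    apex <- interior[y[interior] > y[interior - 1L] & y[interior] > y[interior + 1L]]
    apex <- apex[y[apex] > 0]
  }
  snr <- ifelse(noise[apex] > 0, y[apex] / noise[apex], Inf)
  sel <- snr > snr_threshold
  keep <- apex[sel]
  snr <- snr[sel]
  if (!centroided && length(keep)) {
    # report only apexes that dominate their +/- min_separation window,
    # suppressing noise sub-maxima riding on peak flanks
    lo <- findInterval(spectrum$mz[keep] - min_separation, spectrum$mz) + 1L
    hi <- findInterval(spectrum$mz[keep] + min_separation, spectrum$mz)
    dominant <- vapply(seq_along(keep), function(j) {
      y[keep[j]] >= max(y[lo[j]:hi[j]])
    }, logical(1))
    keep <- keep[dominant]
    snr <- snr[dominant]
  }
  if (centroided) {
    cen <- spectrum$mz[keep]
  } else {
    # centroid over the contiguous run above half maximum (>= apex +/- 2
    # samples), so wide peaks use their full width rather than a fixed
    # 5-sample window
    cen <- vapply(keep, function(i) {
      half <- y[i] / 2
      l <- i
      while (l > 1 && y[l - 1] >= half) l <- l - 1
      r <- i
      while (r < n && y[r + 1] >= half) r <- r + 1
      j <- max(1, min(l, i - 2)):min(n, max(r, i + 2))
      sum(spectrum$mz[j] * y[j]) / sum(y[j])
    }, numeric(1))
  }
  out <- tibble::tibble(mz = cen, intensity = y[keep], snr = snr)
  out <- dplyr::arrange(out, .data$mz)
  class(out) <- c("zooms_peaks", class(out))
  out
}

#' Select monoisotopic peaks, keeping deamidated variants
#'
#' Walks the picked peaks in ascending m/z and assigns each to an
#' isotopologue cluster when it lies one nucleon spacing (1.00336/charge,
#' within `tol`) above an existing cluster member; only the lowest-m/z
#' member of a cluster is flagged monoisotopic.  A peak ~0.984/charge above
#' a monoisotopic peak is the deamidated form of the same peptide, not an
#' isotope: it is retained, flagged `deamidated`, and seeds its own isotope
#' ladder.
#'
#' @param peaks Tibble from [pick_peaks()], sorted by m/z.
#' @param charge Charge state (default 1).
#' @param tol Spacing tolerance in Da (default 0.02, which separates the
#'   1.00336 isotope spacing from the 0.98402 deamidation shift at
#'   MALDI-TOF accuracy).
#' @return The peaks tibble with logical columns `monoisotopic` and
#'   `deamidated` added.
#' @export
select_monoisotopic <- function(peaks, charge = 1L, tol = 0.02) {
  n <- nrow(peaks)
  mono <- logical(n)
  deam <- logical(n)
  cluster <- integer(n)         # cluster id per peak
  if (n) {
    next_id <- 0L
    iso_step <- ISOTOPE_SPACING / charge
    deam_step <- MASS_DEAMIDATION / charge
    for (i in seq_len(n)) {
      d <- peaks$mz[i] - peaks$mz[seq_len(i - 1)]
      iso_prev <- which(abs(d - iso_step) <= tol)
      deam_prev <- which(abs(d - deam_step) <= tol & mono[seq_len(i - 1)])
      # the isotope (1.00336) and deamidation (0.98402) windows overlap at
      # tol 0.02: the nearer spacing wins
      if (length(iso_prev) && length(deam_prev)) {
        if (min(abs(d[deam_prev] - deam_step)) < min(abs(d[iso_prev] - iso_step))) {
          iso_prev <- integer(0)
        } else {
          deam_prev <- integer(0)
        }
      }
      if (length(iso_prev)) {
        cluster[i] <- cluster[iso_prev[length(iso_prev)]]
      } else if (length(deam_prev)) {
        next_id <- next_id + 1L
        cluster[i] <- next_id
        mono[i] <- TRUE
        deam[i] <- TRUE
      } else {
        next_id <- next_id + 1L
        cluster[i] <- next_id
        mono[i] <- TRUE
      }
    }
  }
  out <- dplyr::mutate(peaks, monoisotopic = mono, deamidated = deam)
  class(out) <- c("zooms_peaks", setdiff(class(out), "zooms_peaks"))
  out
}

#' Write picked peaks as TSV
#' @param peaks Tibble from [pick_peaks()] or [select_monoisotopic()].
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  readr::write_tsv(peaks, path)
  invisible(path)
}

#' Plot a spectrum with picked peaks
#'
#' @param spectrum A [new_spectrum()] tibble.
#' @param peaks Optional peaks tibble to annotate.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, peaks = NULL) {
  p <- ggplot2::ggplot(spectrum, ggplot2::aes(.data$mz, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "m/z", y = "Intensity") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_point(
      data = peaks, colour = "firebrick", size = 1,
      ggplot2::aes(.data$mz, .data$intensity)
    )
  }
  p
}
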