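#' Signed mass error in parts per million
#'
#' @param observed,theoretical Positive m/z values.
#' @return Signed ppm error; matching uses its absolute value.
#' @examples
#' ppm_error(1105.6303, 1105.575) # just over +50 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(observed <= 0) || any(theoretical <= 0)) {
    abort("m/z values must be positive.")
  }
  1e6 * (observed - theoretical) / theoretical
}

#' Read a taxon marker database
#'
#' TSV with columns `taxon`, `marker`, `mz` and optional `note` (free-text
#' provenance, e.g. the peptide sequence behind a marker) and `clade`
#' (higher-level group used for less-specific calls).
#'
#' @param path TSV path.
#' @return Tibble of marker records; `(taxon, marker)` pairs are unique.
#' @export
read_marker_db <- function(path) {
  db <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  if ("mz" %in% names(db)) db$mz <- as.numeric(db$mz)
  if ("n_hyd" %in% names(db)) db$n_hyd <- as.integer(db$n_hyd)
  check_marker_db(db)
  db
}

check_marker_db <- function(db) {
  if (!all(c("taxon", "marker", "mz") %in% names(db))) {
    abort("Marker database needs columns `taxon`, `marker`, `mz`.")
  }
  if (any(db$mz <= 0)) abort("Marker m/z values must be positive.")
  if (anyDuplicated(db[c("taxon", "marker")])) {
    abort("Duplicate (taxon, marker) pairs in marker database.")
  }
  invisible(db)
}

#' Match picked peaks against a peptide mass library
#'
#' Each monoisotopic peak is assigned to the nearest library entry within
#' the ppm tolerance (ties broken by smaller absolute ppm, then lower
#' library m/z); a protein is accepted when at least `min_peptides`
#' distinct peptide sequences match, mirroring the two-peptide acceptance
#' rule of peptide mass fingerprinting.
#'
#' @param peaks Peaks tibble; if a `monoisotopic` column is present only
#'   flagged peaks are used.
#' @param library Mass library tibble from [build_mass_library()].
#' @param ppm_tol Maximum absolute ppm error (default 50).
#' @param min_peptides Minimum distinct matching peptides per accepted
#'   protein (default 2).
#' @return Tibble of peptide-level matches with columns `peak_mz`,
#'   `protein_id`, `taxon`, `sequence`, `n_hyd`, `n_deam`, `library_mz`,
#'   `ppm`, `accepted` (protein-level flag).
#' @export
match_library <- function(peaks, library, ppm_tol = 50, min_peptides = 2L) {
  if (is.null(library) || nrow(library) == 0) abort("`library` is empty.")
  if (ppm_tol <= 0) abort("`ppm_tol` must be positive.")
  if ("monoisotopic" %in% names(peaks)) {
    peaks <- dplyr::filter(peaks, .data$monoisotopic)
  }
  empty <- tibble::tibble(
    peak_mz = double(), protein_id = character(), taxon = character(),
    sequence = character(), n_hyd = integer(), n_deam = integer(),
    library_mz = double(), ppm = double(), accepted = logical()
  )
  if (nrow(peaks) == 0) return(empty)

  hits <- purrr::map_dfr(peaks$mz, function(obs) {
    ppm <- ppm_error(obs, library$mz)
    ok <- which(abs(ppm) <= ppm_tol)
    if (!length(ok)) return(NULL)
    # nearest entry per protein; ties by |ppm| then lower library m/z
    cand <- library[ok, ]
    cand$ppm <- ppm[ok]
    cand$peak_mz <- obs
    cand <- dplyr::arrange(cand, abs(.data$ppm), .data$mz)
    dplyr::slice_head(dplyr::group_by(cand, .data$protein_id), n = 1)
  })
  if (nrow(hits) == 0) return(empty)
  hits <- dplyr::ungroup(hits)
  hits <- dplyr::rename(hits, library_mz = "mz")
  acc <- dplyr::summarise(
    dplyr::group_by(hits, .data$protein_id),
    n_peptides = dplyr::n_distinct(.data$sequence)
  )
  hits <- dplyr::left_join(hits, acc, by = "protein_id")
  hits$accepted <- hits$n_peptides >= min_peptides
  dplyr::select(
    hits, "peak_mz", "protein_id", "taxon", "sequence", "n_hyd", "n_deam",
    "library_mz", "ppm", "n_peptides", "accepted"
  )
}

#' Assign a taxon from marker-series matches
#'
#' Counts, per taxon, the database markers found among the monoisotopic
#' peaks within the ppm tolerance (greedily, nearest peak per marker, one
#' peak supporting at most one marker per taxon).  Candidate taxa are those
#' achieving the maximal marker count whose matched markers are not
#' contradicted (a taxon is contradicted at a marker position when another
#' candidate's mass for that marker is observed and its own is not).
#' Biogeographically excluded taxa are removed with a recorded reason.  If
#' the survivors fall within one merge rule the merged clade label is
#' reported; a call requires at least `min_markers` matched markers, below
#' which the spectrum is unidentifiable.
#'
#' @param peaks Peaks tibble (filtered to monoisotopic if flagged).
#' @param markers Marker database tibble (see [read_marker_db()]).
#' @param ppm_tol Maximum absolute ppm error (default 50).
#' @param min_markers Minimum matched markers for a call (default 2).
#' @param exclude Character vector of taxa to exclude on biogeographic
#'   grounds (e.g. musk ox in MIS5-3 southwest France).
#' @param merge_rules List of character vectors, each a set of taxa that
#'   the available markers cannot separate; the merged label joins the set
#'   with "/".
#' @return An object of class `taxon_assignment`: a list with `clade`,
#'   `status` (`"identified"`, `"less-specific"` or `"unidentifiable"`),
#'   `evidence` (tibble of matched markers with ppm errors), `candidates`,
#'   and `excluded` (tibble of taxon, reason).
#' @export
assign_taxon <- function(peaks, markers, ppm_tol = 50, min_markers = 2L,
                         exclude = character(),
                         merge_rules = list()) {
  check_marker_db(markers)
  if ("monoisotopic" %in% names(peaks)) {
    peaks <- dplyr::filter(peaks, .data$monoisotopic)
  }
  evidence_all <- purrr::map_dfr(
    split(markers, markers$taxon),
    function(mk) {
      mk <- dplyr::arrange(mk, .data$mz)
      used <- rep(FALSE, nrow(peaks))
      purrr::map_dfr(seq_len(nrow(mk)), function(i) {
        if (!nrow(peaks)) return(NULL)
        ppm <- ppm_error(peaks$mz, mk$mz[i])
        ok <- which(abs(ppm) <= ppm_tol & !used)
        if (!length(ok)) return(NULL)
        best <- ok[which.min(abs(ppm[ok]))]
        used[best] <<- TRUE
        tibble::tibble(
          taxon = mk$taxon[i], marker = mk$marker[i],
          theoretical_mz = mk$mz[i], observed_mz = peaks$mz[best],
          ppm = ppm[best]
        )
      })
    }
  )

  unident <- function(excluded) {
    structure(
      list(
        clade = NA_character_, status = "unidentifiable",
        evidence = evidence_all[0, ], candidates = character(),
        excluded = excluded
      ),
      class = "taxon_assignment"
    )
  }
  excluded_tbl <- tibble::tibble(taxon = character(), reason = character())
  if (nrow(evidence_all) == 0) return(unident(excluded_tbl))

  counts <- dplyr::count(evidence_all, .data$taxon, name = "n_markers")
  cand <- counts$taxon[counts$n_markers == max(counts$n_markers)]

  # contradiction filter: drop a candidate if, at some marker position,
  # another candidate's mass was observed while its own was not
  contradicted <- purrr::map_lgl(cand, function(t) {
    own <- dplyr::filter(evidence_all, .data$taxon == t)
    other <- dplyr::filter(evidence_all, .data$taxon != t,
                           .data$taxon %in% cand)
    any(other$marker %in% setdiff(unique(markers$marker[markers$taxon == t]),
                                  own$marker))
  })
  cand <- cand[!contradicted]
  if (!length(cand)) return(unident(excluded_tbl))

  drop <- intersect(cand, exclude)
  if (length(drop)) {
    excluded_tbl <- tibble::tibble(
      taxon = drop,
      reason = "excluded on biogeographic grounds (not in regional fauna)"
    )
    cand <- setdiff(cand, drop)
  }
  if (!length(cand)) return(unident(excluded_tbl))

  n_matched <- max(counts$n_markers[counts$taxon %in% cand])
  evidence <- dplyr::filter(evidence_all, .data$taxon %in% cand)

  merged <- merge_label(cand, merge_rules)
  status <- if (n_matched < min_markers) {
    "unidentifiable"
  } else if (!is.na(merged$label)) {
    if (merged$exact) "identified" else "less-specific"
  } else {
    "less-specific"
  }
  label <- if (!is.na(merged$label)) merged$label else paste(sort(cand), collapse = "/")
  if (status == "unidentifiable") label <- NA_character_

  structure(
    list(
      clade = label, status = status, evidence = evidence,
      candidates = sort(cand), excluded = excluded_tbl
    ),
    class = "taxon_assignment"
  )
}

# Returns the merged clade label when the candidate set sits inside one
# merge rule: exact = TRUE if it covers the rule or is a single taxon.
merge_label <- function(cand, merge_rules) {
  if (length(cand) == 1) return(list(label = cand, exact = TRUE))
  for (rule in merge_rules) {
    if (all(cand %in% rule)) {
      return(list(label = paste(sort(rule), collapse = "/"),
                  exact = setequal(cand, rule)))
    }
  }
  list(label = NA_character_, exact = FALSE)
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat("ZooMS taxon assignment\n")
  cat("  status:", x$status, "\n")
  if (!is.na(x$clade)) cat("  clade: ", x$clade, "\n")
  if (nrow(x$evidence)) {
    cat(sprintf("  markers matched: %d (|ppm| max %.1f)\n",
                length(unique(x$evidence$marker)), max(abs(x$evidence$ppm))))
  }
  if (nrow(x$excluded)) {
    cat("  excluded:", paste(x$excluded$taxon, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.taxon_assignment <- function(x, ...) {
  x$evidence
}

#' @exportS3Method generics::glance
glance.taxon_assignment <- function(x, ...) {
  tibble::tibble(
    clade = x$clade, status = x$status,
    n_markers = nrow(x$evidence),
    n_candidates = length(x$candidates),
    n_excluded = nrow(x$excluded)
  )
}

#' Screen accepted protein matches for contamination classes
#'
#' Classifies each accepted protein as an endogenous candidate (collagens),
#' a known process contaminant (trypsin used for digestion, human keratins
#' from handling), or a usage-derived candidate (albumin, hemoglobins,
#' non-human keratins, which would indicate protein transfer from worked
#' animal materials).  Spectra with accepted usage-derived candidates are
#' flagged.
#'
#' @param matches Tibble from [match_library()].
#' @return Tibble with one row per accepted protein: `protein_id`, `taxon`,
#'   `n_peptides`, `class`, `flagged`.
#' @export
contamination_screen <- function(matches) {
  acc <- dplyr::distinct(
    dplyr::filter(matches, .data$accepted),
    .data$protein_id, .data$taxon, .data$n_peptides
  )
  if (nrow(acc) == 0) {
    return(tibble::tibble(
      protein_id = character(), taxon = character(), n_peptides = integer(),
      class = character(), flagged = logical()
    ))
  }
  acc$class <- purrr::map2_chr(acc$protein_id, acc$taxon, classify_protein)
  acc$flagged <- acc$class == "usage-derived-candidate"
  acc
}

# Rule-based protein classification for the contamination screen.
classify_protein <- function(protein_id, taxon) {
  id <- toupper(protein_id)
  human <- !is.na(taxon) && grepl("homo sapiens|human", taxon, ignore.case = TRUE)
  if (grepl("CO[L0-9]?1A[12]|COL1|COLLAGEN", id)) return("endogenous-candidate")
  if (grepl("TRYP", id)) return("known-process-contaminant")
  if (grepl("K[12]C|KRT|KERATIN|K1C", id)) {
    return(if (human) "known-process-contaminant" else "usage-derived-candidate")
  }
  if (grepl("ALBU|^HBA|^HBB|HEMOGLOBIN", id)) return("usage-derived-candidate")
  "usage-derived-candidate"
}
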