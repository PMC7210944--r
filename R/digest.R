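#' In silico tryptic digestion
#'
#' Cleaves a protein C-terminal to K or R except when the next residue is
#' proline, and enumerates peptides carrying up to `missed_cleavages`
#' internal uncleaved sites, in order of occurrence.
#'
#' @param sequence Protein sequence (one-letter code).
#' @param missed_cleavages Maximum number of internal missed cleavage sites
#'   (>= 0).
#' @return Character vector of peptide sequences: all 0-missed products
#'   first (left to right), then 1-missed, and so on.
#' @examples
#' tryptic_digest("AKRPGR")          # "AK", "RPGR" (RP is protected)
#' tryptic_digest("AKGK", missed_cleavages = 1)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string.")
  }
  if (missed_cleavages < 0) abort("`missed_cleavages` must be >= 0.")
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1, n)] != "P"]
  cut_after <- c(cut_after, n)
  starts <- c(1L, head(cut_after, -1) + 1L)
  frags <- vapply(
    seq_along(starts),
    function(i) substr(sequence, starts[i], cut_after[i]),
    character(1)
  )
  out <- character(0)
  for (mc in 0:missed_cleavages) {
    if (mc + 1 > length(frags)) break
    for (i in seq_len(length(frags) - mc)) {
      out <- c(out, paste(frags[i:(i + mc)], collapse = ""))
    }
  }
  out
}

#' Read protein records from a FASTA file
#'
#' Standard multi-record FASTA with ">" headers and wrapped lines.  The
#' first whitespace-delimited token of the header is the protein identifier;
#' the remainder is kept as the description.  A taxon label is parsed from a
#' UniProt-style `OS=` field when present and can otherwise be supplied
#' downstream.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `protein_id`, `description`, `taxon`,
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(sprintf("No FASTA records found in '%s'.", path))
  header <- names(aa)
  id <- stringr::str_extract(header, "^\\S+")
  desc <- stringr::str_trim(stringr::str_remove(header, "^\\S+"))
  taxon <- stringr::str_match(desc, "OS=([^=]+?)(?:\\s+[A-Z]{2}=|$)")[, 2]
  tibble::tibble(
    protein_id = id,
    description = desc,
    taxon = stringr::str_trim(taxon),
    sequence = as.character(aa)
  )
}

#' Build an in silico peptide mass reference library
#'
#' Digests each protein tryptically, keeps peptides within the length
#' bounds, and enumerates every sequence-compatible combination of counted
#' modifications within the requested ranges (hydroxylations bounded by the
#' proline count, deamidations by the N+Q count).  Each entry records its
#' neutral monoisotopic mass and protonated m/z; the library is sorted by
#' m/z and deduplicated per (protein, peptide, modification) triple.
#'
#' @param proteins Tibble as returned by [read_fasta()] (columns
#'   `protein_id`, `sequence`, optionally `taxon`).
#' @param missed_cleavages Maximum missed cleavages (default 1, typical
#'   ZooMS practice).
#' @param min_length,max_length Peptide length bounds (defaults 6 and 40).
#' @param max_hydroxylations Cap on hydroxyprolines per peptide (default 3).
#' @param max_deamidations Cap on deamidations per peptide (default 2).
#' @return Tibble with columns `protein_id`, `taxon`, `sequence`, `n_hyd`,
#'   `n_deam`, `neutral_mass`, `mz`, sorted ascending by `mz`.  Digestion
#'   parameters are attached as the `"params"` attribute.
#' @export
build_mass_library <- function(proteins, missed_cleavages = 1L,
                               min_length = 6L, max_length = 40L,
                               max_hydroxylations = 3L,
                               max_deamidations = 2L) {
  if (min_length > max_length) abort("`min_length` must be <= `max_length`.")
  if (!all(c("protein_id", "sequence") %in% names(proteins))) {
    abort("`proteins` needs columns `protein_id` and `sequence`.")
  }
  if (!"taxon" %in% names(proteins)) proteins$taxon <- NA_character_

  entries <- purrr::pmap(
    proteins[c("protein_id", "taxon", "sequence")],
    function(protein_id, taxon, sequence) {
      peps <- unique(tryptic_digest(sequence, missed_cleavages))
      peps <- peps[nchar(peps) >= min_length & nchar(peps) <= max_length]
      if (!length(peps)) return(NULL)
      purrr::map_dfr(peps, function(p) {
        res <- strsplit(p, "")[[1]]
        hyd <- 0:min(max_hydroxylations, sum(res == "P"))
        deam <- 0:min(max_deamidations, sum(res %in% c("N", "Q")))
        grid <- tidyr::expand_grid(n_hyd = hyd, n_deam = deam)
        grid$neutral_mass <- purrr::map2_dbl(
          grid$n_hyd, grid$n_deam, ~ peptide_mass(p, .x, .y)
        )
        grid$mz <- grid$neutral_mass + MASS_PROTON
        dplyr::mutate(grid,
          protein_id = protein_id, taxon = taxon, sequence = p,
          .before = 1
        )
      })
    }
  )
  lib <- dplyr::bind_rows(entries)
  if (nrow(lib) == 0) {
    lib <- tibble::tibble(
      protein_id = character(), taxon = character(), sequence = character(),
      n_hyd = integer(), n_deam = integer(),
      neutral_mass = double(), mz = double()
    )
  }
  lib <- dplyr::distinct(lib, .data$protein_id, .data$sequence,
                         .data$n_hyd, .data$n_deam, .keep_all = TRUE)
  lib <- dplyr::arrange(lib, .data$mz)
  attr(lib, "params") <- list(
    missed_cleavages = missed_cleavages, min_length = min_length,
    max_length = max_length, max_hydroxylations = max_hydroxylations,
    max_deamidations = max_deamidations
  )
  lib
}

#' Write or read a mass library as TSV
#'
#' Columns: protein_id, taxon, sequence, n_hyd, n_deam, neutral_mass, mz.
#'
#' @param library Tibble from [build_mass_library()].
#' @param path File path.
#' @return `read_mass_library()` returns the library tibble sorted by m/z.
#' @export
write_mass_library <- function(library, path) {
  readr::write_tsv(library, path)
  invisible(path)
}

#' @rdname write_mass_library
#' @export
read_mass_library <- function(path) {
  lib <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      taxon = readr::col_character(),
      sequence = readr::col_character(),
      n_hyd = readr::col_integer(),
      n_deam = readr::col_integer(),
      neutral_mass = readr::col_double(),
      mz = readr::col_double()
    )
  )
  dplyr::arrange(lib, .data$mz)
}
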