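#' Run the full identification and selectivity pipeline
#'
#' Wires the stages together from a single configuration: in silico
#' digestion of the reference proteins, spectrum reading and peak picking,
#' marker-database taxon assignment, library matching with the
#' contamination screen, deamidation estimation, and the rib-selection
#' hypothesis test.  Stages whose inputs are not configured are skipped.
#'
#' @param config A named list or the path to a YAML file with (all
#'   optional unless a stage needs them):
#'   \describe{
#'     \item{spectra}{character vector of spectrum paths (text or mzML)}
#'     \item{fasta}{reference protein FASTA for the mass library}
#'     \item{marker_db}{marker database TSV}
#'     \item{assemblage, layer}{faunal assemblage TSV and layer label}
#'     \item{masses}{body-mass TSV}
#'     \item{obs}{named list of observed rib-blank counts per category}
#'     \item{match}{list: `ppm` (50), `min_peptides` (2), `min_markers`
#'       (2), `exclude` (character)}
#'     \item{selectivity}{list: `c_strong` (1), `c_weak` (2),
#'       `prior_odds` (1)}
#'     \item{seed}{integer seed recorded in the log}
#'     \item{out_dir}{report directory; omit to skip writing}
#'   }
#' @return Invisibly, a list with `status` (0 success, 1 data error,
#'   2 configuration error), `report` (nested list) and `log` (character).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      return(invisible(list(status = 2L,
                            log = sprintf("config file not found: %s", config))))
    }
    config <- yaml::read_yaml(config)
  }
  log <- c(
    sprintf("zoomsel %s", as.character(utils::packageVersion("zoomsel"))),
    sprintf("seed: %s", config$seed %||% "none"),
    sprintf("R %s", R.version.string)
  )
  say <- function(...) log <<- c(log, sprintf(...))

  for (p in c("fasta", "marker_db", "assemblage", "masses")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      say("[config] missing %s: %s", p, config[[p]])
      return(invisible(list(status = 2L, report = NULL, log = log)))
    }
  }
  for (p in config$spectra) {
    if (!file.exists(p)) {
      say("[config] missing spectrum: %s", p)
      return(invisible(list(status = 2L, report = NULL, log = log)))
    }
  }

  match_cfg <- utils::modifyList(
    list(ppm = 50, min_peptides = 2L, min_markers = 2L, exclude = character()),
    config$match %||% list()
  )
  sel_cfg <- utils::modifyList(
    list(c_strong = 1, c_weak = 2, prior_odds = 1),
    config$selectivity %||% list()
  )
  report <- list(parameters = list(match = match_cfg, selectivity = sel_cfg,
                                   seed = config$seed))
  status <- 0L

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("[%s] error: %s", name, conditionMessage(e))
      status <<- 1L
      NULL
    })
  }

  library_tbl <- NULL
  if (!is.null(config$fasta)) {
    library_tbl <- run_stage("digest", {
      lib <- build_mass_library(read_fasta(config$fasta))
      say("[digest] %d library entries from %s", nrow(lib), config$fasta)
      lib
    })
  }
  markers <- if (!is.null(config$marker_db)) {
    run_stage("identify", read_marker_db(config$marker_db))
  }

  if (length(config$spectra)) {
    report$spectra <- purrr::map(config$spectra, function(path) {
      out <- list(path = basename(path))
      sp <- run_stage("spectra", read_spectrum(path))
      if (is.null(sp)) return(out)
      peaks <- select_monoisotopic(pick_peaks(sp))
      say("[spectra] %s: %d monoisotopic peaks", basename(path),
          sum(peaks$monoisotopic))
      if (!is.null(markers)) {
        asg <- assign_taxon(
          peaks, markers, ppm_tol = match_cfg$ppm,
          min_markers = match_cfg$min_markers,
          exclude = match_cfg$exclude,
          merge_rules = default_merge_rules()
        )
        say("[identify] %s: %s (%s)", basename(path), asg$status,
            asg$clade %||% "-")
        out$assignment <- list(
          clade = asg$clade, status = asg$status,
          n_markers = nrow(asg$evidence),
          excluded = asg$excluded$taxon
        )
      }
      if (!is.null(library_tbl) && nrow(library_tbl)) {
        matches <- match_library(peaks, library_tbl,
                                 ppm_tol = match_cfg$ppm,
                                 min_peptides = match_cfg$min_peptides)
        screen <- contamination_screen(matches)
        out$accepted_proteins <- screen
        say("[screen] %s: %d accepted proteins, %d flagged", basename(path),
            nrow(screen), sum(screen$flagged))
      }
      deam <- run_stage("deamidation", fit_deamidation(sp))
      if (!is.null(deam)) {
        out$deamidation <- list(value = deam$value, status = deam$status)
        say("[deamidation] %s: %s", basename(path),
            if (deam$status == "ok") sprintf("%.2f", deam$value) else deam$status)
      }
      out
    })
  }

  if (!is.null(config$assemblage) && length(config$obs)) {
    sel <- run_stage("selectivity", {
      asm <- read_assemblage(config$assemblage, layer = config$layer)
      masses <- readr::read_tsv(config$masses, col_types = readr::cols(
        group = readr::col_character(), mass_kg = readr::col_double(),
        .default = readr::col_character()
      ))
      run_selection_test(
        asm, unlist(config$obs), masses,
        c_strong = sel_cfg$c_strong, c_weak = sel_cfg$c_weak,
        prior_odds = sel_cfg$prior_odds
      )
    })
    if (!is.null(sel)) {
      report$selection_test <- list(
        lik_h0 = sel$lik_h0,
        odds = sel$odds
      )
      say("[selectivity] P(E|H0) = %.3g; odds: %s", sel$lik_h0,
          paste(sprintf("%s %.2f", sel$odds$variant, sel$odds$posterior_odds),
                collapse = ", "))
    }
  }

  if (!is.null(config$out_dir) && status != 2L) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(log, file.path(config$out_dir, "log.txt"))
  }
  invisible(list(status = status, report = report, log = log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
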