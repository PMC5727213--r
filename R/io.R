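#' Write / read a PhenotypeTable as a wide TSV
#'
#' The wide format stores the per-individual compound means (%); technical
#' replicate SDs and counts are not round-tripped (reload with SD 0 and
#' replicate count 1).
#'
#' @param pheno \linkS4class{PhenotypeTable}.
#' @param path TSV path.
#' @return invisibly, the path / the reloaded \linkS4class{PhenotypeTable}.
#' @export
writePhenotypeTable <- function(pheno, path) {
  m <- phenoMeans(pheno)
  df <- data.frame(individual = rownames(m), m, check.names = FALSE)
  write.table(format(df, trim = TRUE, digits = 15), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeTable
#' @export
readPhenotypeTable <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  PhenotypeTable(m)
}

#' Write / read bulk designs as JSON
#'
#' @param designs named list of \linkS4class{BulkDesign} objects.
#' @param path JSON path.
#' @return invisibly the path / a named list of \linkS4class{BulkDesign}.
#' @export
writeBulkDesigns <- function(designs, path) {
  payload <- lapply(designs, function(d)
    list(compound = compounds(d), high = highBulk(d), low = lowBulk(d),
         rule = bulkRule(d)))
  names(payload) <- vapply(designs, compounds, character(1))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeBulkDesigns
#' @export
readBulkDesigns <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(payload, function(p)
    new("BulkDesign", compound = p$compound,
        high = as.character(p$high), low = as.character(p$low),
        rule = as.list(p$rule)))
  names(out) <- vapply(out, compounds, character(1))
  out
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "aromaBSA", mustWork = TRUE)
  path
}

#' Bundled summary tables from the strawberry FDP aroma screen
#'
#' Small plain-text tables transcribed from the published summary output of
#' the 287-feature Fragaria Discovery Panel bulk screen of strawberry aroma
#' compounds (raw hybridisations deposited as GEO series GSE70145). They are
#' inputs for re-analysis: group statistics per DFA-selected feature
#' (\code{fdpGroupStats}), the stepwise-DFA marker sets and their
#' classification rates (\code{fdpDfaModels}, \code{fdpClassificationRates}),
#' the Fisher's-ratio top-10 per compound (\code{fdpFisherTop10}), single
#' SNR snapshots for the FaP1D7 feature (\code{fdpSnapshotSNR}), and the
#' marker-validation panel of genotypes with their FaP1D7 allele and methyl
#' butanoate level (\code{validationPanel}; the six commercial-cultivar
#' levels are evenly spaced synthetic stand-ins within the published
#' 3.9-5.6% range, as only the range is public).
#'
#' @return a data.frame.
#' @name fdpTables
NULL

#' @rdname fdpTables
#' @export
fdpGroupStats <- function() read.delim(.extdata("fdp_group_stats.tsv"))

#' @rdname fdpTables
#' @export
fdpDfaModels <- function() read.delim(.extdata("fdp_dfa_models.tsv"))

#' @rdname fdpTables
#' @export
fdpClassificationRates <- function() read.delim(.extdata("fdp_classification_rates.tsv"))

#' @rdname fdpTables
#' @export
fdpFisherTop10 <- function() read.delim(.extdata("fdp_fisher_top10.tsv"))

#' @rdname fdpTables
#' @export
fdpSnapshotSNR <- function() read.delim(.extdata("fdp_snapshot_snr.tsv"))

#' @rdname fdpTables
#' @export
validationPanel <- function() read.delim(.extdata("validation_panel.tsv"), comment.char = "#")
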