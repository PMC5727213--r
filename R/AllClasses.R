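#' @import methods
#' @importFrom stats pf pt qf quantile sd var median setNames rnorm rgamma rbinom runif
#' @importFrom utils read.delim write.table head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom Biostrings readBStringSet
#' @importFrom jsonlite write_json read_json
#' @importFrom car leveneTest
NULL

#' PhenotypeTable: replicate-aggregated compound phenotypes
#'
#' Holds per-individual mean relative compositions (%) of volatile compounds,
#' together with the standard deviation over technical replicates and the
#' replicate count behind every cell. Rows are individuals (F1 progeny or
#' parental genotypes), columns are compounds.
#'
#' @slot means numeric matrix (individuals x compounds), values in [0, 100].
#' @slot sds numeric matrix of per-cell SDs over technical replicates
#'   (sample SD, n - 1 denominator; 0 when only one replicate was available).
#' @slot nreps integer matrix of replicate counts per cell (>= 1). Cells with
#'   \code{nreps == 1} carry an SD of 0 that should be read as "insufficient
#'   replicates", not as zero variability.
#'
#' @export
setClass("PhenotypeTable",
  representation(means = "matrix", sds = "matrix", nreps = "matrix"),
  validity = function(object) {
    m <- object@means; s <- object@sds; n <- object@nreps
    if (!all(dim(m) == dim(s)) || !all(dim(m) == dim(n)))
      return("means, sds and nreps must share dimensions")
    if (is.null(rownames(m)) || is.null(colnames(m)))
      return("means must have individual (row) and compound (column) names")
    if (any(!is.finite(m)) || any(m < 0 - 1e-12) || any(m > 100 + 1e-12))
      return("mean relative compositions must lie in [0, 100]")
    if (any(s < 0)) return("SDs must be non-negative")
    if (any(n < 1)) return("replicate counts must be >= 1")
    TRUE
  }
)

#' Construct a PhenotypeTable
#'
#' @param means individuals x compounds matrix of mean relative compositions (%).
#' @param sds matching matrix of technical-replicate SDs; defaults to all zero.
#' @param nreps matching matrix (or scalar) of replicate counts; defaults to 1.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
PhenotypeTable <- function(means, sds = NULL, nreps = 1L) {
  means <- as.matrix(means)
  if (is.null(sds)) sds <- array(0, dim(means), dimnames(means))
  if (length(nreps) == 1L) nreps <- array(as.integer(nreps), dim(means), dimnames(means))
  new("PhenotypeTable", means = means, sds = as.matrix(sds),
      nreps = matrix(as.integer(nreps), nrow(means), ncol(means), dimnames = dimnames(means)))
}

#' BulkDesign: extreme-phenotype bulk membership for one compound
#'
#' Records which F1 individuals were pooled into the high ('H') and the
#' low/undetectable ('L') DNA bulk for a single target compound, plus the
#' selection rule that produced the split.
#'
#' @slot compound single compound id.
#' @slot high ids of the 'H' bulk members.
#' @slot low ids of the 'L' bulk members.
#' @slot rule named list describing the cut rule (method and its parameters).
#'
#' @export
setClass("BulkDesign",
  representation(compound = "character", high = "character",
                 low = "character", rule = "list"),
  validity = function(object) {
    if (length(object@compound) != 1L) return("exactly one compound id")
    if (length(intersect(object@high, object@low)) > 0L)
      return("H and L bulks must be disjoint")
    if (anyDuplicated(object@high) || anyDuplicated(object@low))
      return("duplicate individuals within a bulk")
    TRUE
  }
)

#' SignalMatrix: feature x sample array signal-to-noise matrix
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"snr"} holding
#' non-negative signal-to-noise ratios, and colData columns \code{bulk}
#' ("H"/"L"), \code{bioRep} and \code{techRep}. The canonical bulk screening
#' design has 2 bulks x 2 biological x 6 technical replicates, i.e. 12 data
#' points per feature per bulk; incomplete designs load with
#' \code{metadata(x)$complete = FALSE}.
#'
#' @export
setClass("SignalMatrix", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"snr" %in% SummarizedExperiment::assayNames(object))
      return("assay 'snr' is required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("bulk", "bioRep", "techRep")
    if (!all(need %in% colnames(cd)))
      return(paste("colData must contain", paste(need, collapse = ", ")))
    if (!all(cd$bulk %in% c("H", "L"))) return("bulk labels must be 'H' or 'L'")
    snr <- SummarizedExperiment::assay(object, "snr")
    if (any(!is.finite(snr)) || any(snr < 0))
      return("SNR values must be finite and non-negative")
    TRUE
  }
)

#' Construct a SignalMatrix
#'
#' @param snr numeric matrix, features in rows, samples in columns.
#' @param bulk character vector of bulk labels ("H"/"L"), one per sample.
#' @param bioRep,techRep integer replicate indices, one per sample.
#' @return A \linkS4class{SignalMatrix}. \code{metadata(x)$complete} records
#'   whether every (bulk, bioRep) cell carries the same number of technical
#'   replicates and both bulks are present.
#' @export
SignalMatrix <- function(snr, bulk, bioRep, techRep) {
  snr <- as.matrix(snr)
  if (is.null(rownames(snr))) stop("features (rownames) are required")
  if (is.null(colnames(snr)))
    colnames(snr) <- paste(bulk, bioRep, techRep, sep = "_")
  cd <- S4Vectors::DataFrame(bulk = as.character(bulk),
                             bioRep = as.integer(bioRep),
                             techRep = as.integer(techRep),
                             row.names = colnames(snr))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(snr = snr), colData = cd)
  tab <- table(cd$bulk, cd$bioRep)
  complete <- length(unique(cd$bulk)) == 2L && length(unique(as.vector(tab))) == 1L
  se <- as(se, "SignalMatrix")
  S4Vectors::metadata(se)$complete <- complete
  validObject(se)
  se
}

#' DfaModel: a fitted stepwise discriminant function analysis
#'
#' Stores the stepwise-selected features in entry order, the Wilks' lambda
#' trace after each accepted step, Fisher classification function
#' coefficients/constants per group, and the moments needed to re-derive them.
#' An empty model (no variable passed the entry test) is a valid object with
#' \code{noDiscriminators = TRUE}.
#'
#' @slot features selected feature ids, in order of entry.
#' @slot lambdaTrace Wilks' lambda after each accepted entry/removal step.
#' @slot coefficients p x g matrix of Fisher classification coefficients.
#' @slot constants length-g classification constants.
#' @slot groupMeans p x g matrix of group means on the selected features.
#' @slot pooledCov pooled within-group covariance (W / (n - g)).
#' @slot groups group labels, in the order used for columns.
#' @slot counts per-group sample counts.
#' @slot priors per-group prior probabilities.
#' @slot n total samples used for the fit.
#' @slot noDiscriminators TRUE when no feature met the entry criterion.
#'
#' @export
setClass("DfaModel",
  representation(features = "character", lambdaTrace = "numeric",
                 coefficients = "matrix", constants = "numeric",
                 groupMeans = "matrix", pooledCov = "matrix",
                 groups = "character", counts = "integer",
                 priors = "numeric", n = "integer",
                 noDiscriminators = "logical"),
  validity = function(object) {
    if (length(object@noDiscriminators) != 1L) return("noDiscriminators must be scalar")
    if (!object@noDiscriminators) {
      if (length(object@features) == 0L) return("non-empty model needs features")
      if (any(object@lambdaTrace <= 0) || any(object@lambdaTrace > 1 + 1e-12))
        return("Wilks' lambda must lie in (0, 1]")
    }
    if (abs(sum(object@priors) - 1) > 1e-8 && length(object@priors))
      return("priors must sum to 1")
    TRUE
  }
)

#' ClassificationReport: training, cross-validated and holdout accuracy
#'
#' @slot originalPct percent of the fitting samples correctly re-classified.
#' @slot cvPct leave-one-out cross-validated percent correct (classification
#'   functions refit per fold, feature set frozen).
#' @slot holdoutPct percent correct on a held-out sample set (NA when no
#'   holdout was supplied).
#' @slot confusion confusion counts (true x predicted) on the fitting samples.
#' @slot n number of fitting samples.
#' @export
setClass("ClassificationReport",
  representation(originalPct = "numeric", cvPct = "numeric",
                 holdoutPct = "numeric", confusion = "table", n = "integer"),
  validity = function(object) {
    ok <- function(p) is.na(p) || (p >= 0 && p <= 100)
    if (!ok(object@originalPct) || !ok(object@cvPct) || !ok(object@holdoutPct))
      return("percentages must lie in [0, 100]")
    TRUE
  }
)

#' MarkerSelection: three-criterion marker intersection for one compound
#'
#' @slot compound compound id ("(pooled)" for cross-compound unions).
#' @slot dfaSet features selected by stepwise DFA.
#' @slot fisherSet features in the Fisher's-ratio top-K.
#' @slot ttestSet features significant in the bulk-contrast t-test.
#' @slot intersection features satisfying all three criteria.
#' @slot regions named counts of the 7 Venn regions.
#' @export
setClass("MarkerSelection",
  representation(compound = "character", dfaSet = "character",
                 fisherSet = "character", ttestSet = "character",
                 intersection = "character", regions = "numeric"),
  validity = function(object) {
    i <- object@intersection
    if (!all(i %in% object@dfaSet) || !all(i %in% object@fisherSet) ||
        !all(i %in% object@ttestSet))
      return("intersection must be contained in every constituent set")
    u <- union(union(object@dfaSet, object@fisherSet), object@ttestSet)
    if (length(object@regions) != 7L) return("7 Venn regions expected")
    if (sum(object@regions) != length(u))
      return("Venn region counts must sum to the union size")
    TRUE
  }
)

setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf("PhenotypeTable: %d individuals x %d compounds\n",
              nrow(object@means), ncol(object@means)))
  cat("  compounds:", paste(utils::head(colnames(object@means), 6), collapse = ", "),
      if (ncol(object@means) > 6) "..." else "", "\n")
})

setMethod("show", "BulkDesign", function(object) {
  cat(sprintf("BulkDesign for '%s': |H| = %d, |L| = %d (%s)\n",
              object@compound, length(object@high), length(object@low),
              if (length(object@rule)) object@rule$method else "unspecified rule"))
})

setMethod("show", "DfaModel", function(object) {
  if (object@noDiscriminators) {
    cat("DfaModel: no discriminators (no feature met the entry criterion)\n")
  } else {
    cat(sprintf("DfaModel: %d feature(s) [%s], Wilks' lambda = %.4f, n = %d\n",
                length(object@features), paste(object@features, collapse = ", "),
                utils::tail(object@lambdaTrace, 1), object@n))
  }
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport: original %.1f%%, cross-validated %.1f%%, holdout %s (n = %d)\n",
              object@originalPct, object@cvPct,
              if (is.na(object@holdoutPct)) "NA" else sprintf("%.1f%%", object@holdoutPct),
              object@n))
})

setMethod("show", "MarkerSelection", function(object) {
  cat(sprintf("MarkerSelection [%s]: DFA %d, Fisher top-K %d, t-test %d -> intersection %d (%s)\n",
              object@compound, length(object@dfaSet), length(object@fisherSet),
              length(object@ttestSet), length(object@intersection),
              if (length(object@intersection)) paste(object@intersection, collapse = ", ") else "none"))
})
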