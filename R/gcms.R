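#' Relative composition of compounds by area normalisation
#'
#' Converts the peak areas of one chromatogram into relative compositions,
#' C_i = A_i / A_t x 100, where A_t is the total peak area. The usual area
#' normalisation assumptions apply: equal detector response across compounds
#' and complete detection of the injected sample.
#'
#' @param areas named numeric vector of peak areas (detector counts, >= 0)
#'   for one (sample, replicate) chromatogram; names are compound ids.
#' @param allCompounds optional superset of compound ids; compounds absent
#'   from \code{areas} are reported as 0%.
#' @return named numeric vector of relative compositions in percent, summing
#'   to 100 over the detected compounds.
#' @examples
#' relativeComposition(c(hexanal = 10, linalool = 30, mesifuranne = 60))
#' @export
relativeComposition <- function(areas, allCompounds = NULL) {
  if (length(areas) == 0L) stop("no peaks supplied")
  if (is.null(names(areas)) || anyDuplicated(names(areas)))
    stop("areas must carry unique compound names")
  if (any(areas < 0) || any(!is.finite(areas))) stop("peak areas must be finite and >= 0")
  total <- sum(areas)
  if (total <= 0) stop("degenerate input: total peak area is zero")
  comp <- areas / total * 100
  if (!is.null(allCompounds)) {
    out <- setNames(numeric(length(allCompounds)), allCompounds)
    out[names(comp)] <- comp
    comp <- out
  }
  comp
}

#' Filter peaks by library-match quality and technical-replicate support
#'
#' Retains a compound for a sample only when it was detected, with a library
#' match quality strictly greater than \code{minQuality}, in at least
#' \code{minReplicates} technical replicates of that sample. Rows failing the
#' quality cut never count as detections and are dropped.
#'
#' @param peaks data.frame with columns \code{sample_id}, \code{replicate},
#'   \code{compound}, \code{area}, \code{quality}.
#' @param minQuality strict lower bound on match quality (default 80).
#' @param minReplicates minimum number of qualifying technical replicates
#'   (default 2).
#' @return the filtered peak table (same columns, qualifying rows only).
#' @export
qualityReplicateFilter <- function(peaks, minQuality = 80, minReplicates = 2) {
  need <- c("sample_id", "replicate", "compound", "area", "quality")
  if (!all(need %in% names(peaks)))
    stop("peak table must have columns ", paste(need, collapse = ", "))
  nrepAvail <- tapply(peaks$replicate, peaks$sample_id,
                      function(r) length(unique(r)))
  if (minReplicates > max(nrepAvail))
    stop("configuration error: minReplicates exceeds the number of replicates provided")
  ok <- peaks$quality > minQuality
  kept <- peaks[ok, , drop = FALSE]
  if (nrow(kept) == 0L) return(kept)
  key <- interaction(kept$sample_id, kept$compound, drop = TRUE)
  support <- tapply(kept$replicate, key, function(r) length(unique(r)))
  kept[support[key] >= minReplicates, , drop = FALSE]
}

#' Aggregate technical replicates into phenotype means and SDs
#'
#' Computes, per individual and compound, the mean relative composition and
#' the sample standard deviation (n - 1 denominator) over technical
#' replicates. With a single replicate the SD is reported as 0 and the
#' replicate count of 1 flags the cell as having insufficient replicates.
#'
#' @param compositions data.frame with columns \code{sample_id},
#'   \code{replicate}, \code{compound}, \code{composition} (percent); one row
#'   per detected compound per replicate. Compounds undetected in a replicate
#'   are treated as 0% in that replicate.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
aggregateReplicates <- function(compositions) {
  need <- c("sample_id", "replicate", "compound", "composition")
  if (!all(need %in% names(compositions)))
    stop("composition table must have columns ", paste(need, collapse = ", "))
  inds <- sort(unique(compositions$sample_id))
  cmps <- sort(unique(compositions$compound))
  means <- sds <- array(0, c(length(inds), length(cmps)), list(inds, cmps))
  nreps <- array(1L, c(length(inds), length(cmps)), list(inds, cmps))
  for (ind in inds) {
    sub <- compositions[compositions$sample_id == ind, , drop = FALSE]
    reps <- sort(unique(sub$replicate))
    # absent compounds count as 0% within each replicate of this individual
    mat <- array(0, c(length(reps), length(cmps)), list(reps, cmps))
    mat[cbind(match(sub$replicate, reps), match(sub$compound, cmps))] <- sub$composition
    means[ind, ] <- colMeans(mat)
    sds[ind, ] <- if (length(reps) > 1L) apply(mat, 2, sd) else 0
    nreps[ind, ] <- length(reps)
  }
  PhenotypeTable(means, sds, nreps)
}

#' Build a PhenotypeTable from raw peak tables
#'
#' Convenience pipeline: quality/replicate filtering, per-replicate area
#' normalisation, then replicate aggregation.
#'
#' @inheritParams qualityReplicateFilter
#' @return A \linkS4class{PhenotypeTable}.
#' @export
profilePhenotypes <- function(peaks, minQuality = 80, minReplicates = 2) {
  kept <- qualityReplicateFilter(peaks, minQuality, minReplicates)
  if (nrow(kept) == 0L) stop("no peaks survive the quality/replicate filter")
  pieces <- split(kept, interaction(kept$sample_id, kept$replicate, drop = TRUE))
  comp <- do.call(rbind, lapply(pieces, function(p) {
    data.frame(sample_id = p$sample_id[1], replicate = p$replicate[1],
               compound = p$compound,
               composition = as.numeric(relativeComposition(setNames(p$area, p$compound))),
               row.names = NULL)
  }))
  aggregateReplicates(comp)
}

#' Descriptive and parental-contrast summary for one compound
#'
#' Summarises a compound over the F1 population (mean, min, max of the
#' per-individual means) and contrasts the two parents with a two-sample
#' t-test computed from their replicate summary statistics. The transgressive
#' flag is TRUE when any F1 individual falls outside the interval spanned by
#' the two parental means: above the larger mean, or (for individuals in which
#' the compound was actually detected) below the smaller mean. Exact zeros are
#' treated as "undetected" rather than as evidence of sub-parental production,
#' so a population of producers and non-producers is not low-transgressive
#' merely because some individuals lack the compound.
#'
#' @param pheno \linkS4class{PhenotypeTable} of the F1 population.
#' @param parents \linkS4class{PhenotypeTable} with exactly two individuals
#'   (the parents); SDs and replicate counts feed the t-test.
#' @param compound compound id.
#' @param variant \code{"welch"} (default) or \code{"pooled"} t-test form.
#' @return data.frame with one row: F1 mean/min/max, parental means/SDs,
#'   t, df, p, significance class (\code{ns}, \code{*}, \code{**}, or
#'   \code{undefined} when no test is computable), and \code{transgressive}.
#' @export
summarizeCompound <- function(pheno, parents, compound, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (!compound %in% compounds(pheno)) stop("compound not in PhenotypeTable: ", compound)
  if (!compound %in% compounds(parents) || nrow(phenoMeans(parents)) != 2L)
    stop("parents must be a 2-individual PhenotypeTable containing the compound")
  v <- phenoMeans(pheno)[, compound]
  pm <- phenoMeans(parents)[, compound]
  ps <- phenoSDs(parents)[, compound]
  pn <- repCounts(parents)[, compound]
  tt <- tryCatch(
    twoSampleT(pm[1], ps[1], pn[1], pm[2], ps[2], pn[2], variant = variant),
    error = function(e) NULL)
  sig <- if (is.null(tt)) "undefined" else significanceClass(tt$p)
  data.frame(
    compound = compound,
    f1_mean = mean(v), f1_min = min(v), f1_max = max(v),
    parent1_mean = unname(pm[1]), parent1_sd = unname(ps[1]),
    parent2_mean = unname(pm[2]), parent2_sd = unname(ps[2]),
    t = if (is.null(tt)) NA_real_ else tt$t,
    df = if (is.null(tt)) NA_real_ else tt$df,
    p = if (is.null(tt)) NA_real_ else tt$p,
    signif = sig,
    transgressive = max(v) > max(pm) ||
      (any(v > 0) && min(v[v > 0]) < min(pm)),
    row.names = NULL)
}

significanceClass <- function(p) {
  if (is.na(p)) "undefined"
  else if (p > 0.05) "ns"
  else if (p > 0.01) "*"
  else "**"
}

#' Select target compounds for marker development
#'
#' Excludes compounds whose F1 population mean falls below a floor (they are
#' detected too infrequently and are strongly environment-driven) or whose
#' parental contrast is not significant at \code{alpha} (little chance of
#' segregating alleles). Compounds whose parental test is undefined because
#' neither parent produced the compound are excluded under the default policy.
#'
#' @param summaries data.frame of rows from \code{\link{summarizeCompound}}.
#' @param meanFloorPct minimum F1 population mean in percent (default 0.1).
#' @param alpha parental-contrast significance level (default 0.05).
#' @param requireParentalSignif set FALSE to keep compounds with undefined or
#'   non-significant parental contrasts.
#' @return compound ids, sorted by F1 mean, descending.
#' @export
selectTargetCompounds <- function(summaries, meanFloorPct = 0.1, alpha = 0.05,
                                  requireParentalSignif = TRUE) {
  if (is.null(summaries) || nrow(summaries) == 0L) return(character(0))
  keep <- summaries$f1_mean >= meanFloorPct
  if (requireParentalSignif)
    keep <- keep & !is.na(summaries$p) & summaries$p < alpha
  sel <- summaries[keep, , drop = FALSE]
  sel$compound[order(-sel$f1_mean)]
}

#' Frequency histogram with half-open bins
#'
#' Bins percentage values into half-open intervals [lo, hi) anchored at 0, as
#' used for segregation-pattern inspection of compound distributions. A value
#' landing exactly on the top edge gets its own final bin so that counts
#' always sum to the number of values.
#'
#' @param values numeric vector in [0, 100].
#' @param binWidth positive bin width in percent.
#' @return list with \code{breaks} (length nbins + 1) and \code{counts}.
#' @export
frequencyHistogram <- function(values, binWidth) {
  if (binWidth <= 0) stop("binWidth must be positive")
  if (any(values < 0 | values > 100)) stop("values must lie in [0, 100]")
  nbins <- max(1L, floor(max(values) / binWidth) + 1L)
  breaks <- seq(0, by = binWidth, length.out = nbins + 1L)
  idx <- pmin(floor(values / binWidth) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  list(breaks = breaks, counts = counts)
}
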