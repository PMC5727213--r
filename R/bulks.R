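#' Assign extreme-phenotype individuals to H and L bulks
#'
#' Splits the F1 individuals for one compound into a high ('H') and a
#' low/undetectable ('L') bulk. Under the default symmetric quantile rule the
#' L cut is the q-quantile and the H cut the (1 - q)-quantile of the
#' per-individual means; individuals at or below the L cut (always including
#' exact zeros) form L, individuals at or above the H cut form H, and the
#' middle of the distribution is excluded from pooling. Ties at a cut are
#' all included, so bulks can exceed the nominal quantile count.
#'
#' @param pheno \linkS4class{PhenotypeTable}.
#' @param compound compound id to bulk on.
#' @param q symmetric quantile for the default rule (default 0.2).
#' @param thresholds optional numeric \code{c(lo, hi)} absolute cut values in
#'   percent; overrides the quantile rule.
#' @param minBulkSize minimum members per bulk (default 3).
#' @return A \linkS4class{BulkDesign}.
#' @export
assignExtremes <- function(pheno, compound, q = 0.2, thresholds = NULL,
                           minBulkSize = 3L) {
  if (!compound %in% compounds(pheno)) stop("compound not in PhenotypeTable: ", compound)
  v <- phenoMeans(pheno)[, compound]
  if (length(v) < 2L * minBulkSize)
    stop("bulk-size error for '", compound, "': fewer than ", 2L * minBulkSize,
         " phenotyped individuals")
  if (is.null(thresholds)) {
    lo <- unname(quantile(v, q, type = 7))
    hi <- unname(quantile(v, 1 - q, type = 7))
    rule <- list(method = "quantile", q = q, lo = lo, hi = hi)
  } else {
    lo <- thresholds[1]; hi <- thresholds[2]
    rule <- list(method = "absolute", lo = lo, hi = hi)
  }
  if (!(lo < hi))
    stop("bulk-size error for '", compound,
         "': no phenotypic extremes (low and high cuts coincide)")
  low <- names(v)[v <= lo | v == 0]
  high <- names(v)[v >= hi]
  if (length(intersect(low, high)) > 0L)
    stop("bulk-size error for '", compound, "': cut values admit overlapping bulks")
  if (length(low) < minBulkSize || length(high) < minBulkSize)
    stop("bulk-size error for '", compound, "': |H| = ", length(high),
         ", |L| = ", length(low), " below the minimum of ", minBulkSize)
  new("BulkDesign", compound = compound, high = sort(high), low = sort(low),
      rule = rule)
}

#' Summarise a list of bulk designs
#'
#' One row per design with bulk sizes and memberships. In strict mode,
#' designs whose bulk sizes fall outside the 3-27 plant range typical of
#' extreme-bulk BSA on a 50-individual F1 population are flagged.
#'
#' @param designs list of \linkS4class{BulkDesign} objects.
#' @param strict flag sizes outside [3, 27] (default FALSE).
#' @return data.frame with columns compound, n_high, n_low, high, low and,
#'   in strict mode, \code{violation}.
#' @export
bulkReport <- function(designs, strict = FALSE) {
  if (length(designs) == 0L) {
    out <- data.frame(compound = character(0), n_high = integer(0),
                      n_low = integer(0), high = character(0), low = character(0))
    if (strict) out$violation <- logical(0)
    return(out)
  }
  out <- do.call(rbind, lapply(designs, function(d) {
    data.frame(compound = compounds(d),
               n_high = length(highBulk(d)), n_low = length(lowBulk(d)),
               high = paste(highBulk(d), collapse = ","),
               low = paste(lowBulk(d), collapse = ","),
               row.names = NULL)
  }))
  if (strict)
    out$violation <- out$n_high < 3 | out$n_high > 27 | out$n_low < 3 | out$n_low > 27
  out
}
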