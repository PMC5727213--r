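#' Read a long-format SNR table into a SignalMatrix
#'
#' Expects a TSV with header columns \code{feature}, \code{bulk},
#' \code{bio_rep}, \code{tech_rep}, \code{snr}. Each (feature, bulk, bio_rep,
#' tech_rep) cell may appear at most once. A design that is not the complete
#' 2 bulks x equal-replicate layout loads fine but is flagged via
#' \code{metadata(x)$complete}.
#'
#' @param path TSV path.
#' @return A \linkS4class{SignalMatrix}.
#' @export
readSignalMatrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature", "bulk", "bio_rep", "tech_rep", "snr")
  if (!all(need %in% names(tab)))
    stop("signal table must have columns ", paste(need, collapse = ", "))
  if (!is.numeric(tab$snr)) stop("non-numeric SNR values in ", path)
  sampleKey <- paste(tab$bulk, tab$bio_rep, tab$tech_rep, sep = "_")
  dup <- duplicated(paste(tab$feature, sampleKey))
  if (any(dup)) {
    d <- which(dup)[1]
    stop("duplicate cell for feature '", tab$feature[d], "', sample '",
         sampleKey[d], "'")
  }
  features <- unique(tab$feature)
  samples <- unique(data.frame(key = sampleKey, bulk = tab$bulk,
                               bioRep = tab$bio_rep, techRep = tab$tech_rep,
                               stringsAsFactors = FALSE))
  samples <- samples[order(samples$bulk, samples$bioRep, samples$techRep), ]
  m <- matrix(NA_real_, length(features), nrow(samples),
              dimnames = list(features, samples$key))
  m[cbind(match(tab$feature, features), match(sampleKey, samples$key))] <- tab$snr
  if (anyNA(m)) stop("incomplete table: some (feature, sample) cells are missing")
  SignalMatrix(m, samples$bulk, samples$bioRep, samples$techRep)
}

#' Write a SignalMatrix as a long-format TSV
#'
#' Inverse of \code{\link{readSignalMatrix}}; a write-read-write cycle is
#' byte-identical.
#'
#' @param x \linkS4class{SignalMatrix}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeSignalMatrix <- function(x, path) {
  m <- snr(x)
  tab <- data.frame(
    feature = rep(rownames(m), times = ncol(m)),
    bulk = rep(bulkLabels(x), each = nrow(m)),
    bio_rep = rep(bioRep(x), each = nrow(m)),
    tech_rep = rep(techRep(x), each = nrow(m)),
    snr = as.vector(m))
  write.table(format(tab, trim = TRUE, digits = 15), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalise a SignalMatrix
#'
#' \code{"none"} is the identity and the default: bulk-hybridisation SNR
#' pipelines usually arrive already normalised, so printed summary statistics
#' can be consumed directly. \code{"median"} divides each sample by its own
#' median and multiplies by the global median, equalising sample medians.
#'
#' @param x \linkS4class{SignalMatrix}.
#' @param method \code{"none"} or \code{"median"}.
#' @return A \linkS4class{SignalMatrix}.
#' @export
normalizeSignals <- function(x, method = c("none", "median")) {
  method <- match.arg(method)
  if (method == "none") return(x)
  m <- snr(x)
  med <- apply(m, 2, median)
  if (any(med == 0)) stop("cannot median-scale: sample(s) with zero median: ",
                          paste(colnames(m)[med == 0], collapse = ", "))
  scaled <- sweep(m, 2, med, "/") * median(m)
  SignalMatrix(scaled, bulkLabels(x), bioRep(x), techRep(x))
}

#' Per-feature group statistics for the two bulks
#'
#' Pools both biological replicates into one group per bulk (the canonical 12
#' data points) and reports, per feature, mean, sample SD, sample variance
#' (n - 1 denominator) and n for the 'H' and 'L' bulks.
#'
#' @param x \linkS4class{SignalMatrix}.
#' @return data.frame with columns feature, mean_H, sd_H, var_H, n_H,
#'   mean_L, sd_L, var_L, n_L.
#' @export
groupStatistics <- function(x) {
  m <- snr(x)
  b <- bulkLabels(x)
  if (sum(b == "H") < 2L || sum(b == "L") < 2L)
    stop("each bulk needs at least 2 data points")
  h <- m[, b == "H", drop = FALSE]
  l <- m[, b == "L", drop = FALSE]
  data.frame(
    feature = rownames(m),
    mean_H = rowMeans(h), sd_H = apply(h, 1, sd), var_H = apply(h, 1, var),
    n_H = ncol(h),
    mean_L = rowMeans(l), sd_L = apply(l, 1, sd), var_L = apply(l, 1, var),
    n_L = ncol(l),
    row.names = NULL)
}
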