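#' Physical distance spanned by a genetic distance
#'
#' Converts centiMorgans to base pairs under the flat assumption that a
#' normal chromosome spans 100 cM: window_bp = (lg_length_bp / 100) * cm.
#' Linear in both arguments.
#'
#' @param lgLengthBp physical length of the linkage group in bp (> 0).
#' @param cm genetic distance in centiMorgan (>= 0), default 5.
#' @return window size in bp.
#' @examples
#' physicalWindow(1e8, 5) # 5 Mb
#' @export
physicalWindow <- function(lgLengthBp, cm = 5) {
  if (any(lgLengthBp <= 0)) stop("linkage group length must be positive")
  if (any(cm < 0)) stop("cM must be non-negative")
  (lgLengthBp / 100) * cm
}

#' Genes within a physical window of an anchored marker
#'
#' Reports every gene on the anchor's linkage group whose nearest edge lies
#' within \code{windowBp} of the anchor interval, together with a signed
#' offset: 0 for overlap, positive for genes downstream (higher coordinates)
#' and negative for genes upstream. Genes on other linkage groups are
#' silently filtered. Coordinates are 1-based inclusive.
#'
#' @param anchor a length-1 \link[GenomicRanges]{GRanges} (seqname = linkage
#'   group).
#' @param genes a \link[GenomicRanges]{GRanges} of gene records, with a
#'   \code{gene_id} metadata column.
#' @param windowBp window size in bp on either side of the anchor.
#' @return data.frame with columns gene_id, lg, start, end, offset_bp, sorted
#'   by absolute offset.
#' @export
genesWithinWindow <- function(anchor, genes, windowBp) {
  if (length(anchor) != 1L) stop("exactly one anchor expected")
  same <- as.character(GenomicRanges::seqnames(genes)) ==
    as.character(GenomicRanges::seqnames(anchor))
  genes <- genes[same]
  if (length(genes) == 0L) {
    return(data.frame(gene_id = character(0), lg = character(0),
                      start = integer(0), end = integer(0),
                      offset_bp = numeric(0)))
  }
  aStart <- GenomicRanges::start(anchor)
  aEnd <- GenomicRanges::end(anchor)
  gStart <- GenomicRanges::start(genes)
  gEnd <- GenomicRanges::end(genes)
  offset <- numeric(length(genes))
  offset[gStart > aEnd] <- (gStart - aEnd)[gStart > aEnd]
  offset[gEnd < aStart] <- (gEnd - aStart)[gEnd < aStart]
  keep <- abs(offset) <= windowBp
  out <- data.frame(
    gene_id = as.character(S4Vectors::mcols(genes)$gene_id[keep]),
    lg = as.character(GenomicRanges::seqnames(genes))[keep],
    start = gStart[keep], end = gEnd[keep], offset_bp = offset[keep])
  out[order(abs(out$offset_bp)), , drop = FALSE]
}

#' Load a BLAST-style tabular hit file into genomic anchors
#'
#' Reads a 12-column outfmt-6 dialect table (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore), keeps
#' the best hit per query (smallest E-value, ties by largest bitscore), and
#' splits queries into placed anchors (E-value strictly below the cutoff) and
#' unplaced queries. Reversed subject coordinates are normalised to
#' start <= end with strand "-".
#'
#' @param path hit table path (no header).
#' @param eCutoff significance cutoff, strict less-than (default 1e-5).
#' @return list with \code{anchors} (data.frame: query, subject, start, end,
#'   strand, evalue, bitscore) and \code{unplaced} (query ids whose best hit
#'   missed the cutoff).
#' @export
loadHitTable <- function(path, eCutoff = 1e-5) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0)
    return(list(anchors = data.frame(query = character(0), subject = character(0),
                                     start = integer(0), end = integer(0),
                                     strand = character(0), evalue = numeric(0),
                                     bitscore = numeric(0)),
                unplaced = character(0)))
  tab <- read.delim(path, header = FALSE, col.names = cols,
                    stringsAsFactors = FALSE)
  if (!is.numeric(tab$evalue) || !is.numeric(tab$bitscore))
    stop("malformed hit table: non-numeric evalue/bitscore in ", path)
  best <- do.call(rbind, lapply(split(tab, tab$qseqid), function(h) {
    h <- h[order(h$evalue, -h$bitscore), , drop = FALSE]
    h[1, , drop = FALSE]
  }))
  placed <- best$evalue < eCutoff
  anchors <- data.frame(
    query = best$qseqid[placed], subject = best$sseqid[placed],
    start = pmin(best$sstart, best$send)[placed],
    end = pmax(best$sstart, best$send)[placed],
    strand = ifelse(best$sstart <= best$send, "+", "-")[placed],
    evalue = best$evalue[placed], bitscore = best$bitscore[placed],
    row.names = NULL)
  list(anchors = anchors[order(anchors$query), , drop = FALSE],
       unplaced = sort(best$qseqid[!placed]))
}

#' Anchors as GRanges
#'
#' @param anchors the \code{anchors} data.frame of \code{\link{loadHitTable}}.
#' @return A \link[GenomicRanges]{GRanges} keyed by query id.
#' @export
anchorsAsGRanges <- function(anchors) {
  GenomicRanges::GRanges(
    seqnames = anchors$subject,
    ranges = IRanges::IRanges(start = anchors$start, end = anchors$end),
    strand = anchors$strand, query = anchors$query,
    evalue = anchors$evalue)
}

#' Call SNPs and indels between two aligned sequences
#'
#' Column-wise comparison of two equal-length aligned sequences over
#' {A, C, G, T, N, -}. A column with differing non-N characters yields one
#' call; N masks a column entirely. Positions are 1-based alignment columns.
#'
#' @param seqA,seqB aligned sequence strings (or length-1
#'   \link[Biostrings]{BStringSet}).
#' @return data.frame with columns position, alleleA, alleleB, type
#'   ("substitution" or "indel").
#' @export
callSnps <- function(seqA, seqB) {
  toChars <- function(s) {
    if (is(s, "XStringSet")) s <- as.character(s[[1]])
    if (is(s, "XString")) s <- as.character(s)
    strsplit(toupper(s), "")[[1]]
  }
  a <- toChars(seqA)
  b <- toChars(seqB)
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  ok <- c("A", "C", "G", "T", "N", "-")
  if (!all(a %in% ok) || !all(b %in% ok))
    stop("sequences must be over {A, C, G, T, N, -}")
  diffs <- which(a != b & a != "N" & b != "N")
  data.frame(position = diffs, alleleA = a[diffs], alleleB = b[diffs],
             type = ifelse(a[diffs] == "-" | b[diffs] == "-",
                           "indel", "substitution"),
             row.names = NULL)
}

#' Read an aligned FASTA pair and call SNPs
#'
#' @param path FASTA file with exactly two aligned records.
#' @return as \code{\link{callSnps}}.
#' @export
callSnpsFasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 2L) stop("expected exactly two aligned sequences")
  callSnps(as.character(seqs[[1]]), as.character(seqs[[2]]))
}

#' Genotype-phenotype concordance for a biallelic marker
#'
#' Given per-genotype marker alleles and phenotype levels (%), a genotype is
#' expected to be a high producer iff it carries \code{highAllele}; it is
#' concordant when (level >= threshold) matches that expectation. The default
#' 10% threshold sits between typical low-producer levels (< 6%) and
#' validated high producers (> 24%); any threshold strictly inside that gap
#' gives the same answer.
#'
#' @param genotypes named character vector: genotype id -> allele.
#' @param levels named numeric vector: genotype id -> phenotype level (%).
#' @param threshold high/low phenotype cut in percent (default 10).
#' @param highAllele allele expected in high producers (default "T").
#' @param lowAllele allele expected in low producers (default "C").
#' @return list with \code{concordance} (fraction in [0, 1]),
#'   \code{discordant} (genotype ids), and \code{n} (genotypes scored).
#' @export
genotypeConcordance <- function(genotypes, levels, threshold = 10,
                                highAllele = "T", lowAllele = "C") {
  shared <- intersect(names(genotypes), names(levels))
  if (length(shared) == 0L) stop("no shared genotype ids between inputs")
  alleles <- genotypes[shared]
  bad <- setdiff(unique(alleles), c(highAllele, lowAllele))
  if (length(bad))
    stop("allele(s) outside the configured map: ", paste(bad, collapse = ", "))
  expectedHigh <- alleles == highAllele
  observedHigh <- levels[shared] >= threshold
  conc <- expectedHigh == observedHigh
  list(concordance = sum(conc) / length(shared),
       discordant = sort(shared[!conc]), n = length(shared))
}
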