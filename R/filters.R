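#' Fisher's ratio between two groups
#'
#' (M1 - M2)^2 / (V1 + V2): squared mean separation over the summed group
#' variances, the univariate separability score used to rank array features
#' between the H and L bulks. Vectorised over features. When both variances
#' are zero the ratio is 0 for equal means and Inf (infinite separation) for
#' unequal means.
#'
#' @param m1,v1 mean and variance in group 1 (the 'H' bulk).
#' @param m2,v2 mean and variance in group 2 (the 'L' bulk).
#' @return numeric vector of Fisher's ratios (>= 0, possibly Inf).
#' @examples
#' fishersRatio(248.23, 84.05^2, 578.61, 291.75^2) # ~ 1.184
#' @export
fishersRatio <- function(m1, v1, m2, v2) {
  if (any(v1 < 0) || any(v2 < 0)) stop("variances must be non-negative")
  denom <- v1 + v2
  num <- (m1 - m2)^2
  out <- ifelse(denom > 0, num / denom, ifelse(num > 0, Inf, 0))
  as.numeric(out)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled form: t = (M1 - M2) / (s_p * sqrt(1/n1 + 1/n2)) with
#' s_p^2 = ((n1 - 1) SD1^2 + (n2 - 1) SD2^2) / (n1 + n2 - 2) and
#' df = n1 + n2 - 2. Welch form: t = (M1 - M2) / sqrt(SD1^2/n1 + SD2^2/n2)
#' with Welch-Satterthwaite df. p is two-sided. Vectorised over features.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @param variant \code{"pooled"} or \code{"welch"}.
#' @param feature optional feature ids for the output.
#' @return data.frame with columns feature, t, df, p, variant, signif
#'   (\code{"**"} at p < 0.01, else \code{"ns"}). df is full precision;
#'   round to 1 decimal for display.
#' @export
twoSampleT <- function(m1, sd1, n1, m2, sd2, n2,
                       variant = c("pooled", "welch"), feature = NULL) {
  variant <- match.arg(variant)
  if (any(n1 < 2) || any(n2 < 2)) stop("each group needs n >= 2")
  if (any(sd1 < 0) || any(sd2 < 0)) stop("SDs must be non-negative")
  if (any(sd1 == 0 & sd2 == 0 & m1 == m2))
    stop("undefined t: both SDs zero with equal means")
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    t <- (m1 - m2) / sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
    # zero spread with unequal means: infinite separation, df by convention
    zero <- (a + b) == 0
    t <- ifelse(zero, sign(m1 - m2) * Inf, t)
    df <- ifelse(zero, n1 + n2 - 2, df)
  }
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  data.frame(feature = if (is.null(feature)) seq_along(t) else feature,
             t = t, df = df, p = p, variant = variant,
             signif = ifelse(p < 0.01, "**", "ns"),
             row.names = NULL)
}

#' Levene test for equality of group variances (mean-centred)
#'
#' One-way F-test on absolute deviations from the group means, used to choose
#' between the pooled (p > 0.05) and Welch (p <= 0.05) t-test forms when raw
#' replicate values are available. Degenerate inputs (a group with zero
#' spread) skip the test and fall back to the Welch form.
#'
#' @param values numeric vector of raw values.
#' @param groups group labels, one per value.
#' @return list with \code{F}, \code{p}, \code{variant} ("pooled"/"welch")
#'   and \code{fallback} (TRUE when the test was not computable).
#' @export
leveneVarianceTest <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  spread <- tapply(values, groups, function(v) sd(v))
  if (any(spread == 0)) {
    return(list(F = NA_real_, p = NA_real_, variant = "welch", fallback = TRUE))
  }
  lt <- car::leveneTest(values, groups, center = mean)
  f <- lt[1, "F value"]
  p <- lt[1, "Pr(>F)"]
  list(F = f, p = p, variant = if (p > 0.05) "pooled" else "welch",
       fallback = FALSE)
}

#' Rank features by Fisher's ratio and keep the top K
#'
#' @param stats data.frame of per-feature group statistics as produced by
#'   \code{\link{groupStatistics}} (columns feature, mean_H, mean_L and
#'   either var_H/var_L or sd_H/sd_L).
#' @param k how many top-ranked features to keep (default 10).
#' @return data.frame with columns rank, feature, fisher_ratio, sorted by
#'   ratio descending; ties break towards the lexicographically smaller id.
#' @export
rankTopK <- function(stats, k = 10L) {
  if (nrow(stats) == 0L) stop("empty group statistics")
  vH <- if (!is.null(stats$var_H)) stats$var_H else stats$sd_H^2
  vL <- if (!is.null(stats$var_L)) stats$var_L else stats$sd_L^2
  ratio <- fishersRatio(stats$mean_H, vH, stats$mean_L, vL)
  ord <- order(-ratio, stats$feature)
  keep <- utils::head(ord, k)
  data.frame(rank = seq_along(keep), feature = stats$feature[keep],
             fisher_ratio = ratio[keep], row.names = NULL)
}

#' Three-criterion marker intersection with Venn region counts
#'
#' @param dfaSet,fisherSet,ttestSet character vectors of feature ids over a
#'   common feature universe.
#' @param compound label for the resulting selection.
#' @return A \linkS4class{MarkerSelection} with the intersection and the 7
#'   Venn region cardinalities (dfa_only, fisher_only, ttest_only,
#'   dfa_fisher, dfa_ttest, fisher_ttest, all_three).
#' @export
threeWayIntersection <- function(dfaSet, fisherSet, ttestSet, compound = "(pooled)") {
  dfaSet <- unique(as.character(dfaSet))
  fisherSet <- unique(as.character(fisherSet))
  ttestSet <- unique(as.character(ttestSet))
  u <- union(union(dfaSet, fisherSet), ttestSet)
  inD <- u %in% dfaSet; inF <- u %in% fisherSet; inT <- u %in% ttestSet
  regions <- c(
    dfa_only = sum(inD & !inF & !inT),
    fisher_only = sum(!inD & inF & !inT),
    ttest_only = sum(!inD & !inF & inT),
    dfa_fisher = sum(inD & inF & !inT),
    dfa_ttest = sum(inD & !inF & inT),
    fisher_ttest = sum(!inD & inF & inT),
    all_three = sum(inD & inF & inT))
  new("MarkerSelection", compound = compound, dfaSet = sort(dfaSet),
      fisherSet = sort(fisherSet), ttestSet = sort(ttestSet),
      intersection = sort(u[inD & inF & inT]), regions = regions)
}

#' Apply all three marker criteria to one compound
#'
#' Computes the bulk-contrast t-test (two-sided, default alpha 0.01) and the
#' Fisher's-ratio top-K from per-feature group statistics, takes the stepwise
#' DFA selection, and intersects the three sets. No multiple-testing
#' correction is applied by default, matching single-array BSA practice where
#' the intersection itself acts as the guard; a Bonferroni switch is
#' available.
#'
#' @param stats per-feature group statistics (see \code{\link{groupStatistics}}).
#' @param dfaFeatures features selected by stepwise DFA (a
#'   \linkS4class{DfaModel} or a character vector).
#' @param alpha t-test significance level (default 0.01).
#' @param k Fisher's-ratio top-K cut (default 10).
#' @param variant t-test form (default \code{"welch"}).
#' @param bonferroni divide alpha by the number of features (default FALSE).
#' @param compound label for the selection.
#' @return A \linkS4class{MarkerSelection}.
#' @export
filterMarkers <- function(stats, dfaFeatures, alpha = 0.01, k = 10L,
                          variant = c("welch", "pooled"), bonferroni = FALSE,
                          compound = "(pooled)") {
  variant <- match.arg(variant)
  if (is(dfaFeatures, "DfaModel")) dfaFeatures <- selectedFeatures(dfaFeatures)
  tt <- twoSampleT(stats$mean_H, stats$sd_H, stats$n_H,
                   stats$mean_L, stats$sd_L, stats$n_L,
                   variant = variant, feature = stats$feature)
  cut <- if (bonferroni) alpha / nrow(stats) else alpha
  ttestSet <- tt$feature[tt$p < cut]
  fisherSet <- rankTopK(stats, k)$feature
  threeWayIntersection(dfaFeatures, fisherSet, ttestSet, compound = compound)
}
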