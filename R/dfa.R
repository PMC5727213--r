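#' Stepwise DFA configuration
#'
#' Probability thresholds for the partial-F entry/removal tests of stepwise
#' discriminant analysis. The defaults (entry 0.05, removal 0.10) are the
#' conventional stepwise Wilks'-lambda settings for two-group bulk screening.
#'
#' @param pEnter a candidate enters when its F-to-enter p-value is <= pEnter.
#' @param pRemove an entered variable leaves when its F-to-remove p-value is
#'   >= pRemove. Must satisfy 0 < pEnter <= pRemove < 1.
#' @param maxSteps cap on accepted entries, bounding runtime on adversarial
#'   data (default 10).
#' @param prior \code{"equal"} (default; bulks are balanced by design) or
#'   \code{"proportional"} class priors for the classification functions.
#' @return list of class \code{"DfaConfig"}.
#' @export
dfaConfig <- function(pEnter = 0.05, pRemove = 0.10, maxSteps = 10L,
                      prior = c("equal", "proportional")) {
  prior <- match.arg(prior)
  if (!(pEnter > 0 && pEnter <= pRemove && pRemove < 1))
    stop("need 0 < pEnter <= pRemove < 1")
  structure(list(pEnter = pEnter, pRemove = pRemove,
                 maxSteps = as.integer(maxSteps), prior = prior),
            class = "DfaConfig")
}

# Within-group (W) and total (T) scatter matrices for samples x features data.
.scatterMatrices <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  tot <- crossprod(sweep(x, 2, colMeans(x)))
  w <- matrix(0, ncol(x), ncol(x), dimnames = dimnames(tot))
  for (g in levels(groups)) {
    xg <- x[groups == g, , drop = FALSE]
    if (nrow(xg) > 1L) w <- w + crossprod(sweep(xg, 2, colMeans(xg)))
  }
  list(W = w, T = tot)
}

.lambdaFromScatter <- function(W, T, idx) {
  dw <- det(W[idx, idx, drop = FALSE])
  dt <- det(T[idx, idx, drop = FALSE])
  if (!is.finite(dw) || !is.finite(dt) || dt <= 0) return(NA_real_)
  if (dw <= 0) return(0)
  dw / dt
}

#' Wilks' lambda for a feature set
#'
#' Lambda = det(W) / det(T) with W the pooled within-group and T the total
#' scatter matrix of the listed features. Values near 1 mean no group
#' separation; values near 0 mean (near-)complete separation.
#'
#' @param x samples x features numeric matrix.
#' @param groups group labels, one per sample.
#' @param features feature names (or column indices) to include.
#' @return Wilks' lambda in (0, 1].
#' @export
wilksLambda <- function(x, groups, features = colnames(x)) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  g <- nlevels(groups)
  idx <- if (is.character(features)) match(features, colnames(x)) else features
  if (anyNA(idx)) stop("unknown features: ",
                       paste(setdiff(features, colnames(x)), collapse = ", "))
  if (nrow(x) <= g + length(idx) - 1L)
    stop("too few samples for ", length(idx), " features and ", g, " groups")
  sc <- .scatterMatrices(x, groups)
  lam <- .lambdaFromScatter(sc$W, sc$T, idx)
  if (is.na(lam))
    stop("collinearity error: singular scatter for features ",
         paste(colnames(x)[idx], collapse = ", "))
  lam
}

# Partial F for moving between nested models with p and p+1 variables:
# F = ((n - g - p) / (g - 1)) * (lambda_p / lambda_p1 - 1), df (g-1, n-g-p).
.partialF <- function(lambdaP, lambdaP1, n, g, p) {
  df1 <- g - 1
  df2 <- n - g - p
  f <- (df2 / df1) * (lambdaP / lambdaP1 - 1)
  list(F = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Stepwise Wilks'-lambda variable selection
#'
#' Greedy stepwise discriminant analysis. At each step the candidate with the
#' largest partial F-to-enter joins the model if its p-value is at most
#' \code{pEnter} (ties broken towards the lexicographically smallest feature
#' id); entered variables whose F-to-remove p-value reaches \code{pRemove}
#' are then dropped. Candidates with a within-group tolerance (1 - R^2
#' against the entered variables) below 1e-4 are skipped as numerically
#' collinear. Selection stops when no entry or removal occurs, when
#' \code{maxSteps} entries have been accepted, or when the residual degrees
#' of freedom are exhausted.
#'
#' @param x samples x features numeric matrix (named columns).
#' @param groups group labels, one per sample (2 groups for bulk screening).
#' @param config a \code{\link{dfaConfig}}.
#' @return A \linkS4class{DfaModel}; when no feature meets the entry
#'   criterion the model is empty with \code{isEmptyModel(x) == TRUE}.
#' @export
stepwiseSelect <- function(x, groups, config = dfaConfig()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("x must have feature (column) names")
  groups <- as.factor(groups)
  g <- nlevels(groups)
  n <- nrow(x)
  if (g < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  sc <- .scatterMatrices(x, groups)
  W <- sc$W; T <- sc$T
  feats <- colnames(x)
  entered <- character(0)
  lambdaCur <- 1
  trace <- numeric(0)
  steps <- 0L

  tolerance <- function(cand, idxIn) {
    if (W[cand, cand] <= 0) return(0)
    if (length(idxIn) == 0L) return(1)
    wss <- W[idxIn, idxIn, drop = FALSE]
    cross <- W[idxIn, cand]
    resid <- W[cand, cand] - drop(crossprod(cross, solve(wss, cross)))
    resid / W[cand, cand]
  }

  repeat {
    changed <- FALSE
    p <- length(entered)
    # --- entry ---
    if (steps < config$maxSteps && n - g - p >= 2L) {
      cands <- setdiff(feats, entered)
      idxIn <- match(entered, feats)
      best <- NULL
      for (cand in sort(cands)) {
        tol <- tryCatch(tolerance(cand, idxIn), error = function(e) 0)
        if (!is.finite(tol) || tol < 1e-4) next
        lamNew <- .lambdaFromScatter(W, T, c(idxIn, match(cand, feats)))
        if (is.na(lamNew) || lamNew <= 0 || lamNew > lambdaCur + 1e-12) next
        ft <- .partialF(lambdaCur, lamNew, n, g, p)
        if (!is.finite(ft$F)) next
        if (is.null(best) || ft$F > best$F + 1e-12) # sorted cands => lexicographic ties
          best <- list(feature = cand, F = ft$F, pval = ft$p, lambda = lamNew)
      }
      if (!is.null(best) && best$pval <= config$pEnter) {
        entered <- c(entered, best$feature)
        lambdaCur <- best$lambda
        trace <- c(trace, lambdaCur)
        steps <- steps + 1L
        changed <- TRUE
      }
    }
    # --- removal ---
    if (length(entered) > 1L) {
      repeat {
        p2 <- length(entered)
        worst <- NULL
        for (j in entered) {
          keep <- setdiff(entered, j)
          lamWithout <- .lambdaFromScatter(W, T, match(keep, feats))
          if (is.na(lamWithout)) next
          ft <- .partialF(lamWithout, lambdaCur, n, g, p2 - 1L)
          if (is.null(worst) || ft$p > worst$pval)
            worst <- list(feature = j, pval = ft$p, lambda = lamWithout)
        }
        if (!is.null(worst) && worst$pval >= config$pRemove) {
          entered <- setdiff(entered, worst$feature)
          lambdaCur <- worst$lambda
          trace <- c(trace, lambdaCur)
          changed <- TRUE
        } else break
        if (length(entered) <= 1L) break
      }
    }
    if (!changed) break
  }

  if (length(entered) == 0L) {
    return(new("DfaModel", features = character(0), lambdaTrace = numeric(0),
               coefficients = matrix(0, 0, g, dimnames = list(NULL, levels(groups))),
               constants = setNames(numeric(g), levels(groups)),
               groupMeans = matrix(0, 0, g, dimnames = list(NULL, levels(groups))),
               pooledCov = matrix(0, 0, 0), groups = levels(groups),
               counts = as.integer(table(groups)),
               priors = setNames(rep(1 / g, g), levels(groups)),
               n = n, noDiscriminators = TRUE))
  }
  fitClassifier(x, groups, entered, prior = config$prior, lambdaTrace = trace)
}

#' Fisher classification functions for a fixed feature set
#'
#' For group k, coefficients b_k = S_w^{-1} m_k and constant
#' c_k = -0.5 m_k' S_w^{-1} m_k + log(prior_k), with S_w = W / (n - g) the
#' pooled within-group covariance. A sample is assigned to the group with the
#' largest classification score; exact ties break towards the first group
#' level.
#'
#' @param x samples x features matrix.
#' @param groups group labels.
#' @param features feature names to use.
#' @param prior \code{"equal"} or \code{"proportional"}.
#' @param lambdaTrace optional Wilks trace to store in the model.
#' @return A \linkS4class{DfaModel}.
#' @export
fitClassifier <- function(x, groups, features, prior = c("equal", "proportional"),
                          lambdaTrace = NULL) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  groups <- as.factor(groups)
  g <- nlevels(groups)
  n <- nrow(x)
  xs <- x[, features, drop = FALSE]
  sc <- .scatterMatrices(xs, groups)
  Sw <- sc$W / (n - g)
  if (!is.finite(det(Sw)) || det(Sw) <= 0)
    stop("singular pooled within-group covariance for features ",
         paste(features, collapse = ", "))
  means <- sapply(levels(groups), function(lv) colMeans(xs[groups == lv, , drop = FALSE]))
  means <- matrix(means, ncol = g, dimnames = list(features, levels(groups)))
  counts <- as.integer(table(groups))
  pri <- if (prior == "equal") rep(1 / g, g) else counts / n
  names(pri) <- levels(groups)
  coefs <- solve(Sw, means)
  consts <- setNames(-0.5 * colSums(means * coefs) + log(pri), levels(groups))
  if (is.null(lambdaTrace))
    lambdaTrace <- .lambdaFromScatter(sc$W, sc$T, seq_along(features))
  new("DfaModel", features = features, lambdaTrace = lambdaTrace,
      coefficients = matrix(coefs, ncol = g, dimnames = list(features, levels(groups))),
      constants = consts, groupMeans = means, pooledCov = Sw,
      groups = levels(groups), counts = counts, priors = pri,
      n = as.integer(n), noDiscriminators = FALSE)
}

#' Predict group membership from a fitted DfaModel
#'
#' @param model \linkS4class{DfaModel}.
#' @param newdata samples x features matrix containing the model's features.
#' @return character vector of predicted group labels.
#' @export
predictGroups <- function(model, newdata) {
  if (isEmptyModel(model)) stop("cannot predict from an empty model")
  newdata <- as.matrix(newdata)
  miss <- setdiff(model@features, colnames(newdata))
  if (length(miss)) stop("newdata lacks model features: ", paste(miss, collapse = ", "))
  scores <- newdata[, model@features, drop = FALSE] %*% model@coefficients
  scores <- sweep(scores, 2, model@constants, "+")
  model@groups[apply(scores, 1, which.max)] # which.max: ties -> first group
}

#' Classification report: original, leave-one-out, and holdout accuracy
#'
#' The original rate re-classifies the fitting samples. The cross-validated
#' rate is leave-one-out with the classification functions refit per fold but
#' the feature set frozen. The holdout rate scores an independent sample set
#' (e.g. the second biological replicate) with the model fit on all training
#' samples.
#'
#' @param model \linkS4class{DfaModel} fit on \code{x}/\code{groups}.
#' @param x,groups the fitting data.
#' @param testX,testGroups optional holdout data.
#' @return A \linkS4class{ClassificationReport}.
#' @export
classifyAndReport <- function(model, x, groups, testX = NULL, testGroups = NULL) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  n <- nrow(x)
  pred <- predictGroups(model, x)
  originalPct <- 100 * sum(pred == as.character(groups)) / n
  cvHits <- vapply(seq_len(n), function(i) {
    foldModel <- fitClassifier(x[-i, , drop = FALSE], droplevels(groups[-i]),
                               model@features,
                               prior = if (all(model@priors == model@priors[1])) "equal" else "proportional")
    predictGroups(foldModel, x[i, , drop = FALSE]) == as.character(groups[i])
  }, logical(1))
  cvPct <- 100 * sum(cvHits) / n
  holdoutPct <- NA_real_
  if (!is.null(testX)) {
    predT <- predictGroups(model, as.matrix(testX))
    holdoutPct <- 100 * sum(predT == as.character(testGroups)) / nrow(as.matrix(testX))
  }
  new("ClassificationReport", originalPct = originalPct, cvPct = cvPct,
      holdoutPct = holdoutPct,
      confusion = table(true = as.character(groups), predicted = pred),
      n = as.integer(n))
}

#' Screen one compound's bulk hybridisation for discriminative features
#'
#' The two-stage bulk screening design: stepwise selection runs on the first
#' biological replicate (training set), the second biological replicate is
#' scored as a holdout, and the features surviving stage one are subjected to
#' stepwise analysis again on all data points of both biological replicates
#' to form the final classification model, which is then evaluated by
#' leave-one-out cross-validation.
#'
#' @param x \linkS4class{SignalMatrix} for one compound's H/L hybridisations.
#' @param config a \code{\link{dfaConfig}}.
#' @return list with \code{model} (final \linkS4class{DfaModel}),
#'   \code{trainingModel} (stage-one model), and \code{report}
#'   (\linkS4class{ClassificationReport}; holdout slot holds the
#'   biological-replicate-2 accuracy of the stage-one model).
#' @export
screenCompound <- function(x, config = dfaConfig()) {
  m <- t(snr(x))
  b <- bulkLabels(x)
  br <- bioRep(x)
  if (length(unique(b)) != 2L) stop("matrix must cover both bulks")
  train <- br == min(br)
  test <- !train
  stage1 <- stepwiseSelect(m[train, , drop = FALSE], b[train], config)
  if (isEmptyModel(stage1)) {
    return(list(model = stage1, trainingModel = stage1, report = NULL))
  }
  holdout <- if (any(test)) {
    predT <- predictGroups(stage1, m[test, , drop = FALSE])
    100 * sum(predT == b[test]) / sum(test)
  } else NA_real_
  stage2 <- stepwiseSelect(m[, selectedFeatures(stage1), drop = FALSE], b, config)
  if (isEmptyModel(stage2)) {
    return(list(model = stage2, trainingModel = stage1, report = NULL))
  }
  report <- classifyAndReport(stage2, m[, , drop = FALSE], b)
  report@holdoutPct <- holdout
  list(model = stage2, trainingModel = stage1, report = report)
}
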