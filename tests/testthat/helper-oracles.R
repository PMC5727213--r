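# Independent oracles: deliberately re-derive quantities through different
# code paths (stats::manova, direct density formulas, brute-force sorting)
# so they never share logic with the package implementation.

# Wilks' lambda via stats::manova (stats::lm in the univariate case) for a
# feature subset.
oracleWilks <- function(x, groups, features) {
  y <- as.matrix(x[, features, drop = FALSE])
  g <- factor(groups)
  if (ncol(y) == 1L) {
    fit <- stats::lm(y[, 1] ~ g)
    return(sum(stats::resid(fit)^2) / sum((y[, 1] - mean(y[, 1]))^2))
  }
  fit <- stats::manova(y ~ g)
  summary(fit, test = "Wilks")$stats[1, "Wilks"]
}

# Exhaustive greedy stepwise re-implementation: at every step enumerate all
# entry candidates with manova-based Wilks, apply the same entry/removal
# probability rules, lexicographic tie-break.
oracleStepwise <- function(x, groups, pEnter = 0.05, pRemove = 0.10,
                           maxSteps = 10L) {
  x <- as.matrix(x)
  g <- factor(groups)
  n <- nrow(x)
  ng <- nlevels(g)
  entered <- character(0)
  lambdaCur <- 1
  steps <- 0L
  partial <- function(lamP, lamP1, p) {
    df1 <- ng - 1; df2 <- n - ng - p
    f <- (df2 / df1) * (lamP / lamP1 - 1)
    c(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  repeat {
    changed <- FALSE
    p <- length(entered)
    if (steps < maxSteps && n - ng - p >= 2L) {
      best <- NULL
      for (cand in sort(setdiff(colnames(x), entered))) {
        lamNew <- tryCatch(oracleWilks(x, g, c(entered, cand)),
                           error = function(e) NA_real_)
        if (is.na(lamNew) || lamNew <= 0 || lamNew > lambdaCur + 1e-12) next
        # same tolerance rule as the implementation, via lm R^2
        if (p > 0) {
          r2 <- vapply(levels(g), function(lv) {
            sub <- g == lv
            f <- stats::lm(x[sub, cand] ~ x[sub, entered, drop = FALSE])
            summary(f)$r.squared
          }, numeric(1))
          # pooled within-group tolerance
          wres <- 0; wtot <- 0
          for (lv in levels(g)) {
            sub <- g == lv
            f <- stats::lm(x[sub, cand] ~ x[sub, entered, drop = FALSE])
            wres <- wres + sum(stats::resid(f)^2)
            wtot <- wtot + sum((x[sub, cand] - mean(x[sub, cand]))^2)
          }
          if (wtot <= 0 || wres / wtot < 1e-4) next
        }
        ft <- partial(lambdaCur, lamNew, p)
        if (is.null(best) || ft["F"] > best$F + 1e-12)
          best <- list(feature = cand, F = unname(ft["F"]),
                       pval = unname(ft["p"]), lambda = lamNew)
      }
      if (!is.null(best) && best$pval <= pEnter) {
        entered <- c(entered, best$feature)
        lambdaCur <- best$lambda
        steps <- steps + 1L
        changed <- TRUE
      }
    }
    if (length(entered) > 1L) {
      repeat {
        p2 <- length(entered)
        worst <- NULL
        for (j in entered) {
          keep <- setdiff(entered, j)
          lamWithout <- oracleWilks(x, g, keep)
          ft <- partial(lamWithout, lambdaCur, p2 - 1L)
          if (is.null(worst) || ft["p"] > worst$pval)
            worst <- list(feature = j, pval = unname(ft["p"]),
                          lambda = lamWithout)
        }
        if (!is.null(worst) && worst$pval >= pRemove) {
          entered <- setdiff(entered, worst$feature)
          lambdaCur <- worst$lambda
          changed <- TRUE
        } else break
        if (length(entered) <= 1L) break
      }
    }
    if (!changed) break
  }
  entered
}

# Direct two-class linear discriminant from the multivariate normal score
# formula: score_k(x) = x' S^-1 mu_k - 0.5 mu_k' S^-1 mu_k + log(prior).
oracleLdaPredict <- function(x, groups, newdata) {
  x <- as.matrix(x)
  g <- factor(groups)
  n <- nrow(x)
  S <- matrix(0, ncol(x), ncol(x))
  mus <- list()
  for (lv in levels(g)) {
    xg <- x[g == lv, , drop = FALSE]
    mus[[lv]] <- colMeans(xg)
    S <- S + (nrow(xg) - 1) * stats::cov(xg)
  }
  S <- S / (n - nlevels(g))
  scores <- sapply(levels(g), function(lv) {
    as.matrix(newdata) %*% solve(S, mus[[lv]]) -
      0.5 * drop(crossprod(mus[[lv]], solve(S, mus[[lv]]))) +
      log(1 / nlevels(g))
  })
  levels(g)[apply(matrix(scores, ncol = nlevels(g)), 1, which.max)]
}

# Two-group sample builder: p features, groups n1/n2, one optional planted
# column with a mean shift of `shift` SDs.
makeTwoGroup <- function(n1 = 6, n2 = 6, p = 8, shift = 0, plantedCol = 1,
                         seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n1 + n2) * p), n1 + n2, p,
              dimnames = list(NULL, sprintf("V%02d", seq_len(p))))
  if (shift != 0) x[seq_len(n1), plantedCol] <- x[seq_len(n1), plantedCol] + shift
  list(x = x, groups = rep(c("H", "L"), c(n1, n2)))
}

# Small SignalMatrix builder.
makeSignal <- function(m, bulk = NULL, bio = NULL, tech = NULL) {
  ns <- ncol(m)
  if (is.null(bulk)) bulk <- rep(c("H", "L"), each = ns / 2)
  if (is.null(bio)) bio <- rep(1L, ns)
  if (is.null(tech)) tech <- stats::ave(seq_len(ns), bulk, FUN = seq_along)
  SignalMatrix(m, bulk, bio, tech)
}

# TRUE when pct equals 100 * k / n for some integer k.
isGranular <- function(pct, n) {
  abs(pct * n / 100 - round(pct * n / 100)) < 1e-9
}
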