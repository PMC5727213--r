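# Seeded sub-streams: one stream per consumer, derived from the master seed
# by a fixed label, so adding a generator never perturbs existing draws.
.subSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 48271 + h) %% 2147483647
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of one simulated aroma compound
#'
#' The phenotype model is zero-inflated and polygenic: an F1 individual's
#' relative composition is Bernoulli(1 - pi) x (sum of inherited per-allele
#' locus effects + Gamma(shape, scale) noise), truncated to [0, 100]. Locus
#' dosages are disomic: each parent transmits one allele with probability
#' dosage/2. Parents produce their genetic value plus Gamma noise per
#' technical replicate, or exactly 0 when their genetic value is 0.
#'
#' @param name compound id.
#' @param pi zero-inflation probability in [0, 1].
#' @param gammaShape,gammaScale Gamma noise parameters (percent scale).
#' @param effects per-allele effect (%) of each locus.
#' @param parent1,parent2 parental allele dosages per locus (0, 1 or 2).
#' @param nPlanted number of array features carrying this compound's signal.
#' @param delta planted effect size: the bulk mean gap in pooled within-bulk
#'   SDs (recycled). Default 3, the order of separation shown by validated
#'   bulk markers on replicated subtracted arrays.
#' @param direction "H" (signal up in the high bulk) or "L" (up in the low
#'   bulk; both polarities occur on subtracted arrays), recycled.
#' @return list of class \code{"CompoundSpec"}.
#' @export
compoundSpec <- function(name, pi, gammaShape = 1.5, gammaScale = 1.5,
                         effects = c(4, 2), parent1 = c(2, 1), parent2 = c(0, 0),
                         nPlanted = 2L, delta = 3, direction = "H") {
  stopifnot(pi >= 0, pi <= 1, all(delta >= 0),
            length(effects) == length(parent1),
            length(effects) == length(parent2),
            all(parent1 %in% 0:2), all(parent2 %in% 0:2))
  structure(list(name = name, pi = pi, gammaShape = gammaShape,
                 gammaScale = gammaScale, effects = effects,
                 parent1 = parent1, parent2 = parent2,
                 nPlanted = as.integer(nPlanted),
                 delta = rep_len(delta, nPlanted),
                 direction = rep_len(direction, nPlanted)),
            class = "CompoundSpec")
}

# Eight compounds loosely patterned on key strawberry aroma volatiles: mostly
# heterozygous, low-dosage parental genotypes so the F1 distributions come out
# zero-inflated and right-skewed, with heterozygous-in-both-parents loci
# providing transgressive allele combinations; one compound (the methyl
# hexanoate analogue) carries a single large-effect locus and segregates
# bimodally. Planted-marker counts per compound span 1-4, the model sizes seen
# in two-bulk array screens.
.defaultCompounds <- function() {
  list(
    compoundSpec("methyl_butanoate", pi = 0.35, gammaScale = 2,
                 effects = c(7, 5), parent1 = c(1, 1), parent2 = c(0, 0),
                 nPlanted = 2L, direction = c("L", "H")),
    compoundSpec("ethyl_butanoate", pi = 0.30,
                 effects = c(4, 3, 2), parent1 = c(1, 1, 0), parent2 = c(1, 0, 0),
                 nPlanted = 3L, direction = c("L", "L", "H")),
    compoundSpec("methyl_hexanoate", pi = 0.15, gammaShape = 2, gammaScale = 2,
                 effects = c(16, 6), parent1 = c(1, 1), parent2 = c(0, 0),
                 nPlanted = 2L, direction = c("L", "H")),
    compoundSpec("ethyl_hexanoate", pi = 0.30, gammaScale = 2,
                 effects = c(5, 4, 3), parent1 = c(1, 1, 0), parent2 = c(0, 1, 1),
                 nPlanted = 2L, direction = c("H", "L")),
    compoundSpec("mesifuranne", pi = 0.45,
                 effects = c(5, 3), parent1 = c(0, 0), parent2 = c(1, 1),
                 nPlanted = 3L, direction = c("H", "H", "L")),
    compoundSpec("linalool", pi = 0.35, gammaScale = 1,
                 effects = c(5, 3), parent1 = c(1, 1), parent2 = c(1, 0),
                 nPlanted = 1L, direction = "H"),
    compoundSpec("e_nerolidol", pi = 0.30, gammaShape = 2, gammaScale = 2,
                 effects = c(12, 8), parent1 = c(1, 0), parent2 = c(1, 1),
                 nPlanted = 3L, direction = c("H", "L", "H")),
    compoundSpec("g_dodecalactone", pi = 0.50, gammaScale = 1,
                 effects = c(4, 2), parent1 = c(0, 0), parent2 = c(1, 1),
                 nPlanted = 4L, direction = c("H", "H", "L", "H"))
  )
}

#' Simulation configuration
#'
#' Defaults emulate the canonical screening design: 50 F1 individuals, 8
#' target compounds with right-skewed zero-inflated distributions and
#' transgressive segregation, and a 287-feature array hybridised with 2 bulks
#' x 2 biological x 6 technical replicates. Array noise is multiplicative
#' (log-normal): baseline log-mean/log-SD set feature brightness spread,
#' \code{techSD} the per-hybridisation log-scale noise (0.35, matching
#' coefficients of variation around 0.3-0.5 typical of replicated bulk
#' hybridisations), and \code{bioRepSD} an optional per-array batch factor
#' (default 0: biological replicates of the same pooled DNA are treated as
#' exchangeable re-hybridisations).
#'
#' @param seed master seed; all module streams derive from it.
#' @param nIndividuals F1 population size (default 50).
#' @param compounds list of \code{\link{compoundSpec}}s.
#' @param nFeatures array size (default 287); must cover all planted markers.
#' @param baselineLogMean,baselineLogSD log-normal feature brightness.
#' @param bioRepSD log-scale SD of the per-array batch factor.
#' @param techSD log-scale SD of technical noise.
#' @param nBioRep,nTechRep replicate design (defaults 2 and 6).
#' @return list of class \code{"SimConfig"} with planted feature ids assigned
#'   deterministically per compound.
#' @export
simConfig <- function(seed = 1L, nIndividuals = 50L,
                      compounds = .defaultCompounds(), nFeatures = 287L,
                      baselineLogMean = log(150), baselineLogSD = 1,
                      bioRepSD = 0, techSD = 0.35,
                      nBioRep = 2L, nTechRep = 6L) {
  stopifnot(nIndividuals >= 2L, bioRepSD >= 0, techSD >= 0, nFeatures >= 1L)
  totalPlanted <- sum(vapply(compounds, function(cs) cs$nPlanted, integer(1)))
  if (nFeatures < totalPlanted)
    stop("nFeatures must cover all planted markers (", totalPlanted, ")")
  features <- sprintf("FDP%03d", seq_len(nFeatures))
  offset <- 0L
  for (i in seq_along(compounds)) {
    k <- compounds[[i]]$nPlanted
    compounds[[i]]$plantedFeatures <- features[offset + seq_len(k)]
    offset <- offset + k
  }
  structure(list(seed = as.integer(seed), nIndividuals = as.integer(nIndividuals),
                 compounds = compounds, nFeatures = as.integer(nFeatures),
                 features = features, baselineLogMean = baselineLogMean,
                 baselineLogSD = baselineLogSD, bioRepSD = bioRepSD,
                 techSD = techSD, nBioRep = as.integer(nBioRep),
                 nTechRep = as.integer(nTechRep)),
            class = "SimConfig")
}

#' Simulate an F1 phenotype table with known genetic truth
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{pheno} (F1 \linkS4class{PhenotypeTable}),
#'   \code{parents} (2-individual \linkS4class{PhenotypeTable} from 3
#'   technical replicates each), and \code{truth} (per-compound genotype
#'   dosage matrices and planted marker ids).
#' @export
simulatePhenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(.subSeed(config$seed, "phenotypes"), {
    n <- config$nIndividuals
    ids <- sprintf("P%02d", seq_len(n))
    cn <- vapply(config$compounds, `[[`, character(1), "name")
    means <- array(0, c(n, length(cn)), list(ids, cn))
    pmeans <- array(0, c(2, length(cn)), list(c("parent1", "parent2"), cn))
    psds <- pmeans
    genotypes <- list()
    for (j in seq_along(config$compounds)) {
      cs <- config$compounds[[j]]
      L <- length(cs$effects)
      dos <- sapply(seq_len(L), function(l) {
        rbinom(n, 1, cs$parent1[l] / 2) + rbinom(n, 1, cs$parent2[l] / 2)
      })
      dos <- matrix(dos, nrow = n, dimnames = list(ids, paste0("locus", seq_len(L))))
      genetic <- drop(dos %*% cs$effects)
      z <- rbinom(n, 1, 1 - cs$pi)
      val <- z * (genetic + rgamma(n, cs$gammaShape, scale = cs$gammaScale))
      means[, j] <- pmin(val, 100)
      for (pp in 1:2) {
        pg <- sum((if (pp == 1) cs$parent1 else cs$parent2) * cs$effects)
        reps <- if (pg == 0) c(0, 0, 0)
                else pmin(pg + rgamma(3, cs$gammaShape, scale = cs$gammaScale), 100)
        pmeans[pp, j] <- mean(reps)
        psds[pp, j] <- sd(reps)
      }
      genotypes[[cs$name]] <- dos
    }
    list(pheno = PhenotypeTable(means),
         parents = PhenotypeTable(pmeans, psds, 3L),
         truth = list(genotypes = genotypes,
                      planted = lapply(config$compounds, function(cs)
                        setNames(list(cs$plantedFeatures, cs$delta, cs$direction),
                                 c("features", "delta", "direction")))))
  })
}

#' Simulate one compound's bulk-hybridisation SignalMatrix
#'
#' SNR(feature, sample) = exp(mu_f + batch + noise): a log-normal feature
#' baseline times a per-array batch factor times technical noise. Each
#' planted feature for the compound receives a multiplicative effect on one
#' bulk, sized so that the bulk mean gap equals delta pooled within-bulk
#' SDs: with CV = sqrt(exp(s^2) - 1), s^2 = bioRepSD^2 + techSD^2, the
#' multiplier k solves (k - 1) = delta * CV * sqrt((1 + k^2) / 2). Because
#' constant-CV multiplicative noise scales the boosted bulk's SD along with
#' its mean, standardised gaps are capped at sqrt(2)/CV; effects beyond the
#' cap are rejected as infeasible.
#'
#' @param config a \code{\link{simConfig}}.
#' @param compound compound name (must appear in the config); planted effects
#'   come from its \code{\link{compoundSpec}}.
#' @param plantEffects set FALSE for a global null array (delta = 0
#'   everywhere), e.g. for calibration experiments.
#' @return list with \code{signal} (\linkS4class{SignalMatrix}) and
#'   \code{truth} (planted features, deltas, directions).
#' @export
simulateArray <- function(config, compound, plantEffects = TRUE) {
  stopifnot(inherits(config, "SimConfig"))
  cn <- vapply(config$compounds, `[[`, character(1), "name")
  idx <- match(compound, cn)
  if (is.na(idx)) stop("unknown compound: ", compound)
  cs <- config$compounds[[idx]]
  .withSeed(.subSeed(config$seed, paste0("array:", compound)), {
    nf <- config$nFeatures
    bulks <- rep(c("H", "L"), each = config$nBioRep * config$nTechRep)
    bio <- rep(rep(seq_len(config$nBioRep), each = config$nTechRep), 2)
    tech <- rep(seq_len(config$nTechRep), 2 * config$nBioRep)
    ns <- length(bulks)
    mu <- rnorm(nf, config$baselineLogMean, config$baselineLogSD)
    batchKey <- paste(bulks, bio)
    batch <- setNames(rnorm(length(unique(batchKey)), 0, config$bioRepSD),
                      unique(batchKey))
    noise <- matrix(rnorm(nf * ns, 0, config$techSD), nf, ns)
    m <- exp(outer(mu, rep(0, ns), "+") +
               matrix(batch[batchKey], nf, ns, byrow = TRUE) + noise)
    dimnames(m) <- list(config$features,
                        paste(bulks, bio, tech, sep = "_"))
    if (plantEffects && cs$nPlanted > 0L) {
      s2 <- config$bioRepSD^2 + config$techSD^2
      cv <- sqrt(exp(s2) - 1) # within-bulk coefficient of variation
      # multiplier k solving gap = delta * pooled within-bulk SD:
      # (k - 1) m = delta * cv * m * sqrt((1 + k^2) / 2)
      c <- cs$delta * cv
      if (any(c >= sqrt(2)))
        stop("infeasible planted effect: delta * CV must be < sqrt(2) under ",
             "constant-CV multiplicative noise (delta <= ",
             round(sqrt(2) / cv, 2), " here)")
      a <- 1 - c^2 / 2
      k <- (1 + sqrt(pmax(1 - a^2, 0))) / a
      for (i in seq_len(cs$nPlanted)) {
        rows <- cs$plantedFeatures[i]
        cols <- bulks == cs$direction[i]
        m[rows, cols] <- m[rows, cols] * k[i]
      }
    }
    list(signal = SignalMatrix(m, bulks, bio, tech),
         truth = list(features = cs$plantedFeatures, delta = cs$delta,
                      direction = cs$direction))
  })
}

#' Write a self-consistent fixture bundle to disk
#'
#' Simulates phenotypes, builds per-compound bulk designs, simulates one
#' SignalMatrix per compound, and writes everything as plain text: a wide
#' phenotype TSV, a bulk-design JSON, one long-format SNR TSV per compound,
#' and a ground-truth JSON. Byte-stable for a fixed config.
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir output directory (created if missing).
#' @param q,minBulkSize bulk rule parameters (see \code{\link{assignExtremes}}).
#' @return invisibly, a list of the paths written and the in-memory objects.
#' @export
endToEndFixture <- function(config, dir, q = 0.2, minBulkSize = 3L) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulatePhenotypes(config)
  phenoPath <- file.path(dir, "pheno.tsv")
  writePhenotypeTable(sim$pheno, phenoPath)
  designs <- list(); arrays <- list(); arrayPaths <- character(0)
  for (cs in config$compounds) {
    d <- assignExtremes(sim$pheno, cs$name, q = q, minBulkSize = minBulkSize)
    designs[[cs$name]] <- d
    a <- simulateArray(config, cs$name)
    arrays[[cs$name]] <- a$signal
    p <- file.path(dir, paste0("array_", cs$name, ".tsv"))
    writeSignalMatrix(a$signal, p)
    arrayPaths <- c(arrayPaths, p)
  }
  bulksPath <- file.path(dir, "bulks.json")
  writeBulkDesigns(designs, bulksPath)
  truthPath <- file.path(dir, "truth.json")
  truth <- lapply(config$compounds, function(cs)
    list(features = cs$plantedFeatures, delta = cs$delta,
         direction = cs$direction))
  names(truth) <- vapply(config$compounds, `[[`, character(1), "name")
  jsonlite::write_json(truth, truthPath, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = c(pheno = phenoPath, bulks = bulksPath,
                           truth = truthPath, arrays = arrayPaths),
                 pheno = sim$pheno, parents = sim$parents,
                 designs = designs, arrays = arrays, truth = truth))
}

#' Planted-marker recovery experiment
#'
#' Runs the full screen over several seeds: simulate phenotypes, build bulks,
#' simulate arrays, run the two-stage stepwise screen, and apply the
#' three-criterion filter. Reports per (seed, compound) the selected and
#' planted features, leave-one-out accuracy, holdout accuracy, and the
#' three-criterion intersection.
#'
#' @param seeds integer vector of master seeds.
#' @param configFactory function(seed) returning a \code{\link{simConfig}};
#'   defaults to \code{simConfig(seed)}.
#' @param config a \code{\link{dfaConfig}}.
#' @return data.frame with one row per (seed, compound): counts of planted,
#'   selected, true-positive DFA features, intersection counts, and accuracy
#'   percentages.
#' @export
evaluateRecovery <- function(seeds, configFactory = simConfig,
                             config = dfaConfig()) {
  rows <- list()
  for (s in seeds) {
    cfg <- configFactory(s)
    sim <- simulatePhenotypes(cfg)
    for (cs in cfg$compounds) {
      d <- tryCatch(assignExtremes(sim$pheno, cs$name),
                    error = function(e) NULL)
      if (is.null(d)) next
      arr <- simulateArray(cfg, cs$name)
      scr <- screenCompound(arr$signal, config)
      sel <- if (isEmptyModel(scr$model)) character(0)
             else selectedFeatures(scr$model)
      planted <- cs$plantedFeatures
      ms <- filterMarkers(groupStatistics(arr$signal), sel,
                          compound = cs$name)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, compound = cs$name,
        n_planted = length(planted), n_selected = length(sel),
        n_true_positive = length(intersect(sel, planted)),
        n_intersection = length(markerIntersection(ms)),
        n_intersection_tp = length(intersect(markerIntersection(ms), planted)),
        loo_pct = if (is.null(scr$report)) NA_real_ else cvPct(scr$report),
        holdout_pct = if (is.null(scr$report)) NA_real_ else holdoutPct(scr$report),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Null-calibration experiment for the bulk-contrast t-test
#'
#' Simulates arrays with no planted effects over several seeds and reports
#' the per-feature rejection rate of the two-sided t-test at \code{alpha}.
#' The default variant \code{"levene"} mirrors the pipeline's raw-data
#' behaviour: the pooled form when the mean-centred Levene test accepts
#' variance equality (which it does for almost all null features), the Welch
#' form otherwise.
#'
#' @param seeds integer vector of master seeds.
#' @param alpha significance level (default 0.01).
#' @param variant \code{"levene"} (per-feature selection), \code{"pooled"},
#'   or \code{"welch"}.
#' @param configFactory function(seed) returning a \code{\link{simConfig}}.
#' @return list with \code{rate}, \code{rejections}, \code{tests}.
#' @export
nullCalibration <- function(seeds, alpha = 0.01,
                            variant = c("levene", "pooled", "welch"),
                            configFactory = simConfig) {
  variant <- match.arg(variant)
  rej <- 0L; tot <- 0L
  for (s in seeds) {
    cfg <- configFactory(s)
    arr <- simulateArray(cfg, cfg$compounds[[1]]$name, plantEffects = FALSE)
    st <- groupStatistics(arr$signal)
    if (variant == "levene") {
      m <- snr(arr$signal)
      b <- bulkLabels(arr$signal)
      for (i in seq_len(nrow(st))) {
        v <- leveneVarianceTest(m[i, ], b)$variant
        tt <- twoSampleT(st$mean_H[i], st$sd_H[i], st$n_H[i],
                         st$mean_L[i], st$sd_L[i], st$n_L[i], variant = v)
        rej <- rej + (tt$p < alpha)
      }
    } else {
      tt <- twoSampleT(st$mean_H, st$sd_H, st$n_H, st$mean_L, st$sd_L, st$n_L,
                       variant = variant, feature = st$feature)
      rej <- rej + sum(tt$p < alpha)
    }
    tot <- tot + nrow(st)
  }
  list(rate = rej / tot, rejections = rej, tests = tot)
}
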