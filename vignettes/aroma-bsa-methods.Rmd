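---
title: "Microarray-assisted bulked segregant analysis for aroma markers: methods and design"
author: "aromaBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microarray-assisted BSA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromaBSA)
```

## The problem

Fruit aroma is a polygenic trait: individual volatile compounds (esters,
furanones, terpenes, lactones) segregate in F1 populations with strongly
right-skewed, often zero-inflated distributions and frequent transgressive
segregation. Bulked segregant analysis (BSA) sidesteps per-individual
genotyping: DNA from individuals with extreme opposite phenotypes for one
compound is pooled into a high ('H') and a low/undetectable ('L') bulk, and
the two pools are hybridised to a genomic discovery array (here a
287-feature subtracted diversity panel). Any feature whose signal-to-noise
ratio (SNR) differs systematically between bulks is a candidate marker
linked to a locus controlling that compound.

`aromaBSA` implements the full analysis chain: GC-MS quantitation and
compound selection, bulk construction, a from-scratch stepwise discriminant
function analysis (DFA) of the SNR matrices, Fisher's-ratio and t-test
filters with a three-criterion intersection, genomic anchoring with
candidate-gene lookup, SNP calling between parental amplicons, and a seeded
synthetic-data generator with planted ground truth.

## Phenotypes: area normalisation and compound selection

Peak areas from each chromatogram are converted to relative compositions,

$$C_i = A_i / A_t \times 100\,\%,$$

under the usual area-normalisation assumptions (equal detector response,
complete detection). A compound counts as detected in a sample only when it
appears in at least 2 technical replicates with a library-match quality
strictly greater than 80; per-individual means and sample SDs (n − 1) are
taken over three technical replicates. Cells backed by a single replicate
report SD 0 alongside a replicate count of 1 so the degenerate case stays
visible.

Compounds enter marker discovery only if their F1 population mean reaches
0.1% and the two parents differ significantly (two-sided p < 0.05 by
default); rarely detected compounds are strongly environment-driven and
uninformative for segregation analysis.

**Transgression.** An F1 individual is transgressive when it exceeds the
larger parental mean, or — if the compound was actually detected in it —
falls below the smaller parental mean. Exact zeros are treated as
"undetected" rather than as sub-parental production; without this reading a
compound produced by both parents but absent from some F1 individuals would
always be called transgressive, which does not match how segregation
patterns are read in practice.

## Bulks

The cut rule that produces 3–27-plant bulks from 50 individuals is not
uniquely determined by the published range, so the default is a symmetric
quantile rule (q = 0.2) with two refinements: exact zeros are always
eligible for the L bulk (the "low/undetectable" semantics), and ties at a
cut are all included, so bulk sizes are deterministic but may exceed the
nominal quantile count. Absolute thresholds are available where a
quantile-free rule is preferred. Disjointness and the H-above-L ordering
are enforced invariants.

## Stepwise discriminant analysis

For a feature set $S$, Wilks' lambda is
$\Lambda = \det W_S / \det T_S$ with $W$ the pooled within-group and $T$
the total scatter matrix. Selection is greedy: with $p$ variables entered,
a candidate's F-to-enter is

$$F = \frac{n - g - p}{g - 1}\,\Bigl(\frac{\Lambda_p}{\Lambda_{p+1}} - 1\Bigr),
\qquad \mathrm{df} = (g - 1,\; n - g - p),$$

and the candidate with the largest F enters if its p-value is at most
0.05; after each entry, entered variables whose F-to-remove p-value reaches
0.10 are dropped. These probability thresholds (entry 0.05 / removal 0.10)
are the conventional defaults for stepwise Wilks selection. Numerical
guards: candidates with within-group tolerance (1 − R² against the entered
set) below 1e-4 are skipped as collinear; entries stop when the residual
degrees of freedom drop below 2 or after `maxSteps = 10` accepted entries;
exact F ties break towards the lexicographically smallest feature id so
runs are reproducible.

Classification uses Fisher's classification functions,
$b_k = S_w^{-1} m_k$ and $c_k = -\tfrac12 m_k' S_w^{-1} m_k + \log \pi_k$
with $S_w = W/(n-g)$, assigning each sample to the group with the largest
score (ties to the first group level; priors equal by default since the
bulks are balanced 12/12). Three accuracies are reported: *original*
(re-classifying the fitting samples), *cross-validated* (leave-one-out with
the classification functions refit per fold but the feature set frozen —
re-running the stepwise search per fold is a different, more expensive
reading, and the biological-replicate holdout below covers it), and
*holdout*. With 24 samples, every reported percentage is an exact multiple
of 100/24.

`screenCompound()` mirrors the two-stage bulk screening design: stepwise
selection on the first biological replicate (12 points), holdout scoring on
the second, then a second stepwise pass restricted to the stage-one
features but using all 24 points to form the final classification model.

### What stepwise selection can and cannot recover

A point worth stating plainly, because it bounds what a passing test suite
shows: greedy Wilks selection systematically under-recovers *multiple*
equally strong markers for the same compound. Once $k-1$ strong variables
are in, the achieved separation $T^2$ sits in the denominator of every
later partial F; for the $k$-th independent marker of equal strength the
partial F tends to roughly $\mathrm{df}_2/(k-1)$ *regardless of the effect
size*, while the best of ~283 null candidates keeps producing comparable
chance values. Measured on the default synthetic conditions (20 seeds,
delta = 3, 1–4 planted markers per compound), per-compound recall is about
0.95 / 0.52 / 0.40 / 0.30 for 1 / 2 / 3 / 4 planted markers: the screen
reliably finds *a* marker per compound (and its leave-one-out accuracy
averages about 97%), but not *all* markers. The three-criterion
intersection is the guard against the accompanying false entries: its
precision on the same runs is about 0.96. This behaviour is intrinsic to
greedy stepwise selection at n = 24 with hundreds of candidates, not a
tuning artefact.

## Marker filters

Fisher's ratio, $(M_1 - M_2)^2 / (V_1 + V_2)$, ranks features by
univariate bulk separability; the top 10 per compound are retained. The
bulk-contrast t-test uses all 12 data points per bulk, in pooled or Welch
form; from raw replicate values the variant is chosen per feature by a
mean-centred Levene test (pooled when p > 0.05), which reproduces the mixed
integer/fractional degrees of freedom seen in published SPSS output. From
summary statistics alone the caller must pick the variant. Significance for
marker retention is two-sided p < 0.01; no multiple-testing correction is
applied by default — the three-way intersection with the DFA and
Fisher's-ratio sets is the false-positive guard — but a Bonferroni switch
exists. A putative marker must satisfy all three criteria; cross-compound
reports take the union of per-compound intersections, with all seven Venn
region counts exposed.

## Genomic anchoring and SNP validation

Anchors come from 12-column tabular BLAST-style hit files: best hit per
query by E-value (ties by bitscore), significant only when E < 1e-5
(strictly). Coordinates are 1-based inclusive; reversed subject coordinates
are normalised with a "-" strand. Genetic distance converts to physical
windows assuming 100 cM per chromosome:
$\mathrm{window} = (L_{\mathrm{LG}}/100) \times \mathrm{cM}$. Gene lookup
reports every gene on the anchor's linkage group whose nearest edge lies
within the window, with signed offsets (positive = increasing coordinate =
downstream under the default convention).

SNP calling consumes an existing pairwise alignment (equal-length strings
over A/C/G/T/N/-): one call per column with differing non-N characters, N
masking the column, gaps yielding indel calls. Genotype–phenotype
concordance for a biallelic marker classifies a genotype as an expected
high producer iff it carries the high allele (default "T") and scores
agreement against a phenotype threshold of 10% relative composition — any
threshold strictly between the observed low cluster (< 6%) and high cluster
(> 24%) gives identical results, which the tests assert.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested; its defaults are fixed, not tuned per experiment.

**Phenotypes.** 50 F1 individuals, 8 compounds. Each compound value is
Bernoulli(1 − π) × (inherited per-allele locus effects + Gamma noise),
truncated to [0, 100]; inheritance is disomic (each parent transmits an
allele with probability dosage/2 — an approximation for an octoploid crop,
where true allele dosage is unresolved). Parental genotypes are mostly
low-dosage heterozygotes, so distributions come out zero-inflated and
right-skewed with transgressive allele combinations; one compound carries a
single large-effect locus and segregates bimodally. Zero-inflation π ranges
0.15–0.5 across compounds.

**Arrays.** SNR(feature, sample) = exp(μ_f + batch + noise): a log-normal
feature baseline (log-mean log 150, log-SD 1, spanning the one-to-three-digit
SNRs typical of these panels), an optional per-array batch factor, and
technical noise with log-SD 0.35 — chosen to match the within-bulk
coefficients of variation (≈ 0.3–0.5) of published replicated bulk
hybridisations. The batch SD defaults to 0: biological replicates here are
re-hybridisations of the same pooled DNA, and treating the 12 points per
bulk as exchangeable is also what keeps the pooled t-test exactly nominal
under the null; a nonzero batch factor is available but documented to
inflate the t-test's size. Planted markers receive a multiplicative effect
on one bulk (both polarities occur on subtracted arrays) sized so the bulk
mean gap equals δ pooled within-bulk SDs, by solving
$(k-1) = \delta\,\mathrm{CV}\sqrt{(1+k^2)/2}$. Constant-CV multiplicative
noise caps standardised gaps at $\sqrt2/\mathrm{CV}$ (≈ 3.9 at the default
noise); infeasible δ is rejected rather than silently truncated. The
default δ = 3 matches the standardised gaps implied by validated markers in
published group statistics (≈ 2.5–3.7).

**Determinism.** Every consumer draws from its own stream derived from the
master seed by a fixed label, so adding a generator never perturbs existing
draws; fixture bundles are byte-stable for a fixed configuration.

**What passing tests do not show.** The generator emulates independent
features; real panel features are correlated (duplicated clones,
chloroplast sequence families), which changes stepwise behaviour. It plants
clean multiplicative effects, whereas real bulk contrasts also reflect
imperfect bulk composition (a misclassified individual, as seen in marker
validation panels) and hybridisation chemistry. Recovery and calibration
results therefore characterise the statistics of the pipeline, not the
wet-lab platform.

## Problem sizes used by the test suite and acceptance script

The recovery experiment runs 20 seeds × 8 compounds on the full 287 × 24
design; the null calibration runs 50 seeds × 287 features; the stepwise
oracle comparison enumerates 100 instances of up to 8 features. These sizes
give binomial/Monte-Carlo resolution comfortably finer than the thresholds
they are compared against.

## Known limitations

- Greedy stepwise recall for multi-marker compounds saturates (see above);
  treat the DFA model as "at least one marker per trait", and the
  three-criterion intersection as the high-precision call set.
- Only two-group screening is exposed; the Wilks machinery supports g > 2
  but the pipeline does not.
- The Welch test from summary statistics is mildly conservative on skewed
  data at n = 12 (null rejection ≈ 0.8% at α = 1%); the raw-data path with
  Levene-based variant selection is closer to nominal.
- Alignment is consumed, not computed; no octoploid subgenome assignment or
  allele-dosage estimation is attempted.
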