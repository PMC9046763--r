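#' @useDynLib aquaGS, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenotypePanel: SNP dosages with a genome map
#'
#' Container for a biallelic SNP panel coded as alternate-allele dosages.
#' Rows are individuals, columns are SNPs. Dosages are 0, 1, 2 or `NA`
#' (missing); after mean imputation they may be real-valued in `[0, 2]`.
#' The genome map (chromosome and 1-based physical position per SNP) is
#' carried alongside and kept in genome order within each chromosome.
#'
#' @slot dosages numeric matrix, individuals x SNPs, with individual ids as
#'   rownames and SNP ids as colnames.
#' @slot chrom character vector, chromosome name per SNP.
#' @slot pos integer vector, 1-based position per SNP, strictly increasing
#'   within each chromosome.
#'
#' @seealso [GenotypePanel()] for the constructor, [filterSnps()],
#'   [vanRadenGRM()]
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  slots = c(dosages = "matrix", chrom = "character", pos = "integer")
)

setValidity("GenotypePanel", function(object) {
  d <- object@dosages
  msg <- character()
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosages must have individual ids as rownames and SNP ids as colnames")
  else {
    if (anyDuplicated(rownames(d))) msg <- c(msg, "duplicated individual ids")
    if (anyDuplicated(colnames(d))) msg <- c(msg, "duplicated SNP ids")
  }
  if (length(object@chrom) != ncol(d)) msg <- c(msg, "chrom length != number of SNPs")
  if (length(object@pos) != ncol(d)) msg <- c(msg, "pos length != number of SNPs")
  v <- d[!is.na(d)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (length(object@pos) && any(object@pos < 1L, na.rm = TRUE))
    msg <- c(msg, "positions must be >= 1")
  # strictly increasing positions within each chromosome, in map order
  if (length(object@chrom)) {
    for (ch in unique(object@chrom)) {
      p <- object@pos[object@chrom == ch]
      if (length(p) > 1 && any(diff(p) <= 0)) {
        msg <- c(msg, sprintf("positions not strictly increasing on chromosome %s", ch))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' GRM: VanRaden genomic relationship matrix
#'
#' Realized additive relationship matrix \eqn{G = Z Z' / (2 \sum_j p_j (1 - p_j))}
#' where `Z` is the allele-frequency-centered dosage matrix. Symmetric and
#' positive semidefinite up to numerical tolerance.
#'
#' @slot values symmetric numeric matrix, individuals x individuals, with
#'   individual ids as dimnames.
#' @slot denominator the scaling constant \eqn{2 \sum_j p_j(1-p_j)}.
#' @slot alleleFreqs alternate-allele frequencies \eqn{p_j} used for centering.
#'
#' @seealso [vanRadenGRM()]
#' @exportClass GRM
setClass("GRM",
  slots = c(values = "matrix", denominator = "numeric", alleleFreqs = "numeric")
)

setValidity("GRM", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "values must have matching individual-id dimnames")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
  if (length(object@denominator) != 1 || object@denominator <= 0)
    msg <- c(msg, "denominator must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' ModelFit: fitted whole-genome regression model
#'
#' Result of fitting the mixed model `y = Xb + Zu + e` with
#' `u ~ N(0, G sigma_g^2)` (GBLUP) or its marker-effect reparameterisation
#' (Bayesian alphabet models). Stores variance components, narrow-sense
#' heritability `h2 = Vg / (Vg + Ve)` (enforced by validity), fixed effects,
#' genomic breeding values for the training individuals, and, for Bayesian
#' fits, posterior-mean marker effects, inclusion probabilities (BayesB/C)
#' and the training allele frequencies needed to center new genotypes.
#'
#' @slot modelName one of `"GBLUP"`, `"BayesA"`, `"BayesB"`, `"BayesC"`,
#'   `"BayesL"`, `"BayesRR"`.
#' @slot Vg,Ve additive genetic and residual variance (trait units squared).
#' @slot sdVg,sdVe posterior / sampling standard deviations (may be `NA`).
#' @slot h2 narrow-sense heritability.
#' @slot fixedEffects estimated fixed effects (first element the intercept).
#' @slot gebv named numeric vector of breeding values, training individuals.
#' @slot markerEffects posterior-mean per-marker allele substitution effects
#'   (Bayesian models; `NULL` for GBLUP).
#' @slot inclusionProb per-marker posterior inclusion probability
#'   (BayesB/BayesC; `NULL` otherwise).
#' @slot alleleFreqs training allele frequencies (Bayesian models).
#' @slot mcmc list with `iterations`, `burnIn`, `thin`, `seed` (Bayesian) or
#'   optimizer details (GBLUP).
#' @slot boundary logical, `TRUE` when the REML variance-ratio optimum hit
#'   the search boundary.
#'
#' @seealso [fitGBLUP()], [fitBayes()], [predictGebv()]
#' @exportClass ModelFit
setClass("ModelFit",
  slots = c(
    modelName = "character",
    Vg = "numeric", Ve = "numeric", sdVg = "numeric", sdVe = "numeric",
    h2 = "numeric",
    fixedEffects = "numeric",
    gebv = "numeric",
    markerEffects = "numericOrNULL",
    inclusionProb = "numericOrNULL",
    alleleFreqs = "numericOrNULL",
    mcmc = "list",
    boundary = "logical"
  )
)

.MODEL_NAMES <- c("GBLUP", "BayesA", "BayesB", "BayesC", "BayesL", "BayesRR")

setValidity("ModelFit", function(object) {
  msg <- character()
  if (!object@modelName %in% .MODEL_NAMES)
    msg <- c(msg, sprintf("modelName must be one of %s", paste(.MODEL_NAMES, collapse = ", ")))
  if (object@Vg < 0) msg <- c(msg, "Vg must be >= 0")
  if (object@Ve <= 0) msg <- c(msg, "Ve must be > 0")
  if (abs(object@h2 - object@Vg / (object@Vg + object@Ve)) > 1e-12)
    msg <- c(msg, "h2 must equal Vg / (Vg + Ve)")
  if (is.null(names(object@gebv))) msg <- c(msg, "gebv must be named by individual id")
  if (!is.null(object@inclusionProb) &&
      (min(object@inclusionProb) < 0 || max(object@inclusionProb) > 1))
    msg <- c(msg, "inclusionProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GwasResult: per-SNP mixed-model association scan
#'
#' Single-marker association results from the univariate linear mixed model
#' with a genomic relationship matrix controlling structure and relatedness.
#' Per SNP: effect estimate, standard error and Wald p-value; globally:
#' Bonferroni and suggestive thresholds and the genomic-control inflation
#' factor lambda_GC.
#'
#' @slot snps data.frame with columns `id`, `chrom`, `pos`, `beta`, `se`,
#'   `p`, ordered by genome position.
#' @slot nTests number of SNPs tested.
#' @slot bonferroniP genome-wide significance threshold `alpha / nTests`.
#' @slot suggestiveP suggestive threshold `10^-suggestive_neglog10`.
#' @slot lambdaGc median Wald chi-square divided by its null median.
#' @slot nullVarcomp named numeric: `Vg`, `Ve` of the null model.
#'
#' @seealso [lmmGwas()], [candidateWindows()]
#' @exportClass GwasResult
setClass("GwasResult",
  slots = c(
    snps = "data.frame",
    nTests = "integer",
    bonferroniP = "numeric",
    suggestiveP = "numeric",
    lambdaGc = "numeric",
    nullVarcomp = "numeric"
  )
)

setValidity("GwasResult", function(object) {
  msg <- character()
  need <- c("id", "chrom", "pos", "beta", "se", "p")
  if (!all(need %in% names(object@snps)))
    msg <- c(msg, sprintf("snps must have columns %s", paste(need, collapse = ", ")))
  else {
    if (object@nTests != nrow(object@snps)) msg <- c(msg, "nTests must equal nrow(snps)")
    p <- object@snps$p
    if (length(p) && (min(p) <= 0 || max(p) > 1)) msg <- c(msg, "p-values must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' FoldPlan: repeated k-fold cross-validation assignments
#'
#' Fold labels for `nRepeats` independent k-fold partitions of the
#' individuals. Within each repeat the folds partition all individuals and
#' their sizes differ by at most one. The same plan is shared across models
#' so that every model sees identical training/testing splits.
#'
#' @slot assignments integer matrix, repeats x individuals, entries in
#'   `1..k`; colnames are individual ids.
#' @slot k number of folds.
#' @slot baseSeed seed from which each repeat's permutation is derived
#'   (repeat `r` uses `baseSeed + r - 1`).
#'
#' @seealso [makeFolds()], [runCV()]
#' @exportClass FoldPlan
setClass("FoldPlan",
  slots = c(assignments = "matrix", k = "integer", baseSeed = "integer")
)

setValidity("FoldPlan", function(object) {
  a <- object@assignments
  msg <- character()
  if (is.null(colnames(a))) msg <- c(msg, "assignments must have individual ids as colnames")
  k <- object@k
  for (r in seq_len(nrow(a))) {
    tab <- tabulate(a[r, ], nbins = k)
    if (sum(tab) != ncol(a)) { msg <- c(msg, "folds must partition all individuals"); break }
    if (max(tab) - min(tab) > 1L) { msg <- c(msg, "fold sizes must differ by at most 1"); break }
  }
  if (length(msg)) msg else TRUE
})

#' CvReport: cross-validated predictability
#'
#' Per-cell (model x trait x repeat x fold) predictability — the Pearson
#' correlation between predicted breeding values and observed phenotypes in
#' the held-out fold — plus metadata identifying the SNP panel used.
#'
#' @slot cells data.frame with columns `model`, `trait`, `rep`, `fold`, `r`
#'   (and optionally `panelSize`, `strategy`).
#' @slot nFailed number of cells recorded as missing because a fit failed
#'   or a predictability was undefined (zero variance).
#'
#' @seealso [runCV()], [cvSummary()]
#' @exportClass CvReport
setClass("CvReport", slots = c(cells = "data.frame", nFailed = "integer"))

setValidity("CvReport", function(object) {
  msg <- character()
  need <- c("model", "trait", "rep", "fold", "r")
  if (!all(need %in% names(object@cells)))
    msg <- c(msg, sprintf("cells must have columns %s", paste(need, collapse = ", ")))
  else {
    r <- object@cells$r
    if (any(!is.na(r) & (r < -1 | r > 1))) msg <- c(msg, "r must lie in [-1, 1]")
  }
  if (object@nFailed < 0L) msg <- c(msg, "nFailed must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DensityCurve: predictability as a function of SNP panel size
#'
#' Mean and SD of cross-validated predictability at increasing (cumulative,
#' nested) SNP panel sizes under one sampling strategy.
#'
#' @slot strategy one of `"gwas_ranked"`, `"random"`, `"evenly_spaced"`.
#' @slot sizes increasing integer vector of panel sizes.
#' @slot summary data.frame with columns `panelSize`, `mean`, `sd`, `n`.
#' @slot cells per-cell results as in [CvReport-class].
#'
#' @seealso [densityExperiment()], [selectSnps()]
#' @exportClass DensityCurve
setClass("DensityCurve",
  slots = c(strategy = "character", sizes = "integer",
            summary = "data.frame", cells = "data.frame")
)

setValidity("DensityCurve", function(object) {
  msg <- character()
  if (!object@strategy %in% c("gwas_ranked", "random", "evenly_spaced"))
    msg <- c(msg, "unknown strategy")
  if (length(object@sizes) > 1 && any(diff(object@sizes) <= 0))
    msg <- c(msg, "sizes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' SimConfig: synthetic-population configuration
#'
#' Parameters of the synthetic breeding-population generator. Defaults
#' emulate a marine finfish breeding cohort: 455 individuals genotyped at
#' 16,162 SNPs on 24 pseudo-chromosomes (MAF 0.05–0.5), three correlated
#' polygenic growth traits (body weight, total length, body depth) with
#' narrow-sense heritabilities 0.38 / 0.33 / 0.24 and phenotypic
#' correlations 0.88 / 0.85 / 0.81.
#'
#' @slot nIndividuals,nSnps,nChromosomes,chromLengthBp,nQtl counts.
#' @slot mafRange allele-frequency sampling range, within `(0, 0.5]`.
#' @slot heritabilities per-trait narrow-sense heritability targets.
#' @slot traitMeans,traitSds per-trait phenotypic mean and SD targets.
#' @slot geneticCorrelation,phenotypicCorrelation trait correlation
#'   matrices (symmetric, unit diagonal, positive semidefinite);
#'   `phenotypicCorrelation` may be a 0 x 0 matrix, in which case the
#'   environmental correlation defaults to the genetic one.
#' @slot missingRate fraction of dosages set missing (default 0).
#' @slot ldRho copying probability of the haplotype-copying LD mode
#'   (0 = linkage equilibrium, the default).
#' @slot seed integer seed; the generator is deterministic given the config.
#'
#' @seealso [simConfig()], [simulateGenotypes()], [simulatePhenotypes()]
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(
    nIndividuals = "integer", nSnps = "integer", nChromosomes = "integer",
    chromLengthBp = "integer", mafRange = "numeric", nQtl = "integer",
    heritabilities = "numeric", traitNames = "character",
    traitMeans = "numeric", traitSds = "numeric",
    geneticCorrelation = "matrix", phenotypicCorrelation = "matrix",
    missingRate = "numeric", ldRho = "numeric", seed = "integer"
  )
)

.checkCorrMatrix <- function(m, what) {
  msg <- character()
  if (nrow(m) != ncol(m)) return(sprintf("%s must be square", what))
  if (max(abs(m - t(m))) > 1e-10) msg <- c(msg, sprintf("%s must be symmetric", what))
  if (max(abs(diag(m) - 1)) > 1e-10) msg <- c(msg, sprintf("%s must have unit diagonal", what))
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    msg <- c(msg, sprintf("%s must be positive semidefinite", what))
  msg
}

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (object@nChromosomes < 1L || object@nChromosomes > object@nSnps)
    msg <- c(msg, "nChromosomes must be in [1, nSnps]")
  mr <- object@mafRange
  if (length(mr) != 2 || mr[1] > mr[2] || mr[1] <= 0 || mr[2] > 0.5)
    msg <- c(msg, "mafRange must be low <= high within (0, 0.5]")
  if (object@nQtl > object@nSnps) msg <- c(msg, "nQtl must be <= nSnps")
  h2 <- object@heritabilities
  if (any(h2 < 0 | h2 > 1)) msg <- c(msg, "heritabilities must lie in [0, 1]")
  if (any(h2 > 0) && object@nQtl < 1L)
    msg <- c(msg, "nQtl must be >= 1 when any heritability is > 0")
  nt <- length(h2)
  if (length(object@traitMeans) != nt || length(object@traitSds) != nt ||
      length(object@traitNames) != nt)
    msg <- c(msg, "traitNames / traitMeans / traitSds must match the number of traits")
  g <- object@geneticCorrelation
  if (!all(dim(g) == nt)) msg <- c(msg, "geneticCorrelation dimension must match traits")
  else msg <- c(msg, .checkCorrMatrix(g, "geneticCorrelation"))
  p <- object@phenotypicCorrelation
  if (nrow(p) > 0) {
    if (!all(dim(p) == nt)) msg <- c(msg, "phenotypicCorrelation dimension must match traits")
    else msg <- c(msg, .checkCorrMatrix(p, "phenotypicCorrelation"))
  }
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (object@ldRho < 0 || object@ldRho >= 1) msg <- c(msg, "ldRho must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' SimTruth: simulation ground truth
#'
#' True per-allele substitution effects, true breeding values and realized
#' heritabilities of a simulated population, for parameter-recovery tests.
#'
#' @slot trueEffects matrix nSnps x nTraits; rows are zero for non-QTL SNPs.
#' @slot trueBreedingValues matrix nIndividuals x nTraits.
#' @slot realizedH2 per-trait realized `Var(g) / Var(y)`.
#' @slot qtlIndices indices of the causal SNPs.
#'
#' @seealso [simulatePhenotypes()]
#' @exportClass SimTruth
setClass("SimTruth",
  slots = c(trueEffects = "matrix", trueBreedingValues = "matrix",
            realizedH2 = "numeric", qtlIndices = "integer")
)

setValidity("SimTruth", function(object) {
  msg <- character()
  if (any(object@realizedH2 < 0 | object@realizedH2 > 1))
    msg <- c(msg, "realizedH2 must lie in [0, 1]")
  nonqtl <- setdiff(seq_len(nrow(object@trueEffects)), object@qtlIndices)
  if (length(nonqtl) && any(object@trueEffects[nonqtl, ] != 0))
    msg <- c(msg, "trueEffects must be zero for non-QTL SNPs")
  if (length(msg)) msg else TRUE
})

#' QcReport: quality-control accounting
#'
#' Counts of individuals and SNPs removed by each quality-control step,
#' together with the thresholds used. Counts reconcile exactly with the
#' dimension changes of the panel.
#'
#' @slot nIndividualsRemoved,nSnpsRemovedCallrate,nSnpsRemovedMaf,nSnpsRemovedPrune counts.
#' @slot thresholds named numeric vector of the thresholds applied.
#'
#' @seealso [filterIndividuals()], [filterSnps()], [pruneTagSnps()]
#' @exportClass QcReport
setClass("QcReport",
  slots = c(
    nIndividualsRemoved = "integer", nSnpsRemovedCallrate = "integer",
    nSnpsRemovedMaf = "integer", nSnpsRemovedPrune = "integer",
    thresholds = "numeric"
  )
)

setValidity("QcReport", function(object) {
  counts <- c(object@nIndividualsRemoved, object@nSnpsRemovedCallrate,
              object@nSnpsRemovedMaf, object@nSnpsRemovedPrune)
  if (any(counts < 0L)) "counts must be non-negative" else TRUE
})
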