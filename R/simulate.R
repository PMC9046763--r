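#' Configure the synthetic breeding-population generator
#'
#' Returns a validated [SimConfig-class]. The defaults emulate a marine
#' finfish breeding cohort genotyped by reduced-representation sequencing:
#' 455 individuals at 16,162 biallelic SNPs on 24 pseudo-chromosomes with
#' MAF in `[0.05, 0.5]`, and three correlated polygenic growth traits —
#' body weight (g), total length (cm) and body depth (cm) — with target
#' narrow-sense heritabilities 0.38 / 0.33 / 0.24, genetic correlations
#' 0.88 / 0.79 / 0.76 and phenotypic correlations 0.88 / 0.85 / 0.81.
#'
#' @param nIndividuals,nSnps,nChromosomes panel dimensions.
#' @param chromLengthBp length of each pseudo-chromosome in bp.
#' @param mafRange range from which per-SNP allele frequencies are drawn
#'   uniformly; must lie in `(0, 0.5]`.
#' @param nQtl number of causal SNPs; defaults to `nSnps / 4` (polygenic).
#' @param heritabilities per-trait target narrow-sense heritabilities.
#' @param traitMeans,traitSds per-trait phenotypic mean and SD.
#' @param geneticCorrelation correlation matrix of QTL effects across traits.
#' @param phenotypicCorrelation target phenotypic correlation matrix; the
#'   environmental covariance is solved to meet it. `NULL` uses the genetic
#'   correlation for the environmental deviations as well.
#' @param missingRate fraction of dosages masked as missing (QC testing).
#' @param ldRho haplotype-copying probability creating decaying LD between
#'   adjacent SNPs; 0 (default) gives linkage equilibrium.
#' @param seed integer seed making the generator deterministic.
#' @return a [SimConfig-class].
#' @examples
#' cfg <- simConfig(nIndividuals = 100, nSnps = 500, seed = 1)
#' @export
simConfig <- function(nIndividuals = 455L, nSnps = 16162L, nChromosomes = 24L,
                      chromLengthBp = 30000000L,
                      mafRange = c(0.05, 0.5),
                      nQtl = NULL,
                      heritabilities = c(BW = 0.38, TL = 0.33, BD = 0.24),
                      traitMeans = c(BW = 130.71, TL = 18.12, BD = 7.07),
                      traitSds = c(BW = 32.88, TL = 1.41, BD = 0.59),
                      geneticCorrelation = NULL,
                      phenotypicCorrelation = NULL,
                      missingRate = 0, ldRho = 0, seed = 1L) {
  nt <- length(heritabilities)
  if (is.null(nQtl)) nQtl <- max(1L, as.integer(round(nSnps / 4)))
  if (is.null(geneticCorrelation)) {
    geneticCorrelation <- if (nt == 3) {
      matrix(c(1, 0.88, 0.79, 0.88, 1, 0.76, 0.79, 0.76, 1), 3, 3)
    } else diag(nt)
  }
  if (is.null(phenotypicCorrelation) && nt == 3) {
    phenotypicCorrelation <- matrix(c(1, 0.88, 0.85, 0.88, 1, 0.81, 0.85, 0.81, 1), 3, 3)
  }
  if (is.null(phenotypicCorrelation)) {
    phenotypicCorrelation <- matrix(numeric(), 0, 0)
  }
  if (length(traitMeans) == 1L && nt > 1L) traitMeans <- rep(traitMeans, nt)
  if (length(traitSds) == 1L && nt > 1L) traitSds <- rep(traitSds, nt)
  traitNames <- names(heritabilities)
  if (is.null(traitNames)) {
    traitNames <- if (nt == 3) c("BW", "TL", "BD") else sprintf("trait_%d", seq_len(nt))
  }
  new("SimConfig",
      nIndividuals = as.integer(nIndividuals), nSnps = as.integer(nSnps),
      nChromosomes = as.integer(nChromosomes),
      chromLengthBp = as.integer(chromLengthBp),
      mafRange = as.numeric(mafRange), nQtl = as.integer(nQtl),
      heritabilities = as.numeric(heritabilities), traitNames = traitNames,
      traitMeans = as.numeric(traitMeans), traitSds = as.numeric(traitSds),
      geneticCorrelation = geneticCorrelation,
      phenotypicCorrelation = phenotypicCorrelation,
      missingRate = as.numeric(missingRate), ldRho = as.numeric(ldRho),
      seed = as.integer(seed))
}

.traitNames <- function(cfg) cfg@traitNames

#' Simulate a genotype panel
#'
#' Draws per-SNP alternate-allele frequencies uniformly on `mafRange` and
#' genotype dosages as `Binomial(2, p_j)` (Hardy–Weinberg sampling). SNPs
#' are distributed near-evenly over the chromosomes with sorted, distinct
#' positions. With `ldRho > 0`, haplotype alleles copy the previous SNP's
#' allele with probability `ldRho`, producing LD that decays geometrically
#' with marker distance (used to exercise tag-SNP pruning).
#'
#' @param cfg a [SimConfig-class].
#' @return a [GenotypePanel-class]; deterministic given `cfg@seed`. The
#'   drawn per-SNP frequencies are attached as attribute `"trueFreqs"`.
#' @examples
#' panel <- simulateGenotypes(simConfig(nIndividuals = 50, nSnps = 100, seed = 7))
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  withr_seed <- .withSeed(cfg@seed)
  on.exit(withr_seed())

  n <- cfg@nIndividuals; m <- cfg@nSnps; nchr <- cfg@nChromosomes
  p <- stats::runif(m, cfg@mafRange[1], cfg@mafRange[2])

  # near-even split of SNPs over chromosomes, distinct sorted positions
  chromOf <- sort(rep_len(seq_len(nchr), m))
  pos <- integer(m)
  for (ch in seq_len(nchr)) {
    idx <- which(chromOf == ch)
    pos[idx] <- sort(sample.int(cfg@chromLengthBp, length(idx)))
  }

  if (cfg@ldRho > 0) {
    # two haplotypes per individual; allele copied from previous SNP w.p. ldRho
    h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      fresh1 <- stats::rbinom(n, 1L, p[j]); fresh2 <- stats::rbinom(n, 1L, p[j])
      if (j > 1L && chromOf[j] == chromOf[j - 1L]) {
        keep1 <- stats::runif(n) < cfg@ldRho
        keep2 <- stats::runif(n) < cfg@ldRho
        h1[, j] <- ifelse(keep1, h1[, j - 1L], fresh1)
        h2[, j] <- ifelse(keep2, h2[, j - 1L], fresh2)
      } else {
        h1[, j] <- fresh1; h2[, j] <- fresh2
      }
    }
    d <- h1 + h2
  } else {
    d <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  }
  storage.mode(d) <- "double"

  if (cfg@missingRate > 0) {
    d[stats::runif(n * m) < cfg@missingRate] <- NA_real_
  }

  rownames(d) <- sprintf("ind_%03d", seq_len(n))
  colnames(d) <- sprintf("snp_%05d", seq_len(m))
  panel <- GenotypePanel(d, chrom = as.character(chromOf), pos = pos)
  attr(panel, "trueFreqs") <- p
  panel
}

#' Simulate correlated polygenic phenotypes
#'
#' Generates phenotypes under the additive model `y = mu + g + e` with
#' `g = Z alpha` on centered dosages. QTL effects are drawn multivariate
#' normal across traits with the configured genetic correlation, then each
#' trait's genetic values are scaled so the realized genetic variance equals
#' `h2 * traitSd^2` exactly; environmental deviations are multivariate
#' normal with covariance solved so the phenotypic covariance meets the
#' configured phenotypic correlation in expectation.
#'
#' @param panel a complete (no missing) [GenotypePanel-class].
#' @param cfg the [SimConfig-class] used to generate it (supplies trait
#'   architecture and the seed; phenotype draws use `seed + 1`).
#' @return list with `phenotypes` (data.frame: `id` plus one column per
#'   trait) and `truth` (a [SimTruth-class]).
#' @examples
#' cfg <- simConfig(nIndividuals = 60, nSnps = 200, nQtl = 50, seed = 3)
#' sim <- simulatePhenotypes(simulateGenotypes(cfg), cfg)
#' head(sim$phenotypes)
#' @export
simulatePhenotypes <- function(panel, cfg) {
  stopifnot(is(panel, "GenotypePanel"), is(cfg, "SimConfig"))
  d <- dosages(panel)
  if (anyNA(d)) stop("panel has missing dosages; impute or simulate without missingness")
  n <- nrow(d); m <- ncol(d)
  nt <- length(cfg@heritabilities)
  h2 <- cfg@heritabilities
  sds <- cfg@traitSds
  restore <- .withSeed(cfg@seed + 1L)
  on.exit(restore())

  Zc <- scale(d, center = TRUE, scale = FALSE)

  qtl <- sort(sample.int(m, cfg@nQtl))
  # correlated raw effects across traits
  L <- .cholPsd(cfg@geneticCorrelation)
  eff <- matrix(stats::rnorm(cfg@nQtl * nt), cfg@nQtl, nt) %*% t(L)

  gmat <- Zc[, qtl, drop = FALSE] %*% eff
  trueEffects <- matrix(0, m, nt,
                        dimnames = list(colnames(d), .traitNames(cfg)))
  # per-trait scaling so realized Var(g) = h2 * sd^2 exactly
  for (t in seq_len(nt)) {
    vg_target <- h2[t] * sds[t]^2
    vg_now <- stats::var(gmat[, t])
    sc <- if (vg_now > 0 && vg_target > 0) sqrt(vg_target / vg_now) else 0
    gmat[, t] <- gmat[, t] * sc
    trueEffects[qtl, t] <- eff[, t] * sc
  }

  # environmental covariance: phenotypic target minus realized genetic cov
  ve <- (1 - h2) * sds^2
  if (nrow(cfg@phenotypicCorrelation) > 0) {
    sigmaP <- cfg@phenotypicCorrelation * tcrossprod(sds)
    sigmaE <- sigmaP - stats::cov(gmat)
    diag(sigmaE) <- ve
  } else {
    sigmaE <- cfg@geneticCorrelation * tcrossprod(sqrt(ve))
  }
  ev <- eigen((sigmaE + t(sigmaE)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    off <- abs(sigmaE); diag(off) <- -Inf
    bad <- which(off == max(off), arr.ind = TRUE)[1, ]
    tn <- .traitNames(cfg)
    stop(sprintf(paste0("implied environmental covariance is not positive ",
                        "semidefinite; the phenotypic correlation target for ",
                        "traits %s and %s is infeasible given the genetic ",
                        "correlation and heritabilities"),
                 tn[bad[1]], tn[bad[2]]))
  }
  Le <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nt) %*% t(ev$vectors)
  emat <- matrix(stats::rnorm(n * nt), n, nt) %*% Le

  y <- sweep(gmat + emat, 2, cfg@traitMeans, "+")
  # h2 = 1 traits: phenotype is exactly mean + g
  exact <- h2 >= 1 - 1e-12
  if (any(exact)) y[, exact] <- sweep(gmat[, exact, drop = FALSE], 2,
                                      cfg@traitMeans[exact], "+")

  vary <- apply(y, 2, stats::var)
  varg <- apply(gmat, 2, stats::var)
  realized <- ifelse(vary > 0, pmin(1, pmax(0, varg / vary)), 0)

  phen <- data.frame(id = rownames(d), y, stringsAsFactors = FALSE)
  names(phen) <- c("id", .traitNames(cfg))
  truth <- new("SimTruth",
               trueEffects = trueEffects,
               trueBreedingValues = `dimnames<-`(gmat, list(rownames(d), .traitNames(cfg))),
               realizedH2 = as.numeric(realized),
               qtlIndices = as.integer(qtl))
  list(phenotypes = phen, truth = truth)
}

# PSD-tolerant Cholesky-like factor (handles singular correlation matrices)
.cholPsd <- function(m) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(m)) %*% t(ev$vectors)
}

# run code under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
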