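# Shared fixtures: everything is generated in code, at fixed seeds.

# tiny hand-built panel from an explicit dosage matrix
panelFromMatrix <- function(d, chrom = NULL, pos = NULL) {
  d <- as.matrix(d)
  dimnames(d) <- NULL  # let the constructor assign ind_*/snp_* ids
  if (is.null(chrom)) chrom <- rep("1", ncol(d))
  if (is.null(pos)) pos <- seq_len(ncol(d)) * 100L
  GenotypePanel(d, chrom = chrom, pos = pos)
}

# one-trait synthetic population: panel + named phenotype + truth
simFixture <- function(n = 200, m = 400, h2 = 0.4, nQtl = max(5, m %/% 4),
                       seed = 1, maf = c(0.05, 0.5), ldRho = 0) {
  cfg <- simConfig(nIndividuals = n, nSnps = m, nChromosomes = 4L,
                   nQtl = nQtl, mafRange = maf, ldRho = ldRho,
                   heritabilities = c(y = h2), traitMeans = 0, traitSds = 1,
                   geneticCorrelation = matrix(1, 1, 1),
                   phenotypicCorrelation = matrix(1, 1, 1), seed = seed)
  panel <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(panel, cfg)
  y <- sim$phenotypes$y
  names(y) <- sim$phenotypes$id
  list(panel = panel, y = y, truth = sim$truth, cfg = cfg)
}

# independent dense restricted log-likelihood for the GBLUP oracle:
# no eigendecomposition shortcut, straight determinants
denseRestrictedLL <- function(kappa, y, G, Xmat) {
  n <- length(y)
  V <- kappa * G + diag(n)
  Vi <- solve(V)
  XtViX <- t(Xmat) %*% Vi %*% Xmat
  beta <- solve(XtViX, t(Xmat) %*% Vi %*% y)
  r <- y - Xmat %*% beta
  q <- drop(t(r) %*% Vi %*% r)
  np <- n - ncol(Xmat)
  s2e <- q / np
  as.numeric(-0.5 * (np * log(s2e) + determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus + np))
}

# closed-form per-marker OLS Wald p-values (intercept + one SNP)
olsWaldP <- function(y, d) {
  n <- length(y)
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    if (stats::sd(x) == 0) return(1)
    fitX <- cbind(1, x)
    XtX <- crossprod(fitX)
    b <- solve(XtX, crossprod(fitX, y))
    r <- y - fitX %*% b
    s2 <- sum(r^2) / (n - 2)
    se <- sqrt(s2 * solve(XtX)[2, 2])
    stats::pchisq((b[2] / se)^2, df = 1, lower.tail = FALSE)
  }, numeric(1))
}
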