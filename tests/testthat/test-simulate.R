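test_that("genotype draws follow the configured allele frequencies", {
  # symmetric case: p = 0.5 for a single SNP
  cfg <- simConfig(nIndividuals = 2000, nSnps = 1, nChromosomes = 1,
                   mafRange = c(0.5, 0.5), nQtl = 1,
                   heritabilities = c(y = 0.5), traitMeans = 0, traitSds = 1,
                   geneticCorrelation = matrix(1, 1, 1),
                   phenotypicCorrelation = matrix(1, 1, 1), seed = 4)
  panel <- simulateGenotypes(cfg)
  expect_lt(abs(mean(dosages(panel)) - 1.0), 0.05)

  # observed frequencies track the drawn p_j within binomial sampling error
  cfg2 <- simConfig(nIndividuals = 500, nSnps = 200, nChromosomes = 4,
                    nQtl = 50, heritabilities = c(y = 0.5),
                    traitMeans = 0, traitSds = 1,
                    geneticCorrelation = matrix(1, 1, 1),
                    phenotypicCorrelation = matrix(1, 1, 1), seed = 5)
  panel2 <- simulateGenotypes(cfg2)
  pTrue <- attr(panel2, "trueFreqs")
  pObs <- colMeans(dosages(panel2)) / 2
  expect_gte(mean(abs(pObs - pTrue) <= 0.06), 0.95)
})

test_that("the generator is deterministic given the config seed", {
  cfg <- simConfig(nIndividuals = 60, nSnps = 120, nChromosomes = 3,
                   nQtl = 30, seed = 9)
  p1 <- simulateGenotypes(cfg)
  p2 <- simulateGenotypes(cfg)
  expect_identical(dosages(p1), dosages(p2))
  s1 <- simulatePhenotypes(imputeMissing(p1), cfg)
  s2 <- simulatePhenotypes(imputeMissing(p2), cfg)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth@trueEffects, s2$truth@trueEffects)
})

test_that("panel structure: chromosomes, sorted positions, missing-rate knob", {
  cfg <- simConfig(nIndividuals = 40, nSnps = 100, nChromosomes = 5,
                   nQtl = 10, missingRate = 0.1, seed = 2)
  panel <- simulateGenotypes(cfg)
  map <- snpMap(panel)
  expect_equal(length(unique(map$chrom)), 5)
  for (ch in unique(map$chrom)) {
    expect_true(all(diff(map$pos[map$chrom == ch]) > 0))
  }
  miss <- mean(is.na(dosages(panel)))
  expect_gt(miss, 0.05)
  expect_lt(miss, 0.15)
})

test_that("heritability boundaries behave exactly", {
  fx0 <- simFixture(n = 455, m = 300, h2 = 0, nQtl = 50, seed = 3)
  expect_true(all(fx0$truth@trueBreedingValues == 0))
  expect_equal(fx0$truth@realizedH2, 0)

  fx1 <- simFixture(n = 100, m = 300, h2 = 1, nQtl = 50, seed = 3)
  g <- unname(drop(fx1$truth@trueBreedingValues))
  expect_equal(unname(fx1$y), g + fx1$cfg@traitMeans, tolerance = 1e-12)
  expect_equal(fx1$truth@realizedH2, 1)
})

test_that("realized heritability concentrates on the target", {
  # Monte-Carlo: Var(g)/Var(y) across replicate populations
  h2s <- vapply(1:20, function(s) {
    simFixture(n = 455, m = 500, h2 = 0.38, nQtl = 125, seed = 100 + s)$truth@realizedH2
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.38), 0.04)

  big <- simFixture(n = 2000, m = 500, h2 = 0.38, nQtl = 125, seed = 77)
  expect_lt(abs(big$truth@realizedH2 - 0.38), 0.03)
})

test_that("cross-trait structure of breeding values matches the request", {
  base <- list(nIndividuals = 2000, nSnps = 600, nChromosomes = 6,
               nQtl = 150, traitMeans = c(0, 0), traitSds = c(1, 1))
  # identity genetic correlation -> independent breeding values
  cfgI <- do.call(simConfig, c(base, list(
    heritabilities = c(a = 0.4, b = 0.4),
    geneticCorrelation = diag(2), phenotypicCorrelation = diag(2), seed = 21)))
  simI <- simulatePhenotypes(simulateGenotypes(cfgI), cfgI)
  expect_lt(abs(cor(simI$truth@trueBreedingValues)[1, 2]), 0.08)

  # requested genetic correlation recovered
  gc <- matrix(c(1, 0.8, 0.8, 1), 2)
  cfgC <- do.call(simConfig, c(base, list(
    heritabilities = c(a = 0.4, b = 0.4),
    geneticCorrelation = gc, phenotypicCorrelation = gc, seed = 22)))
  simC <- simulatePhenotypes(simulateGenotypes(cfgC), cfgC)
  expect_lt(abs(cor(simC$truth@trueBreedingValues)[1, 2] - 0.8), 0.08)
})

test_that("default three-trait config reproduces the emulated cohort's structure", {
  cfg <- simConfig(nIndividuals = 455, nSnps = 1500, nChromosomes = 24,
                   nQtl = 375, seed = 31)
  sim <- simulatePhenotypes(simulateGenotypes(cfg), cfg)
  ph <- sim$phenotypes
  expect_named(ph, c("id", "BW", "TL", "BD"))
  expect_lt(abs(mean(ph$BW) - 130.71), 5)
  expect_lt(abs(sd(ph$TL) - 1.41), 0.3)
  pc <- cor(as.matrix(ph[, -1]))
  expect_lt(abs(pc[1, 2] - 0.88), 0.08)
  expect_lt(abs(pc[1, 3] - 0.85), 0.08)
  expect_lt(abs(pc[2, 3] - 0.81), 0.08)
  expect_lt(max(abs(sim$truth@realizedH2 - c(0.38, 0.33, 0.24))), 0.08)
})

test_that("configuration errors are caught by name", {
  expect_error(simConfig(mafRange = c(0.2, 0.6), nSnps = 10, nIndividuals = 5,
                         nChromosomes = 1),
               "mafRange")
  badG <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(simConfig(nIndividuals = 10, nSnps = 10, nChromosomes = 1,
                         heritabilities = c(0.4, 0.4), traitMeans = c(0, 0),
                         traitSds = c(1, 1), geneticCorrelation = badG),
               "positive semidefinite")
  # infeasible phenotypic target: env covariance would need corr > 1
  cfg <- simConfig(nIndividuals = 50, nSnps = 100, nChromosomes = 1, nQtl = 20,
                   heritabilities = c(a = 0.9, b = 0.9), traitMeans = c(0, 0),
                   traitSds = c(1, 1),
                   geneticCorrelation = matrix(c(1, -0.9, -0.9, 1), 2),
                   phenotypicCorrelation = matrix(c(1, 0.95, 0.95, 1), 2),
                   seed = 1)
  expect_error(simulatePhenotypes(simulateGenotypes(cfg), cfg),
               "infeasible")
})

test_that("ld_blocks mode creates decaying LD absent under equilibrium", {
  cfgLD <- simConfig(nIndividuals = 300, nSnps = 100, nChromosomes = 1,
                     nQtl = 10, ldRho = 0.9, seed = 12)
  dLD <- dosages(simulateGenotypes(cfgLD))
  r2adj <- mean(vapply(1:99, function(j) cor(dLD[, j], dLD[, j + 1])^2,
                       numeric(1)), na.rm = TRUE)
  cfgLE <- simConfig(nIndividuals = 300, nSnps = 100, nChromosomes = 1,
                     nQtl = 10, ldRho = 0, seed = 12)
  dLE <- dosages(simulateGenotypes(cfgLE))
  r2adjLE <- mean(vapply(1:99, function(j) cor(dLE[, j], dLE[, j + 1])^2,
                         numeric(1)), na.rm = TRUE)
  expect_gt(r2adj, 0.5)
  expect_lt(r2adjLE, 0.1)
})
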