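test_that("individual call-rate filter removes exactly the low-call individuals", {
  d <- rbind(c(0, 1, 2, 1, 0),            # call rate 1.0
             c(0, 1, NA, 1, 0),           # 0.8... make 0.95-ish via 20 SNPs
             c(NA, NA, 2, 1, 0))
  # explicit call rates {1.0, 0.95, 0.80} on 20 SNPs
  d20 <- cbind(matrix(1, 3, 15), rbind(rep(0, 5), c(NA, 0, 0, 0, 0),
                                       c(NA, NA, NA, NA, 0)))
  panel <- panelFromMatrix(d20)
  res <- filterIndividuals(panel, 0.9)
  expect_equal(nIndividuals(res$panel), 2)
  expect_equal(res$report@nIndividualsRemoved, 1L)
  expect_identical(individualIds(res$panel), individualIds(panel)[1:2])

  # no missing data: identity at any threshold
  full <- panelFromMatrix(matrix(c(0, 1, 2, 1), 2))
  expect_identical(dosages(filterIndividuals(full, 1)$panel), dosages(full))

  # threshold 1.0 with one missing call everywhere: empty-panel error
  dAll <- matrix(1, 3, 4); dAll[, 1] <- NA
  expect_error(filterIndividuals(panelFromMatrix(dAll), 1.0),
               "all individuals removed")
})

test_that("SNP filter applies call-rate and MAF exclusion with boundary kept", {
  set.seed(1)
  n <- 100
  d <- cbind(rbinom(n, 2, 0.01), rbinom(n, 2, 0.05), rbinom(n, 2, 0.2),
             rbinom(n, 2, 0.5))
  # force exact MAFs {0.01, 0.05, 0.20, 0.50}
  mk <- function(maf) c(rep(1, round(2 * n * maf)), rep(0, n - round(2 * n * maf)))
  d <- cbind(mk(0.01), mk(0.05), mk(0.20), mk(0.50))
  panel <- panelFromMatrix(d)
  expect_equal(unname(snpMaf(panel)), c(0.01, 0.05, 0.20, 0.50))
  res <- filterSnps(panel, minMaf = 0.05)
  expect_equal(nSnps(res$panel), 3)          # MAF = 0.05 boundary is kept
  expect_equal(res$report@nSnpsRemovedMaf, 1L)

  # monomorphic SNP always removed
  mono <- panelFromMatrix(cbind(rep(0, 10), rep(1, 10) * 0 + c(rep(0, 5), rep(1, 5))))
  expect_equal(nSnps(filterSnps(mono, minMaf = 0.01)$panel), 1)

  # complete, common SNPs: identity
  ok <- panelFromMatrix(cbind(mk(0.3), mk(0.4)))
  expect_identical(dosages(filterSnps(ok)$panel), dosages(ok))
  expect_error(filterSnps(panelFromMatrix(cbind(mk(0.01)))), "no SNPs survive")
})

test_that("mean imputation fills missing dosages with the SNP mean", {
  panel <- panelFromMatrix(matrix(c(0, 2, NA, 1, 1, 1), 3))
  imp <- imputeMissing(panel)
  expect_equal(dosages(imp)[3, 1], 1.0)
  expect_false(anyNA(dosages(imp)))

  # untouched when complete
  full <- panelFromMatrix(matrix(c(0, 1, 2, 1), 2))
  expect_identical(dosages(imputeMissing(full)), dosages(full))

  # all-missing SNP is an error naming the SNP
  bad <- panelFromMatrix(cbind(c(1, 0, 1), c(NA, NA, NA)))
  expect_error(imputeMissing(bad), "snp_2")
})

test_that("tag-SNP pruning drops within-window high-r2 markers only", {
  set.seed(2)
  x <- rbinom(120, 2, 0.4)
  dup <- panelFromMatrix(cbind(x, x, rbinom(120, 2, 0.4)))
  res <- pruneTagSnps(dup, r2Threshold = 0.8, windowSnps = 10)
  expect_equal(nSnps(res$panel), 2)          # exact duplicate dropped
  expect_identical(snpIds(res$panel), c("snp_1", "snp_3"))
  expect_equal(res$report@nSnpsRemovedPrune, 1L)

  # linkage equilibrium: almost everything survives
  fx <- simFixture(n = 500, m = 200, seed = 6)
  le <- pruneTagSnps(fx$panel, r2Threshold = 0.8, windowSnps = 50)
  expect_gte(nSnps(le$panel) / 200, 0.95)

  # r2 threshold 1 with no duplicates: identity
  uni <- pruneTagSnps(fx$panel, r2Threshold = 1.0, windowSnps = 50)
  expect_equal(nSnps(uni$panel), 200)
})

test_that("QC filters are idempotent and reports reconcile with dimensions", {
  cfg <- simConfig(nIndividuals = 80, nSnps = 150, nChromosomes = 3,
                   nQtl = 30, mafRange = c(0.02, 0.5), missingRate = 0.08,
                   seed = 13)
  panel <- simulateGenotypes(cfg)

  f1 <- filterIndividuals(panel, 0.9)
  f1b <- filterIndividuals(f1$panel, 0.9)
  expect_identical(dosages(f1b$panel), dosages(f1$panel))
  expect_equal(f1$report@nIndividualsRemoved,
               nIndividuals(panel) - nIndividuals(f1$panel))

  f2 <- filterSnps(f1$panel, 0.9, 0.05)
  f2b <- filterSnps(f2$panel, 0.9, 0.05)
  expect_identical(dosages(f2b$panel), dosages(f2$panel))
  expect_equal(f2$report@nSnpsRemovedCallrate + f2$report@nSnpsRemovedMaf,
               nSnps(f1$panel) - nSnps(f2$panel))

  imp <- imputeMissing(f2$panel)
  f3 <- pruneTagSnps(imp, 0.8, 50)
  f3b <- pruneTagSnps(f3$panel, 0.8, 50)
  expect_identical(dosages(f3b$panel), dosages(f3$panel))

  # the pipeline wrapper reproduces the same chained result
  qc <- runQc(panel, prune = TRUE)
  expect_identical(dosages(qc$panel), dosages(f3$panel))
  expect_equal(qc$report@nSnpsRemovedPrune, f3$report@nSnpsRemovedPrune)
})
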