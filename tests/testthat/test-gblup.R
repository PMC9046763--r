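test_that("heritability identity is exact and guarded", {
  expect_equal(heritability(1, 1), 0.5)
  expect_equal(heritability(1, 0), 1.0)
  expect_equal(heritability(0, 1), 0.0)
  expect_error(heritability(0, 0), "Vg \\+ Ve")
  expect_error(heritability(-1, 1), "non-negative")
})

test_that("REML matches a brute-force grid search of the restricted likelihood", {
  fx <- simFixture(n = 80, m = 150, h2 = 0.5, nQtl = 40, seed = 16)
  g <- vanRadenGRM(fx$panel)
  fit <- fitGBLUP(fx$y, g)

  # independent dense-likelihood oracle on a kappa grid of spacing 1e-3
  G <- as.matrix(g)[names(fx$y), names(fx$y)]
  X <- matrix(1, length(fx$y), 1)
  grid <- seq(0.001, 5, by = 0.001)
  ll <- vapply(grid, denseRestrictedLL, numeric(1), y = fx$y, G = G, Xmat = X)
  kappaGrid <- grid[which.max(ll)]
  kappaFit <- fit@Vg / fit@Ve
  expect_equal(kappaFit, kappaGrid, tolerance = 2e-3)
  # and the eigendecomposition likelihood agrees with the dense one
  expect_equal(fit@mcmc$restrictedLL,
               as.numeric(denseRestrictedLL(kappaFit, fx$y, G, X)),
               tolerance = 1e-6)
})

test_that("GBLUP is location-invariant in the phenotype", {
  fx <- simFixture(n = 120, m = 200, h2 = 0.4, nQtl = 60, seed = 17)
  g <- vanRadenGRM(fx$panel)
  f1 <- fitGBLUP(fx$y, g)
  f2 <- fitGBLUP(fx$y + 100, g)
  expect_equal(f2@Vg, f1@Vg, tolerance = 1e-6)
  expect_equal(f2@Ve, f1@Ve, tolerance = 1e-6)
  expect_equal(gebv(f2), gebv(f1), tolerance = 1e-6)
  expect_equal(f2@fixedEffects[["intercept"]],
               f1@fixedEffects[["intercept"]] + 100, tolerance = 1e-6)
})

test_that("GBLUP prediction is consistent for genotypic twins and zero effects", {
  fx <- simFixture(n = 100, m = 150, h2 = 0.5, nQtl = 50, seed = 18)
  d <- dosages(fx$panel)
  # append a genotypic twin of a training individual as a new individual
  dAll <- rbind(d, twin = d[7, ])
  rownames(dAll)[nrow(dAll)] <- "twin"
  joint <- vanRadenGRM(GenotypePanel(dAll, chrom = fx$panel@chrom,
                                     pos = fx$panel@pos))
  fit <- fitGBLUP(fx$y, joint[names(fx$y), names(fx$y)])
  pred <- predictGebv(fit, joint)
  expect_equal(unname(pred["twin"]), unname(gebv(fit)[7]), tolerance = 1e-8)

  # all-zero marker effects predict zero for any new genotypes
  fitB <- fitBayes(fx$y, fx$panel, "BayesRR",
                   gibbsSettings("desk", iterations = 600, burnIn = 100,
                                 seed = 1))
  fitB@markerEffects[] <- 0
  expect_equal(unname(predictGebv(fitB, fx$panel[1:5, ])), rep(0, 5))
})

test_that("variance-component SDs are finite and h2 is slot-consistent", {
  fx <- simFixture(n = 150, m = 200, h2 = 0.4, nQtl = 50, seed = 19)
  fit <- fitGBLUP(fx$y, vanRadenGRM(fx$panel))
  vc <- varComp(fit)
  expect_true(all(is.finite(vc[c("sdVg", "sdVe")])))
  expect_equal(fit@h2, vc[["Vg"]] / (vc[["Vg"]] + vc[["Ve"]]), tolerance = 1e-12)
})
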