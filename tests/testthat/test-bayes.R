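# Reduced chains keep these tests fast; the sampler itself is the same code
# that runs the full 50,000-iteration preset.

test_that("chains are deterministic given seed and settings", {
  fx <- simFixture(n = 80, m = 120, h2 = 0.4, nQtl = 40, seed = 20)
  s <- gibbsSettings("desk", iterations = 800, burnIn = 200, seed = 5)
  f1 <- fitBayes(fx$y, fx$panel, "BayesB", s)
  f2 <- fitBayes(fx$y, fx$panel, "BayesB", s)
  expect_identical(markerEffects(f1), markerEffects(f2))
  expect_identical(varComp(f1), varComp(f2))
  f3 <- fitBayes(fx$y, fx$panel, "BayesB",
                 gibbsSettings("desk", iterations = 800, burnIn = 200, seed = 6))
  expect_false(identical(markerEffects(f1), markerEffects(f3)))
})

test_that("settings invariants are enforced", {
  expect_error(gibbsSettings(iterations = 100, burnIn = 100), "burnIn")
  expect_error(gibbsSettings(pi = 1), "pi")
  expect_error(gibbsSettings(thin = 0), "thin")
  fx <- simFixture(n = 40, m = 50, seed = 21)
  yConst <- rep(1, 40); names(yConst) <- names(fx$y)
  expect_error(fitBayes(yConst, fx$panel, "BayesRR"), "zero variance")
})

test_that("the spike-only limit of BayesC shrinks everything to the spike", {
  fx <- simFixture(n = 150, m = 200, h2 = 0, nQtl = 50, seed = 22)
  s <- gibbsSettings("desk", iterations = 1500, burnIn = 500,
                     pi = 1 - 1e-12, seed = 2)
  fit <- fitBayes(fx$y, fx$panel, "BayesC", s)
  expect_lte(max(inclusionProb(fit)), 0.05)
  expect_lte(stats::var(gebv(fit)) / stats::var(fx$y), 0.05)
})

test_that("Bayesian ridge regression reproduces GBLUP breeding values", {
  fx <- simFixture(n = 250, m = 500, h2 = 0.4, nQtl = 125, seed = 23)
  gb <- fitGBLUP(fx$y, vanRadenGRM(fx$panel))
  rr <- fitBayes(fx$y, fx$panel, "BayesRR",
                 gibbsSettings("desk", iterations = 3000, burnIn = 500, seed = 3))
  expect_gte(cor(gebv(rr), gebv(gb)), 0.98)
})

test_that("BayesB singles out a large simulated QTL", {
  set.seed(24)
  fx <- simFixture(n = 300, m = 400, h2 = 0, nQtl = 1, seed = 24)
  d <- dosages(fx$panel)
  qtl <- 137
  gval <- scale(d[, qtl])[, 1]
  # one causal marker explaining ~30% of phenotypic variance
  y <- sqrt(0.3) * gval + sqrt(0.7) * rnorm(300)
  names(y) <- names(fx$y)
  fit <- fitBayes(y, fx$panel, "BayesB",
                  gibbsSettings("desk", iterations = 2000, burnIn = 500,
                                pi = 0.95, seed = 4))
  expect_equal(which.max(inclusionProb(fit)), qtl, ignore_attr = TRUE)
})

test_that("posterior-mean h2 is stable under chain doubling", {
  fx <- simFixture(n = 200, m = 300, h2 = 0.4, nQtl = 75, seed = 25)
  h2short <- fitBayes(fx$y, fx$panel, "BayesRR",
                      gibbsSettings("desk", iterations = 3000, burnIn = 500,
                                    seed = 7))@h2
  h2long <- fitBayes(fx$y, fx$panel, "BayesRR",
                     gibbsSettings("desk", iterations = 6000, burnIn = 500,
                                   seed = 7))@h2
  expect_lt(abs(h2long - h2short), 0.02)
})

test_that("held-out prediction recovers true breeding values", {
  rs <- vapply(1:3, function(s) {
    fx <- simFixture(n = 400, m = 800, h2 = 0.5, nQtl = 200, seed = 400 + s)
    trainIds <- names(fx$y)[1:300]
    testIds <- names(fx$y)[301:400]
    fit <- fitBayes(fx$y[trainIds], fx$panel[trainIds, ], "BayesRR",
                    gibbsSettings("desk", iterations = 2000, burnIn = 500,
                                  seed = s))
    pred <- predictGebv(fit, fx$panel[testIds, ])
    cor(pred, fx$truth@trueBreedingValues[testIds, 1])
  }, numeric(1))
  expect_gte(mean(rs), 0.4)
})

test_that("prediction demands the training SNP set", {
  fx <- simFixture(n = 60, m = 80, seed = 26)
  fit <- fitBayes(fx$y, fx$panel, "BayesRR",
                  gibbsSettings("desk", iterations = 600, burnIn = 100, seed = 1))
  expect_error(predictGebv(fit, fx$panel[1:5, 1:70]), "training SNP")
})
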