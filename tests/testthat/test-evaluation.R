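test_that("fold plans partition individuals into near-equal reproducible folds", {
  plan <- makeFolds(103, k = 5, nRepeats = 4, baseSeed = 2)
  a <- foldAssignments(plan)
  for (r in 1:4) {
    tab <- table(a[r, ])
    expect_equal(sum(tab), 103)
    expect_lte(max(tab) - min(tab), 1)
  }
  plan2 <- makeFolds(103, k = 5, nRepeats = 4, baseSeed = 2)
  expect_identical(foldAssignments(plan2), a)
  plan3 <- makeFolds(103, k = 5, nRepeats = 4, baseSeed = 3)
  expect_false(identical(foldAssignments(plan3), a))
  expect_error(makeFolds(3, k = 5), "n must be")
})

test_that("predictability is the Pearson correlation with guarded inputs", {
  x <- rnorm(91)
  expect_equal(predictability(x, x), 1.0)
  expect_equal(predictability(x, -x), -1.0)
  expect_error(predictability(x, rep(1, 91)), "zero-variance")
  expect_error(predictability(x[1:2], x[1:2]), "at least 3")

  # permutation null: mean r over independent shuffles is ~0
  set.seed(33)
  y <- rnorm(91)
  rs <- replicate(200, predictability(x, sample(y)))
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("cross-validation never reads test phenotypes", {
  fx <- simFixture(n = 120, m = 150, h2 = 0.5, nQtl = 50, seed = 34)
  plan <- makeFolds(names(fx$y), k = 4, nRepeats = 1, baseSeed = 9)
  cv1 <- runCV(fx$y, fx$panel, "GBLUP", plan, returnGebv = TRUE)

  # corrupt the phenotypes of fold 1's test individuals: predictions for
  # that cell must not move (only the reported r may)
  a <- foldAssignments(plan)
  testIds <- colnames(a)[a[1, ] == 1]
  yBad <- fx$y
  yBad[testIds] <- yBad[testIds] + 1000
  cv2 <- runCV(yBad, fx$panel, "GBLUP", plan, returnGebv = TRUE)
  cell <- which(cvCells(cv1)$fold == 1)[1]
  expect_equal(attr(cv1, "predictions")[[cell]],
               attr(cv2, "predictions")[[cell]])
})

test_that("a null trait yields no predictability and a heritable one does", {
  fx0 <- simFixture(n = 200, m = 250, h2 = 0, nQtl = 60, seed = 35)
  plan <- makeFolds(names(fx0$y), k = 5, nRepeats = 4, baseSeed = 1)
  cv0 <- runCV(fx0$y, fx0$panel, "GBLUP", plan)
  expect_lte(abs(mean(cvCells(cv0)$r, na.rm = TRUE)), 0.05)

  fx1 <- simFixture(n = 150, m = 300, h2 = 1, nQtl = 300, seed = 36)
  plan1 <- makeFolds(names(fx1$y), k = 5, nRepeats = 1, baseSeed = 1)
  cv1 <- runCV(fx1$y, fx1$panel, "GBLUP", plan1)
  expect_gte(mean(cvCells(cv1)$r), 0.5)
})

test_that("summaries recompute exactly from stored cells", {
  fx <- simFixture(n = 100, m = 120, h2 = 0.5, nQtl = 40, seed = 37)
  plan <- makeFolds(names(fx$y), k = 5, nRepeats = 2, baseSeed = 4)
  cv <- runCV(fx$y, fx$panel, "GBLUP", plan)
  cells <- cvCells(cv)
  summ <- cvSummary(cv)
  expect_equal(summ$mean, mean(cells$r, na.rm = TRUE))
  expect_equal(summ$sd, sd(cells$r, na.rm = TRUE))
  expect_equal(summ$n, plan@k * nrow(foldAssignments(plan)))
})

test_that("SNP selection follows each strategy's contract", {
  fx <- simFixture(n = 80, m = 10, seed = 38)
  # evenly spaced: floor(j*(m-1)/(size-1)) -> 0-based {0,2,4,6,9}
  expect_equal(selectSnps(fx$panel, "evenly_spaced", 5), c(1L, 3L, 5L, 7L, 10L))
  expect_equal(selectSnps(fx$panel, "evenly_spaced", 10), 1:10)

  # random: seeded and nested across sizes
  s100 <- selectSnps(fx$panel, "random", 4, seed = 11)
  s150 <- selectSnps(fx$panel, "random", 7, seed = 11)
  expect_true(all(s100 %in% s150))
  expect_identical(selectSnps(fx$panel, "random", 4, seed = 11), s100)

  # gwas_ranked: full size returns everything; ranking required
  fx2 <- simFixture(n = 120, m = 50, h2 = 0.5, nQtl = 10, seed = 39)
  res <- lmmGwas(fx2$y, fx2$panel, vanRadenGRM(fx2$panel))
  expect_equal(selectSnps(fx2$panel, "gwas_ranked", 50, ranking = res), 1:50)
  top <- selectSnps(fx2$panel, "gwas_ranked", 5, ranking = res)
  tab <- as.data.frame(res)
  expect_setequal(tab$id[top], tab$id[order(tab$p)][1:5])
  expect_error(selectSnps(fx2$panel, "gwas_ranked", 5), "ranking")
  expect_error(selectSnps(fx2$panel, "random", 0), "size")
})

test_that("density curves coincide with full-panel CV at size m", {
  fx <- simFixture(n = 100, m = 80, h2 = 0.6, nQtl = 40, seed = 40)
  plan <- makeFolds(names(fx$y), k = 4, nRepeats = 1, baseSeed = 6)
  full <- runCV(fx$y, fx$panel, "GBLUP", plan)
  for (strat in c("random", "evenly_spaced")) {
    curve <- densityExperiment(fx$y, fx$panel, plan, strat, sizes = c(40, 80))
    atM <- curve@cells[curve@cells$panelSize == 80, ]
    expect_equal(atM$r, cvCells(full)$r, tolerance = 1e-10)
  }
})

test_that("density summary reflects noisy monotone improvement with size", {
  fx <- simFixture(n = 150, m = 300, h2 = 0.6, nQtl = 150, seed = 41)
  plan <- makeFolds(names(fx$y), k = 5, nRepeats = 1, baseSeed = 8)
  curve <- densityExperiment(fx$y, fx$panel, plan, "evenly_spaced",
                             sizes = c(30, 300))
  s <- curve@summary
  expect_gte(s$mean[s$panelSize == 300],
             s$mean[s$panelSize == 30] - 0.02)
})
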