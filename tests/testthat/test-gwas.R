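test_that("genotype PCA is orthogonal with non-increasing explained variance", {
  fx <- simFixture(n = 100, m = 300, seed = 27)
  pca <- genotypePCA(fx$panel, k = 3)
  xp <- crossprod(pca$scores)
  expect_lt(max(abs(xp[upper.tri(xp)])), 1e-8)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_error(genotypePCA(fx$panel, k = 101), "exceeds")
})

test_that("PC1 separates two diverged subpopulations with no overlap", {
  set.seed(28)
  m <- 200; n <- 60
  p1 <- runif(m, 0.1, 0.4); p2 <- pmin(0.9, p1 + 0.4)
  d <- rbind(matrix(rbinom(n * m, 2, rep(p1, each = n)), n, m),
             matrix(rbinom(n * m, 2, rep(p2, each = n)), n, m))
  pca <- genotypePCA(panelFromMatrix(d), k = 2)
  a <- pca$scores[1:n, 1]; b <- pca$scores[(n + 1):(2 * n), 1]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("with an identity GRM the mixed-model scan equals per-marker OLS", {
  fx <- simFixture(n = 120, m = 200, h2 = 0.3, nQtl = 50, seed = 29)
  ids <- names(fx$y)
  gI <- new("GRM", values = diag(length(ids)) |>
              (\(v) {dimnames(v) <- list(ids, ids); v})(),
            denominator = 1, alleleFreqs = numeric())
  res <- lmmGwas(fx$y, fx$panel, gI)
  pOls <- olsWaldP(fx$y, dosages(fx$panel)[ids, ])
  expect_equal(as.data.frame(res)$p, pOls, tolerance = 1e-6)
})

test_that("a major simulated QTL attains the genome-wide minimum p", {
  set.seed(30)
  fx <- simFixture(n = 300, m = 500, h2 = 0.2, nQtl = 125, seed = 30)
  d <- dosages(fx$panel)
  qtl <- 250
  y <- fx$y + sqrt(0.25 / (1 - 0.25)) * sd(fx$y) * scale(d[, qtl])[, 1]
  res <- lmmGwas(y, fx$panel, vanRadenGRM(fx$panel))
  tab <- as.data.frame(res)
  expect_equal(tab$id[which.min(tab$p)], snpIds(fx$panel)[qtl])
})

test_that("null p-values are uniform under a polygenic background", {
  # fully polygenic trait: no individual marker is a QTL of notable effect
  fx <- simFixture(n = 455, m = 10000, h2 = 0.3, nQtl = 10000, seed = 31)
  res <- lmmGwas(fx$y, fx$panel, vanRadenGRM(fx$panel))
  p <- as.data.frame(res)$p
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
  expect_equal(res@lambdaGc, 1, tolerance = 0.1)
})

test_that("p-values are invariant to phenotype location and positive scale", {
  fx <- simFixture(n = 100, m = 150, h2 = 0.4, nQtl = 40, seed = 32)
  g <- vanRadenGRM(fx$panel)
  p1 <- as.data.frame(lmmGwas(fx$y, fx$panel, g))$p
  p2 <- as.data.frame(lmmGwas(3.2 * fx$y + 17, fx$panel, g))$p
  expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("significance thresholds follow Bonferroni and the suggestive rule", {
  thr <- significanceThresholds(16162, 0.05, 4)
  expect_equal(thr[["bonferroni_p"]], 0.05 / 16162)
  expect_equal(thr[["suggestive_p"]], 1e-4)
  expect_equal(significanceThresholds(1, 0.05)[["bonferroni_p"]], 0.05)
  expect_error(significanceThresholds(0), "nTests")
})

test_that("per-SNP PVE uses 2p(1-p)beta^2/var and clips to [0, 1]", {
  expect_equal(snpPve(0, 0.3, 1), 0)
  expect_equal(snpPve(1, 0.5, 2), 0.25)
  expect_equal(snpPve(100, 0.5, 1), 1)   # clipped
  expect_error(snpPve(1, 0.6, 1), "maf")
})

test_that("candidate windows clip, overlap by >= 1 bp, and warn on unknown chromosomes", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t399000\t401000\t.\t+\t.\tID=geneA;Name=geneA",
    "chr1\ttest\tgene\t650000\t700000\t.\t-\t.\tID=geneB;Name=geneB",
    "chr1\ttest\tgene\t10\t120000\t.\t+\t.\tID=geneC;Name=geneC"),
    gff)
  hits <- data.frame(id = c("s1", "s2"), chrom = c("chr1", "chr1"),
                     pos = c(500000L, 40000L))
  cw <- candidateWindows(hits, gff, flankBp = 100000L)
  w1 <- cw[cw$snp == "s1", ]
  expect_equal(w1$windowStart[1], 400000L)
  expect_equal(w1$windowEnd[1], 600000L)
  expect_true("geneA" %in% w1$gene)        # 1-bp-overlap rule: [399000,401000]
  expect_false("geneB" %in% w1$gene)
  w2 <- cw[cw$snp == "s2", ]
  expect_equal(w2$windowStart[1], 1L)      # clipped at chromosome start
  expect_true("geneC" %in% w2$gene)

  expect_warning(
    candidateWindows(data.frame(id = "s3", chrom = "chrZ", pos = 1000L), gff),
    "chrZ")
})
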