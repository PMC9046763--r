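#' Principal component analysis of genotypes
#'
#' PCA of the column-standardized dosage matrix, used descriptively to
#' examine population structure and relatedness before association
#' analysis. Monomorphic columns (zero variance) are centered only.
#'
#' @param panel an imputed [GenotypePanel-class].
#' @param k number of components (default 3).
#' @return list with `scores` (n x k, mutually orthogonal columns) and
#'   `explained` (fractions of total variance, non-increasing).
#' @export
genotypePCA <- function(panel, k = 3L) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  if (anyNA(d)) stop("panel has missing dosages; impute first")
  if (k > min(dim(d))) stop("k exceeds min(n, m)")
  sds <- apply(d, 2, stats::sd)
  ds <- sweep(sweep(d, 2, colMeans(d)), 2, ifelse(sds > 0, sds, 1), "/")
  sv <- svd(ds, nu = k, nv = 0)
  if (k > sum(sv$d > sv$d[1] * 1e-12)) stop("k exceeds the rank of the panel")
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(d)
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  list(scores = scores, explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}

#' Mixed-model genome-wide association scan
#'
#' Single-marker association under the univariate linear mixed model
#' `y = W a + x beta + u + e`, `u ~ N(0, sigma_g^2 G)`, with the genomic
#' relationship matrix absorbing structure and relatedness. The null-model
#' variance ratio is estimated once by REML via the eigendecomposition of
#' `G` and reused for every SNP (the standard EMMAX-style approximation);
#' per SNP, the effect and its standard error come from generalized least
#' squares in the rotated space, with the residual variance re-estimated
#' per SNP so that with `G = I` the scan reduces exactly to ordinary least
#' squares. Significance is the Wald test `(beta/se)^2` against
#' chi-square(1). With `exact = TRUE` the variance ratio is re-optimized
#' for every SNP (slower; negligibly different in designs like this one).
#'
#' @param y named numeric phenotype vector.
#' @param panel imputed [GenotypePanel-class].
#' @param grm [GRM-class] for the same individuals.
#' @param covariates optional covariate matrix (e.g. PCA scores); an
#'   intercept is always included.
#' @param alpha genome-wide significance level for the Bonferroni
#'   threshold (default 0.05).
#' @param suggestiveNeglog10 suggestive threshold on the -log10(p) scale
#'   (default 4).
#' @param exact re-optimize the variance ratio per SNP.
#' @return a [GwasResult-class]; SNPs with zero variance in the rotated
#'   space get `p = 1` and `beta = se = NA`.
#' @export
lmmGwas <- function(y, panel, grm, covariates = NULL, alpha = 0.05,
                    suggestiveNeglog10 = 4, exact = FALSE) {
  stopifnot(is(panel, "GenotypePanel"), is(grm, "GRM"))
  if (is.null(names(y))) stop("y must be named by individual id")
  ids <- names(y)
  if (!all(ids %in% individualIds(panel)) || !all(ids %in% individualIds(grm)))
    stop("panel/GRM do not cover all phenotyped individuals")
  d <- dosages(panel)[ids, , drop = FALSE]
  if (anyNA(d)) stop("panel has missing dosages; impute first")
  G <- as.matrix(grm)[ids, ids]

  null <- fitGBLUP(y, grm, covariates)
  kappa <- null@Vg / null@Ve

  ev <- eigen(G, symmetric = TRUE)
  dG <- pmax(ev$values, 0)
  U <- ev$vectors
  w <- 1 / (kappa * dG + 1)
  ystar <- drop(crossprod(U, y))
  W <- cbind(intercept = rep(1, length(y)), covariates)
  Wstar <- crossprod(U, W)
  Xstar <- crossprod(U, d)  # n x m rotated genotypes

  m <- ncol(d)
  n <- length(y)
  pcov <- ncol(W)

  if (!exact) {
    out <- .gwasScanFixedRatio(ystar, Wstar, Xstar, w, n, pcov)
  } else {
    out <- .gwasScanExact(ystar, Wstar, Xstar, dG, n, pcov, kappa)
  }

  snps <- data.frame(id = colnames(d), chrom = panel@chrom, pos = panel@pos,
                     beta = out$beta, se = out$se, p = out$p,
                     stringsAsFactors = FALSE)
  thr <- significanceThresholds(m, alpha, suggestiveNeglog10)
  chi2 <- stats::qchisq(snps$p, df = 1, lower.tail = FALSE)
  lambdaGc <- stats::median(chi2, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
  new("GwasResult", snps = snps, nTests = as.integer(m),
      bonferroniP = thr[["bonferroni_p"]], suggestiveP = thr[["suggestive_p"]],
      lambdaGc = lambdaGc, nullVarcomp = c(Vg = null@Vg, Ve = null@Ve))
}

# GLS per SNP with fixed variance ratio; residual variance re-estimated
# per SNP (df = n - pcov - 1) so G = I reproduces per-marker OLS exactly.
.gwasScanFixedRatio <- function(ystar, Wstar, Xstar, w, n, pcov) {
  m <- ncol(Xstar)
  WtW <- crossprod(Wstar, Wstar * w)
  Wty <- crossprod(Wstar, ystar * w)
  WtX <- crossprod(Wstar, Xstar * w)          # pcov x m
  xx <- colSums(Xstar^2 * w)
  xy <- colSums(Xstar * (ystar * w))
  yy <- sum(ystar^2 * w)

  WtWinv <- solve(WtW)
  A <- WtWinv %*% WtX                         # pcov x m
  sxx <- xx - colSums(WtX * A)                # x'Wx adjusted for covariates
  sxy <- xy - colSums(A * drop(Wty))
  aW <- drop(WtWinv %*% Wty)
  syy <- yy - sum(Wty * aW)

  beta <- se <- p <- rep(NA_real_, m)
  ok <- sxx > 1e-10
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- syy - sxy^2 / ifelse(ok, sxx, 1)
  dfres <- n - pcov - 1
  s2 <- pmax(rss, 0) / dfres
  se[ok] <- sqrt(s2[ok] / sxx[ok])
  wald <- (beta / se)^2
  p[ok] <- stats::pchisq(wald[ok], df = 1, lower.tail = FALSE)
  p[!ok] <- 1
  p[ok] <- pmax(p[ok], .Machine$double.xmin)
  list(beta = beta, se = se, p = p)
}

.gwasScanExact <- function(ystar, Wstar, Xstar, dG, n, pcov, kappaInit) {
  m <- ncol(Xstar)
  beta <- se <- p <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    Xj <- cbind(Wstar, Xstar[, j])
    if (stats::sd(Xstar[, j]) < 1e-10) { p[j] <- 1; next }
    nll <- function(lk) {
      k <- exp(lk)
      wj <- 1 / (k * dG + 1)
      XtWX <- crossprod(Xj, Xj * wj)
      b <- solve(XtWX, crossprod(Xj, ystar * wj))
      r <- ystar - drop(Xj %*% b)
      q <- sum(wj * r^2)
      np <- n - pcov - 1
      0.5 * (np * log(q / np) + sum(log1p(k * dG)) +
               as.numeric(determinant(XtWX, logarithm = TRUE)$modulus) + np)
    }
    opt <- stats::optimize(nll, log(c(1e-6, 1e6)), tol = 1e-6)
    k <- exp(opt$minimum)
    wj <- 1 / (k * dG + 1)
    XtWX <- crossprod(Xj, Xj * wj)
    b <- solve(XtWX, crossprod(Xj, ystar * wj))
    r <- ystar - drop(Xj %*% b)
    s2 <- sum(wj * r^2) / (n - pcov - 1)
    covb <- solve(XtWX) * s2
    beta[j] <- b[pcov + 1]
    se[j] <- sqrt(covb[pcov + 1, pcov + 1])
    p[j] <- stats::pchisq((beta[j] / se[j])^2, df = 1, lower.tail = FALSE)
  }
  p[is.na(p)] <- 1
  list(beta = beta, se = se, p = p)
}

#' Genome-wide and suggestive significance thresholds
#'
#' Bonferroni correction `alpha / nTests` for genome-wide significance and
#' a fixed suggestive threshold `10^-suggestiveNeglog10` (conventionally
#' -log10(p) > 4 when no marker reaches Bonferroni significance in a
#' polygenic trait).
#'
#' @param nTests number of markers tested.
#' @param alpha family-wise error rate (default 0.05).
#' @param suggestiveNeglog10 suggestive -log10(p) cut-off (default 4).
#' @return named numeric: `bonferroni_p`, `suggestive_p`.
#' @examples
#' significanceThresholds(16162)
#' @export
significanceThresholds <- function(nTests, alpha = 0.05, suggestiveNeglog10 = 4) {
  if (nTests < 1) stop("nTests must be >= 1")
  c(bonferroni_p = alpha / nTests, suggestive_p = 10^(-suggestiveNeglog10))
}

#' Per-SNP proportion of phenotypic variance explained
#'
#' The standard single-marker estimator
#' `PVE = 2 maf (1 - maf) beta^2 / var_y`, clipped to `[0, 1]`.
#'
#' @param beta allele substitution effect.
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @param varY phenotypic variance.
#' @return fraction in `[0, 1]`.
#' @examples
#' snpPve(1, 0.5, 2)  # 0.25
#' @export
snpPve <- function(beta, maf, varY) {
  stopifnot(all(maf > 0 & maf <= 0.5), all(varY > 0))
  pmin(1, pmax(0, 2 * maf * (1 - maf) * beta^2 / varY))
}

#' Candidate-gene windows around association hits
#'
#' For each hit SNP, forms the window `[pos - flankBp, pos + flankBp]`
#' (1-based inclusive, clipped at position 1 and, when chromosome lengths
#' are known, at the chromosome end) and reports every annotated gene
#' whose span overlaps the window by at least 1 bp.
#'
#' @param hits data.frame with columns `id`, `chrom`, `pos` (e.g. a subset
#'   of `as.data.frame(gwasResult)` ranked by p-value).
#' @param annotation gene annotation: a `GRanges` (e.g. from
#'   `rtracklayer::import` of a GFF3, filtered to gene features) or a
#'   GFF3 file path.
#' @param flankBp flank on each side of the SNP (default 100,000).
#' @param chromLengths optional named vector of chromosome lengths for
#'   right-clipping.
#' @return data.frame with one row per SNP-gene overlap (SNPs without
#'   overlapping genes keep one row with NA gene fields); windows on
#'   chromosomes absent from the annotation yield a warning.
#' @export
candidateWindows <- function(hits, annotation, flankBp = 100000L,
                             chromLengths = NULL) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(hits)))
  if (is.character(annotation)) {
    annotation <- rtracklayer::import(annotation)
    annotation <- annotation[annotation$type == "gene"]
  }
  start <- pmax(1L, hits$pos - as.integer(flankBp))
  end <- hits$pos + as.integer(flankBp)
  if (!is.null(chromLengths)) {
    lim <- chromLengths[as.character(hits$chrom)]
    end <- ifelse(!is.na(lim), pmin(end, as.integer(lim)), end)
  }
  win <- GenomicRanges::GRanges(as.character(hits$chrom),
                                IRanges::IRanges(start, end))
  missingChrom <- setdiff(unique(as.character(hits$chrom)),
                          as.character(GenomicRanges::seqnames(annotation)))
  if (length(missingChrom)) {
    warning(sprintf("chromosome(s) absent from the annotation: %s",
                    paste(missingChrom, collapse = ", ")))
  }
  # seqlevel-mismatch warnings are redundant with the explicit one above
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(win, annotation, minoverlap = 1L))
  geneName <- function(gr) {
    nm <- if (!is.null(gr$Name)) gr$Name else if (!is.null(gr$ID)) gr$ID else NA
    as.character(nm)
  }
  rows <- lapply(seq_along(win), function(i) {
    genes <- annotation[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
    base <- data.frame(snp = hits$id[i], chrom = as.character(hits$chrom[i]),
                       snpPos = hits$pos[i], windowStart = start[i],
                       windowEnd = end[i], stringsAsFactors = FALSE)
    if (!length(genes)) {
      cbind(base, data.frame(gene = NA_character_, geneStart = NA_integer_,
                             geneEnd = NA_integer_, strand = NA_character_))
    } else {
      cbind(base[rep(1, length(genes)), , drop = FALSE],
            data.frame(gene = geneName(genes),
                       geneStart = GenomicRanges::start(genes),
                       geneEnd = GenomicRanges::end(genes),
                       strand = as.character(GenomicRanges::strand(genes)),
                       stringsAsFactors = FALSE))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
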