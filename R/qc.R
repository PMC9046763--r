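#' Genotype quality control
#'
#' Call-rate filtering of individuals and SNPs, minor-allele-frequency
#' filtering, mean-dosage imputation and windowed r-squared tag-SNP pruning.
#' The pipeline order is fixed: individuals, then SNP call rate / MAF, then
#' imputation, then pruning. All thresholds use keep-if-at-threshold
#' (`>=`) semantics, matching common PLINK usage where "MAF < 5%" is the
#' exclusion rule.
#'
#' @name genotype-qc
NULL

.emptyQc <- function(thresholds = numeric()) {
  new("QcReport", nIndividualsRemoved = 0L, nSnpsRemovedCallrate = 0L,
      nSnpsRemovedMaf = 0L, nSnpsRemovedPrune = 0L, thresholds = thresholds)
}

#' Minor allele frequencies of a panel
#'
#' Computed from non-missing dosages only: `maf = min(p, 1 - p)` with
#' `p = mean(dosage) / 2`.
#' @param panel a [GenotypePanel-class].
#' @return named numeric vector, one MAF per SNP.
#' @export
snpMaf <- function(panel) {
  p <- colMeans(dosages(panel), na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @describeIn genotype-qc Remove individuals whose genotype call rate is
#'   below `minCallRate`; survivor order is preserved.
#' @param panel a [GenotypePanel-class].
#' @param minCallRate minimum fraction of non-missing genotypes, in `(0, 1]`.
#' @return list with the filtered `panel` and a `report` ([QcReport-class]).
#' @export
filterIndividuals <- function(panel, minCallRate = 0.9) {
  stopifnot(is(panel, "GenotypePanel"))
  if (minCallRate <= 0 || minCallRate > 1) stop("minCallRate must lie in (0, 1]")
  d <- dosages(panel)
  callRate <- rowMeans(!is.na(d))
  keep <- callRate >= minCallRate
  if (!any(keep)) stop("all individuals removed by the call-rate filter")
  list(panel = panel[which(keep), ],
       report = new("QcReport", nIndividualsRemoved = sum(!keep),
                    nSnpsRemovedCallrate = 0L, nSnpsRemovedMaf = 0L,
                    nSnpsRemovedPrune = 0L,
                    thresholds = c(min_ind_call_rate = minCallRate)))
}

#' @describeIn genotype-qc Remove SNPs with call rate below `minCallRate`
#'   or minor allele frequency below `minMaf` (MAF computed on non-missing
#'   dosages); genome map order is preserved.
#' @param minMaf minimum minor allele frequency, in `(0, 1]`; SNPs at
#'   exactly the threshold are kept.
#' @export
filterSnps <- function(panel, minCallRate = 0.9, minMaf = 0.05) {
  stopifnot(is(panel, "GenotypePanel"))
  if (minCallRate <= 0 || minCallRate > 1) stop("minCallRate must lie in (0, 1]")
  if (minMaf <= 0 || minMaf > 1) stop("minMaf must lie in (0, 1]")
  d <- dosages(panel)
  callRate <- colMeans(!is.na(d))
  maf <- snpMaf(panel)
  lowCall <- callRate < minCallRate
  lowMaf <- !lowCall & maf < minMaf
  keep <- !(lowCall | lowMaf)
  if (!any(keep)) stop("no SNPs survive the call-rate/MAF filter")
  list(panel = panel[, which(keep)],
       report = new("QcReport", nIndividualsRemoved = 0L,
                    nSnpsRemovedCallrate = sum(lowCall),
                    nSnpsRemovedMaf = sum(lowMaf),
                    nSnpsRemovedPrune = 0L,
                    thresholds = c(min_snp_call_rate = minCallRate,
                                   min_maf = minMaf)))
}

#' @describeIn genotype-qc Replace missing dosages by the SNP's mean
#'   observed dosage (real-valued dosages result). Mean imputation
#'   preserves each SNP's allele frequency; haplotype-aware imputation is
#'   deliberately out of scope.
#' @export
imputeMissing <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  if (!anyNA(d)) return(panel)
  allMissing <- colSums(!is.na(d)) == 0L
  if (any(allMissing)) {
    stop(sprintf("SNP(s) with all calls missing: %s",
                 paste(colnames(d)[allMissing], collapse = ", ")))
  }
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  GenotypePanel(d, chrom = panel@chrom, pos = panel@pos)
}

#' @describeIn genotype-qc Greedy left-to-right tag-SNP selection within
#'   each chromosome: a SNP is dropped when its squared Pearson correlation
#'   with any *retained* SNP among the trailing `windowSnps` retained
#'   markers exceeds `r2Threshold`. Reduces the multicollinearity of
#'   whole-genome regression while keeping one representative per LD block.
#' @param r2Threshold squared-correlation ceiling in `(0, 1]`; a SNP is
#'   dropped only when r-squared strictly exceeds it.
#' @param windowSnps number of trailing retained SNPs compared against.
#' @export
pruneTagSnps <- function(panel, r2Threshold = 0.8, windowSnps = 50L) {
  stopifnot(is(panel, "GenotypePanel"))
  if (r2Threshold <= 0 || r2Threshold > 1) stop("r2Threshold must lie in (0, 1]")
  if (windowSnps < 2L) stop("windowSnps must be >= 2")
  d <- dosages(panel)
  if (anyNA(d)) stop("panel must be imputed before pruning")
  m <- ncol(d)
  sds <- apply(d, 2, stats::sd)
  # standardized columns; zero-variance SNPs have undefined r2 -> kept
  ds <- sweep(sweep(d, 2, colMeans(d)), 2, ifelse(sds > 0, sds, 1), "/")
  n1 <- nrow(d) - 1
  keep <- logical(m)
  for (ch in unique(panel@chrom)) {
    idx <- which(panel@chrom == ch)
    retained <- integer(0)
    for (j in idx) {
      win <- utils::tail(retained, windowSnps)
      drop <- FALSE
      if (length(win) && sds[j] > 0) {
        r <- crossprod(ds[, win, drop = FALSE], ds[, j]) / n1
        drop <- any(r^2 > r2Threshold + 1e-12)
      }
      if (!drop) {
        keep[j] <- TRUE
        retained <- c(retained, j)
      }
    }
  }
  list(panel = panel[, which(keep)],
       report = new("QcReport", nIndividualsRemoved = 0L,
                    nSnpsRemovedCallrate = 0L, nSnpsRemovedMaf = 0L,
                    nSnpsRemovedPrune = sum(!keep),
                    thresholds = c(prune_r2 = r2Threshold,
                                   prune_window = windowSnps)))
}

#' Run the full QC pipeline
#'
#' Applies, in this order: individual call-rate filter, SNP call-rate/MAF
#' filter, mean-dosage imputation, and (optionally) tag-SNP pruning.
#'
#' @param panel a [GenotypePanel-class].
#' @param minIndCallRate,minSnpCallRate,minMaf,pruneR2,pruneWindow thresholds.
#' @param prune logical; run the tag-SNP pruning step.
#' @return list with `panel` and an aggregated `report`.
#' @export
runQc <- function(panel, minIndCallRate = 0.9, minSnpCallRate = 0.9,
                  minMaf = 0.05, prune = FALSE, pruneR2 = 0.8,
                  pruneWindow = 50L) {
  s1 <- filterIndividuals(panel, minIndCallRate)
  s2 <- filterSnps(s1$panel, minSnpCallRate, minMaf)
  p <- imputeMissing(s2$panel)
  prunedCount <- 0L
  if (prune) {
    s3 <- pruneTagSnps(p, pruneR2, pruneWindow)
    p <- s3$panel
    prunedCount <- s3$report@nSnpsRemovedPrune
  }
  report <- new("QcReport",
                nIndividualsRemoved = s1$report@nIndividualsRemoved,
                nSnpsRemovedCallrate = s2$report@nSnpsRemovedCallrate,
                nSnpsRemovedMaf = s2$report@nSnpsRemovedMaf,
                nSnpsRemovedPrune = prunedCount,
                thresholds = c(min_ind_call_rate = minIndCallRate,
                               min_snp_call_rate = minSnpCallRate,
                               min_maf = minMaf,
                               prune_r2 = if (prune) pruneR2 else NA_real_,
                               prune_window = if (prune) pruneWindow else NA_real_))
  list(panel = p, report = report)
}
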