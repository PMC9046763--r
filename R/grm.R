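#' VanRaden genomic relationship matrix
#'
#' Builds the realized additive relationship matrix (VanRaden's first
#' method) from an imputed dosage panel:
#' \deqn{G = \frac{Z Z'}{2 \sum_j p_j (1 - p_j)}}
#' where `Z` is the dosage matrix with each column centered by twice the
#' observed alternate-allele frequency `p_j`. Frequencies are estimated
#' from the panel itself (no base-population frequencies are assumed);
#' real-valued imputed dosages are accepted.
#'
#' @param panel an imputed [GenotypePanel-class] with no monomorphic SNPs.
#' @return a [GRM-class]. Under Hardy–Weinberg sampling the mean diagonal
#'   is close to 1.
#' @examples
#' gp <- GenotypePanel(matrix(c(0, 2, 2, 0), 2), chrom = c("1", "1"), pos = c(1L, 2L))
#' as.matrix(vanRadenGRM(gp))
#' @export
vanRadenGRM <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  if (anyNA(d)) stop("panel has missing dosages; run imputeMissing() first")
  p <- colMeans(d) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    stop(sprintf("monomorphic SNP(s) present (%s); apply the MAF filter first",
                 paste(utils::head(colnames(d)[mono], 5), collapse = ", ")))
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero VanRaden denominator; no segregating SNPs")
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  new("GRM", values = G, denominator = denom, alleleFreqs = p)
}
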