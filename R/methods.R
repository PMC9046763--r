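#' Construct a GenotypePanel
#'
#' @param dosages numeric matrix of alternate-allele dosages (individuals x
#'   SNPs). Rownames/colnames are used as ids; generated when absent.
#' @param chrom chromosome per SNP.
#' @param pos 1-based physical position per SNP.
#' @param individualIds,snpIds optional ids overriding the dimnames.
#' @return a [GenotypePanel-class]. SNPs are reordered to genome order
#'   (chromosome, then position).
#' @examples
#' gp <- GenotypePanel(matrix(c(0, 2, 2, 0), 2), chrom = c("1", "1"), pos = c(100L, 200L))
#' nSnps(gp)
#' @export
GenotypePanel <- function(dosages, chrom, pos, individualIds = NULL, snpIds = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (!is.null(individualIds)) rownames(dosages) <- individualIds
  if (!is.null(snpIds)) colnames(dosages) <- snpIds
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ind_%d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("snp_%d", seq_len(ncol(dosages)))
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ord <- order(.chromRank(chrom), pos)
  new("GenotypePanel", dosages = dosages[, ord, drop = FALSE],
      chrom = chrom[ord], pos = pos[ord])
}

# numeric-aware chromosome ordering ("2" before "10", names after numbers)
.chromRank <- function(chrom) {
  suppress <- function(x) suppressWarnings(as.numeric(x))
  num <- suppress(sub("^chr", "", chrom))
  ifelse(is.na(num), rank(chrom, ties.method = "min") + 1e6, num)
}

#' @rdname GenotypePanel
#' @export
setMethod("dosages", "GenotypePanel", function(x, ...) x@dosages)

#' @rdname GenotypePanel
#' @export
setMethod("individualIds", "GenotypePanel", function(x, ...) rownames(x@dosages))

#' @rdname GenotypePanel
#' @export
setMethod("snpIds", "GenotypePanel", function(x, ...) colnames(x@dosages))

#' @rdname GenotypePanel
#' @export
setMethod("snpMap", "GenotypePanel", function(x, ...) {
  data.frame(snp = colnames(x@dosages), chrom = x@chrom, pos = x@pos,
             stringsAsFactors = FALSE)
})

#' @rdname GenotypePanel
#' @export
setMethod("nIndividuals", "GenotypePanel", function(x, ...) nrow(x@dosages))

#' @rdname GenotypePanel
#' @export
setMethod("nSnps", "GenotypePanel", function(x, ...) ncol(x@dosages))

setMethod("show", "GenotypePanel", function(object) {
  d <- object@dosages
  nmiss <- sum(is.na(d))
  cat(sprintf("GenotypePanel: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(d), ncol(d), length(unique(object@chrom))))
  cat(sprintf("  missing dosages: %d (%.2f%%)\n", nmiss, 100 * nmiss / length(d)))
})

# subset by individuals (i) and/or SNPs (j); keeps genome order
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  if (is.character(i)) i <- match(i, rownames(x@dosages))
  if (is.character(j)) j <- match(j, colnames(x@dosages))
  if (is.logical(j)) j <- which(j)
  j <- sort(j)
  new("GenotypePanel", dosages = x@dosages[i, j, drop = FALSE],
      chrom = x@chrom[j], pos = x@pos[j])
})

#' Construct a GRM object directly
#'
#' Mostly internal; use [vanRadenGRM()] to build one from a panel.
#' @param values symmetric relationship matrix with id dimnames.
#' @param denominator scaling constant \eqn{2\sum_j p_j(1-p_j)}.
#' @param alleleFreqs per-SNP allele frequencies used for centering.
#' @return a [GRM-class].
#' @export
GRM <- function(values, denominator, alleleFreqs = numeric()) {
  new("GRM", values = values, denominator = denominator, alleleFreqs = alleleFreqs)
}

#' @rdname GRM
#' @export
setMethod("individualIds", "GRM", function(x, ...) rownames(x@values))

#' @rdname GRM
#' @export
setMethod("alleleFreqs", "GRM", function(x, ...) x@alleleFreqs)

#' @rdname GRM
#' @export
setMethod("nIndividuals", "GRM", function(x, ...) nrow(x@values))

#' @export
setMethod("as.matrix", "GRM", function(x, ...) x@values)

#' @export
setMethod("[", "GRM", function(x, i, j, ..., drop = FALSE) {
  if (missing(j)) j <- i
  if (is.character(i)) i <- match(i, rownames(x@values))
  if (is.character(j)) j <- match(j, colnames(x@values))
  new("GRM", values = x@values[i, j, drop = FALSE],
      denominator = x@denominator, alleleFreqs = x@alleleFreqs)
})

setMethod("show", "GRM", function(object) {
  cat(sprintf("GRM: %d individuals, denominator 2*sum(p(1-p)) = %.4f\n",
              nrow(object@values), object@denominator))
  cat(sprintf("  mean diagonal: %.4f\n", mean(diag(object@values))))
})

#' @rdname ModelFit
#' @export
setMethod("varComp", "ModelFit", function(x, ...)
  c(Vg = x@Vg, Ve = x@Ve, sdVg = x@sdVg, sdVe = x@sdVe))

#' @rdname ModelFit
#' @export
setMethod("gebv", "ModelFit", function(x, ...) x@gebv)

#' @rdname ModelFit
#' @export
setMethod("markerEffects", "ModelFit", function(x, ...) x@markerEffects)

#' @rdname ModelFit
#' @export
setMethod("inclusionProb", "ModelFit", function(x, ...) x@inclusionProb)

#' @rdname ModelFit
#' @export
setMethod("fixedEffects", "ModelFit", function(x, ...) x@fixedEffects)

#' @rdname heritability
#' @export
setMethod("heritability", signature(x = "ModelFit", Ve = "missing"),
  function(x, Ve, ...) x@h2)

#' @rdname heritability
#' @export
setMethod("heritability", signature(x = "numeric", Ve = "numeric"),
  function(x, Ve, ...) {
    if (x < 0 || Ve < 0) stop("variance components must be non-negative")
    if (x + Ve == 0) stop("Vg + Ve must be > 0")
    x / (x + Ve)
  })

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit [%s]: n = %d training individuals\n",
              object@modelName, length(object@gebv)))
  cat(sprintf("  Vg = %.4g, Ve = %.4g, h2 = %.3f%s\n",
              object@Vg, object@Ve, object@h2,
              if (isTRUE(object@boundary)) " (boundary)" else ""))
  if (!is.null(object@markerEffects))
    cat(sprintf("  %d posterior-mean marker effects\n", length(object@markerEffects)))
})

#' @export
setMethod("as.data.frame", "GwasResult", function(x, ...) x@snps)

setMethod("show", "GwasResult", function(object) {
  cat(sprintf("GwasResult: %d SNPs tested\n", object@nTests))
  cat(sprintf("  Bonferroni p = %.3g, suggestive p = %.3g, lambda_GC = %.3f\n",
              object@bonferroniP, object@suggestiveP, object@lambdaGc))
  cat(sprintf("  hits: %d genome-wide, %d suggestive\n",
              sum(object@snps$p < object@bonferroniP),
              sum(object@snps$p < object@suggestiveP)))
})

#' @rdname FoldPlan
#' @export
setMethod("foldAssignments", "FoldPlan", function(x, ...) x@assignments)

#' @rdname FoldPlan
#' @export
setMethod("nIndividuals", "FoldPlan", function(x, ...) ncol(x@assignments))

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d individuals, %d folds x %d repeats (base seed %d)\n",
              ncol(object@assignments), object@k, nrow(object@assignments),
              object@baseSeed))
})

#' @rdname CvReport
#' @export
setMethod("cvCells", "CvReport", function(x, ...) x@cells)

#' Summarise a CvReport
#'
#' Mean and SD of predictability over all repeat x fold cells, per model and
#' trait (and per panel size / strategy when present).
#' @rdname CvReport
#' @export
setMethod("cvSummary", "CvReport", function(x, ...) {
  cells <- x@cells
  keys <- intersect(c("model", "trait", "panelSize", "strategy"), names(cells))
  split_keys <- interaction(cells[keys], drop = TRUE)
  out <- do.call(rbind, lapply(split(cells, split_keys), function(df) {
    data.frame(df[1, keys, drop = FALSE],
               mean = mean(df$r, na.rm = TRUE),
               sd = stats::sd(df$r, na.rm = TRUE),
               n = sum(!is.na(df$r)), row.names = NULL)
  }))
  rownames(out) <- NULL
  out
})

setMethod("show", "CvReport", function(object) {
  cat(sprintf("CvReport: %d cells (%d failed)\n", nrow(object@cells), object@nFailed))
  print(cvSummary(object), digits = 3)
})

setMethod("show", "DensityCurve", function(object) {
  cat(sprintf("DensityCurve [%s]: %d panel sizes (nested subsets)\n",
              object@strategy, length(object@sizes)))
  print(object@summary, digits = 3)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d individuals x %d SNPs on %d chromosomes, %d QTL\n",
              object@nIndividuals, object@nSnps, object@nChromosomes, object@nQtl))
  cat(sprintf("  h2 targets: %s; MAF in [%.2f, %.2f]; seed %d\n",
              paste(format(object@heritabilities), collapse = "/"),
              object@mafRange[1], object@mafRange[2], object@seed))
})

setMethod("show", "QcReport", function(object) {
  cat("QcReport:\n")
  cat(sprintf("  individuals removed: %d\n", object@nIndividualsRemoved))
  cat(sprintf("  SNPs removed (call rate / MAF / prune): %d / %d / %d\n",
              object@nSnpsRemovedCallrate, object@nSnpsRemovedMaf,
              object@nSnpsRemovedPrune))
})
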