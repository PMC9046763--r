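#' @rdname GenotypePanel
#' @param x an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname GenotypePanel
#' @export
setGeneric("individualIds", function(x, ...) standardGeneric("individualIds"))

#' @rdname GenotypePanel
#' @export
setGeneric("snpIds", function(x, ...) standardGeneric("snpIds"))

#' @rdname GenotypePanel
#' @export
setGeneric("snpMap", function(x, ...) standardGeneric("snpMap"))

#' @rdname GenotypePanel
#' @export
setGeneric("nIndividuals", function(x, ...) standardGeneric("nIndividuals"))

#' @rdname GenotypePanel
#' @export
setGeneric("nSnps", function(x, ...) standardGeneric("nSnps"))

#' @rdname GRM
#' @param x an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("alleleFreqs", function(x, ...) standardGeneric("alleleFreqs"))

#' @rdname ModelFit
#' @param x an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("varComp", function(x, ...) standardGeneric("varComp"))

#' @rdname ModelFit
#' @export
setGeneric("gebv", function(x, ...) standardGeneric("gebv"))

#' @rdname ModelFit
#' @export
setGeneric("markerEffects", function(x, ...) standardGeneric("markerEffects"))

#' @rdname ModelFit
#' @export
setGeneric("inclusionProb", function(x, ...) standardGeneric("inclusionProb"))

#' @rdname ModelFit
#' @export
setGeneric("fixedEffects", function(x, ...) standardGeneric("fixedEffects"))

#' Narrow-sense heritability from variance components
#'
#' Computes \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)}, the fraction
#' of phenotypic variance attributable to additive genetic variance.
#'
#' @param x additive genetic variance \eqn{\sigma_g^2} (a non-negative
#'   number), or a [ModelFit-class] object.
#' @param Ve residual variance \eqn{\sigma_e^2} (ignored for `ModelFit`).
#' @param ... further arguments for methods.
#' @return heritability in `[0, 1]`.
#' @examples
#' heritability(454.89, 709.52)  # 0.39 at two decimals
#' @export
setGeneric("heritability", function(x, Ve, ...) standardGeneric("heritability"))

#' Predict genomic breeding values for new individuals
#'
#' For Bayesian marker-effect fits, new genotypes are centered with the
#' *training* allele frequencies and multiplied by the posterior-mean marker
#' effects. For GBLUP, prediction is the conditional mean given the training
#' phenotypes, computed from the train/test blocks of a joint genomic
#' relationship matrix.
#'
#' @param fit a [ModelFit-class].
#' @param newdata a [GenotypePanel-class] of the new individuals on the
#'   training SNP set (Bayesian models), or a joint [GRM-class] containing
#'   both training and new individuals (GBLUP).
#' @param ... further arguments: for the GBLUP path, `y` (named training
#'   phenotypes) when the fit was produced outside [runCV()].
#' @return named numeric vector of predicted breeding values.
#' @export
setGeneric("predictGebv", function(fit, newdata, ...) standardGeneric("predictGebv"))

#' @rdname FoldPlan
#' @param x an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("foldAssignments", function(x, ...) standardGeneric("foldAssignments"))

#' @rdname CvReport
#' @param x an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("cvCells", function(x, ...) standardGeneric("cvCells"))

#' @rdname CvReport
#' @export
setGeneric("cvSummary", function(x, ...) standardGeneric("cvSummary"))
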