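#' Settings for the Gibbs samplers
#'
#' MCMC run lengths and prior hyperparameters for the Bayesian alphabet
#' models. Two presets are provided: `"full"` (50,000 iterations, 5,000
#' burn-in, thinning 5 — the production analysis settings) and `"desk"`
#' (6,000 / 1,000 / 5 — for tests and quick exploration; posterior-mean
#' heritabilities on the bundled synthetic fixtures move by less than 0.02
#' when the chain is doubled).
#'
#' @slot iterations,burnIn,thin chain length, burn-in, thinning interval.
#' @slot pi prior probability that a marker has a *null* effect
#'   (BayesB/BayesC only; default 0.95).
#' @slot priorDf degrees of freedom of the scaled-inverse-chi-square priors
#'   on the residual and marker variances.
#' @slot samplePi when `TRUE`, `pi` is sampled with a uniform prior instead
#'   of being fixed.
#' @slot seed integer seed for the chain.
#' @exportClass GibbsSettings
setClass("GibbsSettings",
  slots = c(iterations = "integer", burnIn = "integer", thin = "integer",
            pi = "numeric", priorDf = "numeric", samplePi = "logical",
            seed = "integer")
)

setValidity("GibbsSettings", function(object) {
  msg <- character()
  if (object@burnIn >= object@iterations) msg <- c(msg, "burnIn must be < iterations")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@pi < 0 || object@pi >= 1) msg <- c(msg, "pi must lie in [0, 1)")
  if (object@priorDf <= 0) msg <- c(msg, "priorDf must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname GibbsSettings-class
#' @param preset `"full"` or `"desk"`; individual arguments override the
#'   preset values.
#' @param iterations,burnIn,thin,pi,priorDf,samplePi,seed see slots.
#' @return a [GibbsSettings-class].
#' @examples
#' gibbsSettings("desk", seed = 42)
#' @export
gibbsSettings <- function(preset = c("full", "desk"), iterations = NULL,
                          burnIn = NULL, thin = NULL, pi = 0.95,
                          priorDf = 5, samplePi = FALSE, seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
                full = c(50000L, 5000L, 5L),
                desk = c(6000L, 1000L, 5L))
  new("GibbsSettings",
      iterations = as.integer(if (is.null(iterations)) def[1] else iterations),
      burnIn = as.integer(if (is.null(burnIn)) def[2] else burnIn),
      thin = as.integer(if (is.null(thin)) def[3] else thin),
      pi = pi, priorDf = priorDf, samplePi = samplePi,
      seed = as.integer(seed))
}

setMethod("show", "GibbsSettings", function(object) {
  cat(sprintf("GibbsSettings: %d iterations, %d burn-in, thin %d, pi = %.3g%s, seed %d\n",
              object@iterations, object@burnIn, object@thin, object@pi,
              if (object@samplePi) " (sampled)" else " (fixed)", object@seed))
})

.BAYES_CODES <- c(BayesRR = 0L, BayesA = 1L, BayesB = 2L, BayesC = 3L, BayesL = 4L)

#' Fit a Bayesian whole-genome regression model by Gibbs sampling
#'
#' Fits `y = Xb + Z alpha + e` where `Z` holds dosages centered by twice
#' the observed allele frequency and `alpha` carries one of five
#' "Bayesian alphabet" priors:
#'
#' * **BayesRR** — a common normal prior (the Bayesian counterpart of GBLUP);
#' * **BayesA** — per-marker variances with scaled-inverse-chi-square priors
#'   (heterogeneous shrinkage);
#' * **BayesB** — a spike at zero with probability `pi` plus a per-marker
#'   variance slab (variable selection with heterogeneous slab);
#' * **BayesC** — spike plus a common-variance slab;
#' * **BayesL** — the Bayesian LASSO: an exponential mixture of normals
#'   whose marginal is double-exponential, with the rate hyperparameter
#'   `lambda^2` given a gamma hyperprior and sampled.
#'
#' Prior scales are set from the data: the residual-variance prior mode is
#' half the phenotypic variance and the marker-variance prior mode is the
#' matching genomic-variance share divided by `sum(2 p (1 - p))` (and by
#' `1 - pi` for the spike models, since only that fraction of markers is
#' expected in the slab). Reported `Vg` is the *genomic* variance — the
#' posterior mean of `var(Z alpha)` across saved draws — which is directly
#' comparable with GBLUP's additive variance; `Ve` is the posterior mean
#' residual variance. Chains are deterministic given `settings@seed`.
#'
#' @param y named numeric phenotype vector.
#' @param panel imputed, QC'd [GenotypePanel-class] for the same ids.
#' @param model one of `"BayesRR"`, `"BayesA"`, `"BayesB"`, `"BayesC"`,
#'   `"BayesL"`.
#' @param settings a [GibbsSettings-class].
#' @param covariates optional fixed-effect covariate matrix (intercept is
#'   always included).
#' @return a [ModelFit-class] with posterior-mean marker effects, breeding
#'   values, inclusion probabilities (BayesB/C), and variance components.
#' @seealso [fitGBLUP()], [predictGebv()]
#' @export
fitBayes <- function(y, panel, model = c("BayesRR", "BayesA", "BayesB",
                                         "BayesC", "BayesL"),
                     settings = gibbsSettings("desk"), covariates = NULL) {
  model <- match.arg(model)
  stopifnot(is(panel, "GenotypePanel"), is(settings, "GibbsSettings"))
  validObject(settings)
  if (is.null(names(y))) stop("y must be named by individual id")
  if (anyNA(y)) stop("y must be complete (no NA)")
  if (stats::var(y) <= 0) stop("y has zero variance")
  if (!all(names(y) %in% individualIds(panel)))
    stop("panel does not cover all phenotyped individuals")
  d <- dosages(panel)[names(y), , drop = FALSE]
  if (anyNA(d)) stop("panel has missing dosages; run imputeMissing() first")

  n <- length(y); m <- ncol(d)
  p <- colMeans(d) / 2
  Z <- sweep(d, 2, 2 * p)
  W <- cbind(intercept = rep(1, n), covariates)

  vy <- stats::var(y)
  df <- settings@priorDf
  scaleResid <- 0.5 * vy * (df + 2) / df  # prior mode at vy/2
  msx <- sum(2 * p * (1 - p))
  s2aTarget <- 0.5 * vy / msx
  if (model %in% c("BayesB", "BayesC")) {
    s2aTarget <- s2aTarget / max(1 - settings@pi, 1e-8)
  }
  scaleMarker <- s2aTarget * (df + 2) / df
  # BayesL: gamma hyperprior on lambda^2 with mode at the value implying
  # the same marker-variance share (marginal var = 2 sigma2e / lambda^2)
  lambda2Shape <- 1.1
  lambda0sq <- 2 * (0.5 * vy) / s2aTarget
  lambda2Rate <- (lambda2Shape - 1) / lambda0sq

  restore <- .withSeed(settings@seed)
  on.exit(restore())
  res <- .gibbsWgr(y, Z, W, .BAYES_CODES[[model]],
                   settings@iterations, settings@burnIn, settings@thin,
                   settings@pi, df, scaleResid, df, scaleMarker,
                   lambda2Shape, lambda2Rate, settings@samplePi)

  Vg <- mean(res$varGDraws); Ve <- mean(res$veDraws)
  alpha <- as.numeric(res$alpha); names(alpha) <- colnames(d)
  u <- as.numeric(res$g); names(u) <- names(y)
  incl <- if (model %in% c("BayesB", "BayesC")) {
    pr <- as.numeric(res$delta); names(pr) <- colnames(d); pr
  } else NULL
  fe <- as.numeric(res$b)
  names(fe) <- colnames(W)

  new("ModelFit", modelName = model,
      Vg = Vg, Ve = Ve,
      sdVg = stats::sd(res$varGDraws), sdVe = stats::sd(res$veDraws),
      h2 = Vg / (Vg + Ve),
      fixedEffects = fe, gebv = u,
      markerEffects = alpha, inclusionProb = incl, alleleFreqs = p,
      mcmc = list(iterations = settings@iterations, burnIn = settings@burnIn,
                  thin = settings@thin, seed = settings@seed,
                  nSaved = res$nSaved, model = model,
                  varGDraws = as.numeric(res$varGDraws),
                  veDraws = as.numeric(res$veDraws)),
      boundary = FALSE)
}
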