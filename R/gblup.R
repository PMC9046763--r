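#' Fit GBLUP by restricted maximum likelihood
#'
#' Fits the mixed model `y = Xb + u + e`, `u ~ N(0, G sigma_g^2)`,
#' `e ~ N(0, I sigma_e^2)`, using the eigendecomposition of `G` to reduce
#' REML to a one-dimensional optimization over the variance ratio
#' `kappa = sigma_g^2 / sigma_e^2` (searched on the log scale over
#' `[1e-6, 1e6]`, convergence tolerance 1e-8). Fixed effects are estimated
#' by generalized least squares at the optimum and breeding values by BLUP.
#' Sampling SDs of the variance components come from the inverse observed
#' information of the restricted likelihood.
#'
#' @param y named numeric phenotype vector (names are individual ids
#'   present in the GRM); must be complete.
#' @param grm a [GRM-class] covering the phenotyped individuals.
#' @param covariates optional numeric matrix of fixed-effect covariates
#'   (rows matching `y`); an intercept is always included.
#' @return a [ModelFit-class] with `modelName = "GBLUP"`. The `mcmc` slot
#'   carries optimizer details and the precomputed `vinvResid` vector used
#'   by [predictGebv()] for new individuals.
#' @seealso [predictGebv()], [fitBayes()]
#' @export
fitGBLUP <- function(y, grm, covariates = NULL) {
  stopifnot(is(grm, "GRM"))
  if (is.null(names(y))) stop("y must be named by individual id")
  if (anyNA(y)) stop("y must be complete (no NA)")
  ids <- names(y)
  if (!all(ids %in% individualIds(grm)))
    stop("GRM does not cover all phenotyped individuals")
  G <- as.matrix(grm)[ids, ids]
  n <- length(y)
  X <- cbind(intercept = rep(1, n), covariates)
  p <- ncol(X)

  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values), 1))
    stop("GRM is not positive semidefinite")
  d <- pmax(ev$values, 0)
  U <- ev$vectors
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)

  profile <- function(logk) {
    k <- exp(logk)
    w <- 1 / (k * d + 1)
    XtWX <- crossprod(Xstar, Xstar * w)
    beta <- solve(XtWX, crossprod(Xstar, ystar * w))
    r <- ystar - drop(Xstar %*% beta)
    q <- sum(w * r^2)
    np <- n - p
    s2e <- q / np
    ll <- -0.5 * (np * log(s2e) + sum(log1p(k * d)) +
                    determinant(XtWX, logarithm = TRUE)$modulus + np)
    list(ll = as.numeric(ll), beta = drop(beta), r = r, w = w, s2e = s2e, k = k)
  }

  lo <- log(1e-6); hi <- log(1e6)
  opt <- stats::optimize(function(lk) -profile(lk)$ll, c(lo, hi), tol = 1e-8)
  sol <- profile(opt$minimum)
  boundary <- opt$minimum < lo + 1e-3 || opt$minimum > hi - 1e-3

  Ve <- sol$s2e
  Vg <- sol$k * Ve
  # BLUP in the rotated space: u = kappa * U diag(d) W r
  u <- drop(U %*% (sol$k * d * sol$w * sol$r))
  names(u) <- ids
  vinvResid <- drop(U %*% (sol$w * sol$r)) / Ve
  names(vinvResid) <- ids

  sds <- .remlComponentSds(d, Xstar, ystar, Vg, Ve)

  new("ModelFit", modelName = "GBLUP",
      Vg = Vg, Ve = Ve, sdVg = sds[1], sdVe = sds[2],
      h2 = Vg / (Vg + Ve),
      fixedEffects = sol$beta,
      gebv = u,
      markerEffects = NULL, inclusionProb = NULL, alleleFreqs = NULL,
      mcmc = list(optimizer = "Brent-log-ratio", logKappa = opt$minimum,
                  restrictedLL = sol$ll, vinvResid = vinvResid),
      boundary = boundary)
}

# restricted log-likelihood in (Vg, Ve); numeric observed information
.remlLL <- function(Vg, Ve, d, Xstar, ystar) {
  n <- length(ystar); p <- ncol(Xstar)
  v <- Vg * d + Ve
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  XtWX <- crossprod(Xstar, Xstar * w)
  beta <- solve(XtWX, crossprod(Xstar, ystar * w))
  r <- ystar - drop(Xstar %*% beta)
  -0.5 * (sum(log(v)) +
            as.numeric(determinant(XtWX, logarithm = TRUE)$modulus) +
            sum(w * r^2))
}

.remlComponentSds <- function(d, Xstar, ystar, Vg, Ve) {
  f <- function(par) .remlLL(par[1], par[2], d, Xstar, ystar)
  h <- tryCatch({
    eps <- pmax(c(Vg, Ve), 1e-8) * 1e-4
    H <- matrix(0, 2, 2)
    par <- c(Vg, Ve)
    for (i in 1:2) for (j in 1:2) {
      ei <- ej <- c(0, 0); ei[i] <- eps[i]; ej[j] <- eps[j]
      H[i, j] <- (f(par + ei + ej) - f(par + ei - ej) -
                    f(par - ei + ej) + f(par - ei - ej)) / (4 * eps[i] * eps[j])
    }
    cv <- solve(-H)
    sqrt(pmax(diag(cv), 0))
  }, error = function(e) c(NA_real_, NA_real_))
  h
}

#' @rdname predictGebv
#' @export
setMethod("predictGebv", signature(fit = "ModelFit", newdata = "GRM"),
  function(fit, newdata, ...) {
    if (fit@modelName != "GBLUP")
      stop("GRM-based prediction applies to GBLUP fits; give Bayesian fits a GenotypePanel")
    vinvResid <- fit@mcmc$vinvResid
    trainIds <- names(vinvResid)
    if (!all(trainIds %in% individualIds(newdata)))
      stop("joint GRM must contain all training individuals")
    newIds <- setdiff(individualIds(newdata), trainIds)
    if (!length(newIds)) stop("joint GRM contains no new individuals")
    Gnt <- as.matrix(newdata)[newIds, trainIds, drop = FALSE]
    out <- drop(Gnt %*% vinvResid) * fit@Vg
    names(out) <- newIds
    out
  })

#' @rdname predictGebv
#' @export
setMethod("predictGebv", signature(fit = "ModelFit", newdata = "GenotypePanel"),
  function(fit, newdata, ...) {
    if (is.null(fit@markerEffects))
      stop("marker-effect prediction requires a Bayesian fit; give GBLUP a joint GRM")
    alpha <- fit@markerEffects
    missingSnps <- setdiff(names(alpha), snpIds(newdata))
    if (length(missingSnps)) {
      stop(sprintf("new panel lacks %d training SNP(s): %s%s",
                   length(missingSnps),
                   paste(utils::head(missingSnps, 5), collapse = ", "),
                   if (length(missingSnps) > 5) ", ..." else ""))
    }
    d <- dosages(newdata)[, names(alpha), drop = FALSE]
    if (anyNA(d)) stop("new panel has missing dosages; impute first")
    Z <- sweep(d, 2, 2 * fit@alleleFreqs)  # training-frequency centering
    drop(Z %*% alpha)
  })
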