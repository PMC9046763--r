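#' Build a repeated k-fold cross-validation plan
#'
#' Each repeat is an independent uniformly random partition of the
#' individuals into `k` folds whose sizes differ by at most one (455
#' individuals with `k = 5` give five folds of 91, i.e. training sets of
#' 364). Repeat `r` is seeded as `baseSeed + r - 1`, so the plan is fully
#' reproducible and can be exported and shared across models: every model
#' evaluated against the same plan sees identical training/testing splits.
#'
#' @param ids individual ids (or a single integer n, generating ids).
#' @param k number of folds (default 5).
#' @param nRepeats number of repeats (default 40).
#' @param baseSeed integer base seed.
#' @return a [FoldPlan-class].
#' @examples
#' plan <- makeFolds(455, k = 5, nRepeats = 2, baseSeed = 1)
#' table(foldAssignments(plan)[1, ])
#' @export
makeFolds <- function(ids, k = 5L, nRepeats = 40L, baseSeed = 1L) {
  if (length(ids) == 1L && is.numeric(ids)) ids <- sprintf("ind_%03d", seq_len(ids))
  n <- length(ids)
  k <- as.integer(k); nRepeats <- as.integer(nRepeats)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("n must be >= k")
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  a <- matrix(0L, nRepeats, n, dimnames = list(NULL, ids))
  for (r in seq_len(nRepeats)) {
    restore <- .withSeed(as.integer(baseSeed) + r - 1L)
    perm <- sample.int(n)
    restore()
    a[r, perm] <- rep.int(seq_len(k), sizes)
  }
  new("FoldPlan", assignments = a, k = k, baseSeed = as.integer(baseSeed))
}

#' Predictability of genomic breeding values
#'
#' The Pearson correlation between predicted breeding values and observed
#' phenotypes in a held-out test set — the operational measure of
#' predictive ability in genomic selection.
#'
#' @param gebvHat predicted breeding values.
#' @param yTest observed test phenotypes (same length, >= 3).
#' @return correlation coefficient in `[-1, 1]`.
#' @export
predictability <- function(gebvHat, yTest) {
  if (length(gebvHat) != length(yTest)) stop("lengths differ")
  if (length(yTest) < 3) stop("need at least 3 test individuals")
  if (stats::sd(gebvHat) == 0 || stats::sd(yTest) == 0)
    stop("zero-variance input; predictability undefined")
  stats::cor(gebvHat, yTest)
}

.fitPredictCell <- function(y, panel, grmFull, model, trainIds, testIds,
                            settings, cellSeed) {
  yTrain <- y[trainIds]  # test phenotypes are never passed to any fit
  if (model == "GBLUP") {
    fit <- fitGBLUP(yTrain, grmFull[trainIds, trainIds])
    joint <- grmFull[c(trainIds, testIds), c(trainIds, testIds)]
    pred <- predictGebv(fit, joint)[testIds]
  } else {
    s <- settings
    s@seed <- as.integer(cellSeed)
    fit <- fitBayes(yTrain, panel[trainIds, ], model = model, settings = s)
    pred <- predictGebv(fit, panel[testIds, ])
  }
  pred
}

#' Cross-validated predictability of genomic prediction models
#'
#' For every repeat x fold x model cell: fit on the training individuals
#' only (allele frequencies and relationship matrices may use all
#' genotypes, but test *phenotypes* are never visible to a fit), predict
#' breeding values for the held-out fold, and record the predictability.
#' All models share the same [FoldPlan-class], so their cells are directly
#' comparable. Failed cells are recorded as `NA` and counted, and the run
#' continues.
#'
#' @param y named numeric phenotype vector.
#' @param panel imputed [GenotypePanel-class] covering `names(y)`.
#' @param models character vector from `c("GBLUP", "BayesA", "BayesB",
#'   "BayesC", "BayesL", "BayesRR")`.
#' @param foldPlan a [FoldPlan-class] over `names(y)`.
#' @param settings [GibbsSettings-class] for the Bayesian models; each cell
#'   uses seed `settings@seed + 1000 * rep + fold` for chain independence.
#' @param trait trait label recorded in the report.
#' @param returnGebv keep per-cell predictions (attribute `"predictions"`
#'   of the returned report) for auditing.
#' @return a [CvReport-class].
#' @seealso [makeFolds()], [cvSummary()]
#' @export
runCV <- function(y, panel, models = "GBLUP", foldPlan,
                  settings = gibbsSettings("desk"), trait = "trait",
                  returnGebv = FALSE) {
  stopifnot(is(panel, "GenotypePanel"), is(foldPlan, "FoldPlan"))
  if (is.null(names(y))) stop("y must be named by individual id")
  badModels <- setdiff(models, .MODEL_NAMES)
  if (length(badModels)) stop("unknown model(s): ", paste(badModels, collapse = ", "))
  ids <- colnames(foldAssignments(foldPlan))
  if (!setequal(ids, names(y))) stop("fold plan ids must match names(y)")
  grmFull <- if ("GBLUP" %in% models) vanRadenGRM(panel[names(y), ]) else NULL

  a <- foldAssignments(foldPlan)
  cells <- expand.grid(model = models, rep = seq_len(nrow(a)),
                       fold = seq_len(foldPlan@k), stringsAsFactors = FALSE)
  rvec <- rep(NA_real_, nrow(cells))
  nFailed <- 0L
  preds <- if (returnGebv) vector("list", nrow(cells)) else NULL
  for (i in seq_len(nrow(cells))) {
    r <- cells$rep[i]; f <- cells$fold[i]; model <- cells$model[i]
    testIds <- ids[a[r, ] == f]
    trainIds <- ids[a[r, ] != f]
    res <- tryCatch({
      pred <- .fitPredictCell(y, panel, grmFull, model, trainIds, testIds,
                              settings, settings@seed + 1000L * r + f)
      if (returnGebv) preds[[i]] <- pred
      predictability(pred, y[testIds])
    }, error = function(e) NA_real_)
    if (is.na(res)) nFailed <- nFailed + 1L
    rvec[i] <- res
  }
  out <- new("CvReport",
             cells = data.frame(model = cells$model, trait = trait,
                                rep = cells$rep, fold = cells$fold, r = rvec,
                                stringsAsFactors = FALSE),
             nFailed = nFailed)
  if (returnGebv) attr(out, "predictions") <- preds
  out
}

#' Select a SNP subset under a sampling strategy
#'
#' Three strategies for building reduced-density panels, all cumulative
#' (subsets at increasing sizes are nested for `gwas_ranked` and `random`):
#'
#' * `gwas_ranked` — the `size` most significant SNPs by ascending
#'   association p-value (ties broken by genome order);
#' * `random` — a seeded uniform draw without replacement; the same seed
#'   yields nested subsets across sizes;
#' * `evenly_spaced` — indices `floor(j (m-1) / (size-1))`, `j = 0 ..
#'   size-1`, over the genome-ordered panel, deduplicated and padded with
#'   the nearest unused indices.
#'
#' @param panel a [GenotypePanel-class] (genome-ordered).
#' @param strategy `"gwas_ranked"`, `"random"` or `"evenly_spaced"`.
#' @param size subset size in `[1, nSnps]`.
#' @param ranking a [GwasResult-class] (required for `gwas_ranked`).
#' @param seed seed for the `random` strategy.
#' @return sorted integer vector of SNP indices into the panel.
#' @export
selectSnps <- function(panel, strategy = c("gwas_ranked", "random", "evenly_spaced"),
                       size, ranking = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  m <- nSnps(panel)
  size <- as.integer(size)
  if (size < 1L || size > m) stop("size must lie in [1, nSnps]")
  switch(strategy,
    gwas_ranked = {
      if (is.null(ranking)) stop("gwas_ranked requires a GwasResult ranking")
      tab <- as.data.frame(ranking)
      if (!setequal(tab$id, snpIds(panel)))
        stop("ranking SNP set does not match the panel")
      ord <- tab$id[order(tab$p)]  # tab rows are in genome order: stable ties
      sort(match(ord[seq_len(size)], snpIds(panel)))
    },
    random = {
      restore <- .withSeed(as.integer(seed))
      perm <- sample.int(m)
      restore()
      sort(perm[seq_len(size)])
    },
    evenly_spaced = {
      idx <- if (size == 1L) (m + 1L) %/% 2L else {
        as.integer(floor((seq_len(size) - 1) * (m - 1) / (size - 1))) + 1L
      }
      sel <- unique(idx)
      if (length(sel) < size) {
        unused <- setdiff(seq_len(m), sel)
        dups <- idx[duplicated(idx)]
        for (d in dups) {
          if (!length(unused)) break
          pick <- unused[which.min(abs(unused - d))]
          sel <- c(sel, pick)
          unused <- setdiff(unused, pick)
        }
      }
      sort(sel[seq_len(min(size, length(sel)))])
    })
}

.defaultSizeGrid <- c(50L, 100L, 200L, 300L, 500L, 800L, 1000L, 2000L, 3000L,
                      5000L, 8000L, 10000L, 13000L, 16162L)

#' Marker-density reduction experiment
#'
#' Evaluates cross-validated predictability of GBLUP (by default) on
#' reduced SNP panels of increasing size under one sampling strategy.
#' The default size grid is the 14-point design 50, 100, 200, 300, 500,
#' 800, 1000, 2000, 3000, 5000, 8000, 10000, 13000, all — scaled
#' proportionally when the panel has fewer than ~16 K SNPs. In
#' `gwas_ranked` mode the association ranking is, by default, recomputed
#' *within each training set* so that no test-phenotype information leaks
#' into marker selection; `rankOnFullData = TRUE` instead uses a single
#' global ranking computed on all phenotyped individuals (the common but
#' leakage-prone shortcut).
#'
#' @param y named phenotype vector.
#' @param panel imputed [GenotypePanel-class].
#' @param foldPlan a [FoldPlan-class].
#' @param strategy `"gwas_ranked"`, `"random"` or `"evenly_spaced"`.
#' @param sizes increasing panel sizes (default: the scaled 14-point grid).
#' @param model fitted model per cell (default `"GBLUP"`).
#' @param rankOnFullData use one global GWAS ranking (see above).
#' @param settings [GibbsSettings-class] for Bayesian `model`s.
#' @param randomSeed seed of the `random` strategy's (nested) draw.
#' @return a [DensityCurve-class].
#' @export
densityExperiment <- function(y, panel, foldPlan,
                              strategy = c("gwas_ranked", "random", "evenly_spaced"),
                              sizes = NULL, model = "GBLUP",
                              rankOnFullData = FALSE,
                              settings = gibbsSettings("desk"),
                              randomSeed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(is(panel, "GenotypePanel"), is(foldPlan, "FoldPlan"))
  m <- nSnps(panel)
  if (is.null(sizes)) {
    grid <- .defaultSizeGrid
    if (m < max(grid)) {
      grid <- unique(pmax(10L, as.integer(round(grid * m / max(grid)))))
    }
    sizes <- sort(unique(pmin(grid, m)))
    if (sizes[length(sizes)] != m) sizes <- c(sizes, m)
  }
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  if (max(sizes) > m) stop("sizes must not exceed nSnps")

  ids <- colnames(foldAssignments(foldPlan))
  if (!setequal(ids, names(y))) stop("fold plan ids must match names(y)")
  a <- foldAssignments(foldPlan)

  globalRanking <- NULL
  if (strategy == "gwas_ranked" && rankOnFullData) {
    grmAll <- vanRadenGRM(panel[names(y), ])
    globalRanking <- lmmGwas(y, panel[names(y), ], grmAll)
  }

  cells <- list()
  for (r in seq_len(nrow(a))) {
    for (f in seq_len(foldPlan@k)) {
      testIds <- ids[a[r, ] == f]
      trainIds <- ids[a[r, ] != f]
      ranking <- globalRanking
      if (strategy == "gwas_ranked" && !rankOnFullData) {
        trainPanel <- panel[trainIds, ]
        ranking <- lmmGwas(y[trainIds], trainPanel, vanRadenGRM(trainPanel))
      }
      for (s in sizes) {
        rcell <- tryCatch({
          idx <- selectSnps(panel, strategy, s, ranking = ranking,
                            seed = randomSeed)
          sub <- panel[, idx]
          subGrm <- if (model == "GBLUP") vanRadenGRM(sub[names(y), ]) else NULL
          pred <- .fitPredictCell(y, sub, subGrm, model,
                                  trainIds, testIds, settings,
                                  settings@seed + 1000L * r + f)
          predictability(pred, y[testIds])
        }, error = function(e) NA_real_)
        cells[[length(cells) + 1L]] <- data.frame(
          model = model, trait = "trait", rep = r, fold = f,
          panelSize = s, strategy = strategy, r = rcell,
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, cells)
  summ <- do.call(rbind, lapply(split(cells, cells$panelSize), function(df) {
    data.frame(panelSize = df$panelSize[1], mean = mean(df$r, na.rm = TRUE),
               sd = stats::sd(df$r, na.rm = TRUE), n = sum(!is.na(df$r)))
  }))
  summ <- summ[order(summ$panelSize), ]
  rownames(summ) <- NULL
  new("DensityCurve", strategy = strategy, sizes = sizes,
      summary = summ, cells = cells)
}
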