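#' Read, validate and write pipeline configurations
#'
#' The pipeline configuration is a plain YAML document with blocks
#' `paths` (genotypes, phenotypes, annotation, outDir), `simulate`
#' (generator settings, used when no genotype path is given), `qc`,
#' `gwas`, `fit`, `cv`, `density`, and a global `seed`. Reading and
#' writing round-trip exactly; [validatePipelineConfig()] checks every
#' threshold against its documented domain before any stage runs.
#'
#' @param path YAML file.
#' @return named list (the configuration).
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname readPipelineConfig
#' @param config configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  validatePipelineConfig(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

.cfgGet <- function(cfg, block, key, default) {
  v <- cfg[[block]][[key]]
  if (is.null(v)) default else v
}

#' @rdname readPipelineConfig
#' @export
validatePipelineConfig <- function(config) {
  inDomain <- function(x, lo, hi, what) {
    if (!is.null(x) && (!is.numeric(x) || x <= lo || x > hi))
      stop(sprintf("%s must lie in (%g, %g]", what, lo, hi))
  }
  inDomain(config$qc$minIndCallRate, 0, 1, "qc$minIndCallRate")
  inDomain(config$qc$minSnpCallRate, 0, 1, "qc$minSnpCallRate")
  inDomain(config$qc$minMaf, 0, 0.5, "qc$minMaf")
  inDomain(config$qc$pruneR2, 0, 1, "qc$pruneR2")
  pi0 <- config$fit$pi
  if (!is.null(pi0) && (pi0 < 0 || pi0 >= 1)) stop("fit$pi must lie in [0, 1)")
  models <- c(config$fit$models, config$cv$models)
  bad <- setdiff(models, .MODEL_NAMES)
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  strat <- config$density$strategy
  if (!is.null(strat) && !strat %in% c("gwas_ranked", "random", "evenly_spaced"))
    stop("unknown density strategy: ", strat)
  h2 <- config$simulate$heritabilities
  if (!is.null(h2) && any(h2 < 0 | h2 > 1)) stop("heritabilities must lie in [0, 1]")
  invisible(TRUE)
}

.writeStamped <- function(df, path, stage, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# aquaGS stage=%s seed=%d", stage, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: genotype input (or synthetic
#' generation), quality control, GRM construction, optional GWAS, and the
#' optional model-fitting / cross-validation / marker-density stages.
#' Every artifact is a headed TSV or JSON file in `paths$outDir`; a
#' `manifest.json` records input checksums, the seed, the package version
#' and the per-stage input/output dimensions. Rerunning with an identical
#' configuration reproduces all artifacts (randomness is derived
#' deterministically from the global `seed`).
#'
#' @param config configuration list or YAML path
#'   (see [readPipelineConfig()]).
#' @return invisibly, a list with the artifact paths and the manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validatePipelineConfig(config)
  outDir <- config$paths$outDir
  if (is.null(outDir)) stop("paths$outDir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(if (is.null(config$seed)) 1L else config$seed)
  manifest <- list(seed = seed,
                   package = as.character(utils::packageVersion("aquaGS")),
                   stages = list(), inputs = list(), failed = NULL)
  artifacts <- character()
  finish <- function() {
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(list(artifacts = artifacts, manifest = manifest))
  }

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed <<- list(stage = name, message = conditionMessage(e))
      finish()
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- input / simulate ------------------------------------------------
  truthPath <- NULL
  if (!is.null(config$paths$genotypes)) {
    panel <- step("input", readGenotypes(config$paths$genotypes))
    phen <- step("input", readPhenotypes(config$paths$phenotypes))
    manifest$inputs <- lapply(
      c(genotypes = config$paths$genotypes, phenotypes = config$paths$phenotypes),
      function(p) unname(tools::md5sum(p)))
  } else {
    sim <- config$simulate
    cfg <- step("simulate", do.call(simConfig, c(sim, list(seed = seed))))
    panel <- step("simulate", simulateGenotypes(cfg))
    ph <- step("simulate", simulatePhenotypes(imputeMissing(panel), cfg))
    phen <- ph$phenotypes
    artifacts <- c(artifacts,
                   writeGenotypes(panel, file.path(outDir, "genotypes")))
    artifacts <- c(artifacts, .writeStamped(phen, file.path(outDir, "phenotypes.tsv"),
                                            "simulate", seed))
    eff <- ph$truth@trueEffects
    truthPath <- .writeStamped(
      data.frame(snp = rownames(eff), eff, check.names = FALSE),
      file.path(outDir, "qtl_effects.tsv"), "simulate", seed)
    artifacts <- c(artifacts, truthPath)
  }
  manifest$stages$input <- list(n = nIndividuals(panel), m = nSnps(panel))

  # --- qc ---------------------------------------------------------------
  qc <- step("qc", runQc(panel,
                         minIndCallRate = .cfgGet(config, "qc", "minIndCallRate", 0.9),
                         minSnpCallRate = .cfgGet(config, "qc", "minSnpCallRate", 0.9),
                         minMaf = .cfgGet(config, "qc", "minMaf", 0.05),
                         prune = isTRUE(config$qc$prune),
                         pruneR2 = .cfgGet(config, "qc", "pruneR2", 0.8),
                         pruneWindow = .cfgGet(config, "qc", "pruneWindow", 50L)))
  panel <- qc$panel
  qcRep <- qc$report
  jsonlite::write_json(
    list(nIndividualsRemoved = qcRep@nIndividualsRemoved,
         nSnpsRemovedCallrate = qcRep@nSnpsRemovedCallrate,
         nSnpsRemovedMaf = qcRep@nSnpsRemovedMaf,
         nSnpsRemovedPrune = qcRep@nSnpsRemovedPrune,
         thresholds = as.list(qcRep@thresholds)),
    file.path(outDir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, file.path(outDir, "qc_report.json"))
  manifest$stages$qc <- list(n = nIndividuals(panel), m = nSnps(panel))

  phen <- matchPhenotypes(panel, phen)
  traits <- setdiff(names(phen), "id")

  # --- grm --------------------------------------------------------------
  grm <- step("grm", vanRadenGRM(panel[phen$id, ]))
  artifacts <- c(artifacts, writeGrm(grm, file.path(outDir, "grm")))
  manifest$stages$grm <- list(n = nIndividuals(grm),
                              meanDiag = mean(diag(as.matrix(grm))))

  getY <- function(trait) {
    y <- phen[[trait]]
    names(y) <- phen$id
    y[!is.na(y)]
  }

  # --- gwas -------------------------------------------------------------
  if (isTRUE(config$gwas$enabled)) {
    trait <- .cfgGet(config, "gwas", "trait", traits[1])
    res <- step("gwas", lmmGwas(getY(trait), panel, grm,
                                suggestiveNeglog10 = .cfgGet(config, "gwas",
                                                             "suggestiveNeglog10", 4)))
    tab <- as.data.frame(res)
    tab$neglog10p <- -log10(tab$p)
    artifacts <- c(artifacts, .writeStamped(tab, file.path(outDir, "gwas.tsv"),
                                            "gwas", seed))
    jsonlite::write_json(list(nTests = res@nTests, bonferroniP = res@bonferroniP,
                              suggestiveP = res@suggestiveP,
                              lambdaGc = res@lambdaGc),
                         file.path(outDir, "gwas_thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(outDir, "gwas_thresholds.json"))
    if (!is.null(config$paths$annotation)) {
      hits <- tab[tab$p < res@suggestiveP, c("id", "chrom", "pos")]
      if (nrow(hits)) {
        cw <- step("gwas", candidateWindows(
          hits, config$paths$annotation,
          flankBp = .cfgGet(config, "gwas", "flankBp", 100000L)))
        artifacts <- c(artifacts, .writeStamped(
          cw, file.path(outDir, "candidate_windows.tsv"), "gwas", seed))
      }
    }
    manifest$stages$gwas <- list(m = res@nTests, lambdaGc = res@lambdaGc)
  }

  # --- fit --------------------------------------------------------------
  if (!is.null(config$fit$models)) {
    trait <- .cfgGet(config, "fit", "trait", traits[1])
    y <- getY(trait)
    settings <- gibbsSettings(.cfgGet(config, "fit", "preset", "desk"),
                              pi = .cfgGet(config, "fit", "pi", 0.95),
                              seed = seed)
    fits <- list()
    for (mod in config$fit$models) {
      fit <- step("fit", if (mod == "GBLUP") fitGBLUP(y, grm)
                  else fitBayes(y, panel[names(y), ], mod, settings))
      fits[[mod]] <- list(Vg = fit@Vg, Ve = fit@Ve, h2 = fit@h2,
                          sdVg = fit@sdVg, sdVe = fit@sdVe)
      artifacts <- c(artifacts, .writeStamped(
        data.frame(id = names(gebv(fit)), gebv = gebv(fit)),
        file.path(outDir, sprintf("gebv_%s_%s.tsv", mod, trait)), "fit", seed))
      if (!is.null(markerEffects(fit))) {
        artifacts <- c(artifacts, .writeStamped(
          data.frame(snp = names(markerEffects(fit)),
                     effect = markerEffects(fit)),
          file.path(outDir, sprintf("effects_%s_%s.tsv", mod, trait)),
          "fit", seed))
      }
    }
    jsonlite::write_json(fits, file.path(outDir, "fit_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(outDir, "fit_summary.json"))
    manifest$stages$fit <- list(trait = trait, models = config$fit$models)
  }

  # --- cv ---------------------------------------------------------------
  if (isTRUE(config$cv$enabled)) {
    trait <- .cfgGet(config, "cv", "trait", traits[1])
    y <- getY(trait)
    plan <- makeFolds(names(y), k = .cfgGet(config, "cv", "folds", 5L),
                      nRepeats = .cfgGet(config, "cv", "repeats", 40L),
                      baseSeed = seed)
    artifacts <- c(artifacts, .writeStamped(
      data.frame(id = colnames(foldAssignments(plan)),
                 t(foldAssignments(plan)), check.names = FALSE),
      file.path(outDir, "folds.tsv"), "cv", seed))
    settings <- gibbsSettings(.cfgGet(config, "cv", "preset", "desk"),
                              pi = .cfgGet(config, "fit", "pi", 0.95),
                              seed = seed)
    cv <- step("cv", runCV(y, panel[names(y), ],
                           models = .cfgGet(config, "cv", "models", "GBLUP"),
                           foldPlan = plan, settings = settings,
                           trait = trait))
    artifacts <- c(artifacts, .writeStamped(cvCells(cv),
                                            file.path(outDir, "cv_cells.tsv"),
                                            "cv", seed))
    artifacts <- c(artifacts, .writeStamped(cvSummary(cv),
                                            file.path(outDir, "cv_summary.tsv"),
                                            "cv", seed))
    manifest$stages$cv <- list(trait = trait, nFailed = cv@nFailed)
  }

  # --- density ----------------------------------------------------------
  if (isTRUE(config$density$enabled)) {
    trait <- .cfgGet(config, "density", "trait", traits[1])
    y <- getY(trait)
    plan <- makeFolds(names(y), k = .cfgGet(config, "density", "folds", 5L),
                      nRepeats = .cfgGet(config, "density", "repeats", 2L),
                      baseSeed = seed)
    curve <- step("density", densityExperiment(
      y, panel[names(y), ], plan,
      strategy = .cfgGet(config, "density", "strategy", "gwas_ranked"),
      sizes = config$density$sizes,
      rankOnFullData = isTRUE(config$density$rankOnFullData),
      randomSeed = seed))
    artifacts <- c(artifacts, .writeStamped(
      curve@summary, file.path(outDir, "density_curve.tsv"), "density", seed))
    artifacts <- c(artifacts, .writeStamped(
      curve@cells, file.path(outDir, "density_cells.tsv"), "density", seed))
    manifest$stages$density <- list(trait = trait, strategy = curve@strategy,
                                    sizes = curve@sizes)
  }

  finish()
}
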