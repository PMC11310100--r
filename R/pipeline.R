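# Configuration-driven orchestration of the whole study on synthetic
# data: simulate -> features (preprocess + ReHo) -> mvpa -> diffmap ->
# transcript -> modules -> assoc -> enrich. Stage outputs are plain
# files under the output directory; a rerun that finds a stage's outputs
# on disk reuses them, and a stage whose upstream artifact is missing
# fails naming the stage to run first.

pipelineStages <- c("simulate", "features", "mvpa", "diffmap",
                    "transcript", "modules", "assoc", "enrich")

#' Default pipeline configuration
#'
#' Every analysis parameter is surfaced with its study-design default:
#' FD threshold 0.5 mm, band 0.01-0.08 Hz, 10 folds, 5000 permutations,
#' Spearman rho threshold 0.2, 6 mm sphere, top 20% weights. Toy runs
#' override sizes, not meanings.
#'
#' @param seed root seed; all stage seeds derive from it.
#' @param outdir output directory.
#' @return nested list of defaults, mergeable with a YAML config.
#' @export
defaultPipelineConfig <- function(seed = 1L, outdir = "pipeline_out") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = pipelineStages,
    simulation = list(),           # overrides for simulationConfig()
    preprocess = list(fd_threshold = 0.5, low_hz = 0.01, high_hz = 0.08,
                      include_global = TRUE),
    reho = list(connectivity = 26, zscore = TRUE),
    features = list(scale = "scale2"),
    mvpa = list(n_folds = 10, permutations = 5000, permutation_seed = NULL,
                feature_fractions = seq(0.1, 1, by = 0.1),
                kernels = c("linear", "polynomial", "rbf"),
                svm_types = c("C-SVC", "nu-SVC"),
                inner_folds = 5, top_weight_fraction = 0.2),
    transcript = list(rho_threshold = 0.2, background_threshold = 0.5,
                      apply_ds = TRUE),
    modules = list(min_module_size = 30, cut_height = NULL,
                   target_r2 = 0.8),
    assoc = list(sphere_radius = 6, alpha = 0.05),
    enrich = list(gmt = NULL, alpha = 0.05)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

hashFiles <- function(paths) {
  paths <- sort(paths[file.exists(paths)])
  h <- tools::md5sum(paths)
  as.list(setNames(unname(h), basename(paths)))   # list -> YAML map
}

writeTsv <- function(x, path, rowNames = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = rowNames,
              col.names = if (rowNames) NA else TRUE)
  path
}

needArtifact <- function(path, stage) {
  if (!all(file.exists(path)))
    stop("missing upstream artifact '", basename(path[1]),
         "': run stage '", stage, "' first")
  path
}

#' Run the end-to-end pipeline from a configuration
#'
#' Executes the requested stages in dependency order on synthetic data
#' and returns a run manifest (config snapshot, seeds, package version,
#' per-stage output hashes, warnings). Rerunning with an identical
#' configuration reproduces identical outputs for deterministic stages;
#' partial runs resume from the files earlier stages left in `outdir`.
#'
#' @param config a YAML file path, or a (possibly partial) configuration
#'   list merged over [defaultPipelineConfig()].
#' @param stages subset of stages to run (default: those in the config).
#' @return the manifest, invisibly (also written to
#'   `outdir/manifest.yaml`).
#' @export
runPipeline <- function(config, stages = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  if (is.null(stages)) stages <- cfg$stages
  stages <- intersect(pipelineStages, stages)
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, seed = cfg$seed,
                   version = as.character(utils::packageVersion("rehomics")),
                   stages = list(), warnings = character())
  note <- function(w) manifest$warnings <<- c(manifest$warnings, w)

  simCfg <- do.call(simulationConfig,
                    c(list(seed = cfg$seed), cfg$simulation))
  atlas <- makeAtlas(simCfg)
  scl <- cfg$features$scale

  paths <- list(
    participants = file.path(out, "participants.tsv"),
    features = file.path(out, sprintf("features_%s.tsv", scl)),
    cv = file.path(out, "cv_accuracy.tsv"),
    perm = file.path(out, "permutations.tsv"),
    consensus = file.path(out, "consensus_features.tsv"),
    clinical = file.path(out, "clinical_correlations.tsv"),
    diffmap = file.path(out, sprintf("diffmap_%s.tsv", scl)),
    bundleDir = file.path(out, "bundle"),
    expr = file.path(out, "expression_processed.tsv"),
    modules = file.path(out, "modules.tsv"),
    eigengenes = file.path(out, "eigengenes.tsv"),
    netmeta = file.path(out, "network_meta.tsv"),
    assoc = file.path(out, sprintf("association_%s.tsv", scl)),
    demo = file.path(out, "demographics.tsv"),
    enrich = file.path(out, "enrichment.tsv"))

  if ("simulate" %in% stages) {
    cohort <- makeCohort(simCfg, atlas)
    writeTsv(cohort$participants, paths$participants)
    manifest$stages$simulate <- list(outputs = hashFiles(paths$participants))
  } else if (any(c("features", "mvpa", "diffmap", "assoc") %in% stages)) {
    needArtifact(paths$participants, "simulate")
    cohort <- makeCohort(simCfg, atlas)   # volumes regenerate from the seed
  }

  if ("features" %in% stages) {
    fds <- cohortFeatures(cohort, atlas, scale = scl,
                          connectivity = cfg$reho$connectivity,
                          zscore = cfg$reho$zscore,
                          fdThreshold = cfg$preprocess$fd_threshold,
                          includeGlobal = cfg$preprocess$include_global,
                          lowHz = cfg$preprocess$low_hz,
                          highHz = cfg$preprocess$high_hz)
    ftab <- data.frame(id = subjectId(fds), group = groupLabels(fds),
                       featureMatrix(fds), check.names = FALSE)
    writeTsv(ftab, paths$features)
    manifest$stages$features <- list(outputs = hashFiles(paths$features))
  }

  loadFeatures <- function() {
    needArtifact(paths$features, "features")
    ftab <- read.delim(paths$features, check.names = FALSE)
    featureDataset(as.matrix(ftab[, -(1:2), drop = FALSE]), ftab$group,
                   ftab$id, scale = scl)
  }

  if ("mvpa" %in% stages) {
    fds <- loadFeatures()
    mcv <- cfg$mvpa
    cvc <- cvConfig(nFolds = mcv$n_folds,
                    featureFractions = mcv$feature_fractions,
                    svmTypes = mcv$svm_types, kernels = mcv$kernels,
                    innerFolds = mcv$inner_folds,
                    seed = deriveSeed(cfg$seed, "mvpa"))
    res <- runCV(fds, cvc)
    writeTsv(data.frame(fraction = rep(rownames(res$foldAccuracy),
                                       ncol(res$foldAccuracy)),
                        fold = rep(seq_len(ncol(res$foldAccuracy)),
                                   each = nrow(res$foldAccuracy)),
                        accuracy = as.vector(res$foldAccuracy)),
             paths$cv)
    permSeed <- if (is.null(mcv$permutation_seed))
      deriveSeed(cfg$seed, "perm") else mcv$permutation_seed
    pt <- permutationTest(fds, cvc, B = mcv$permutations, observed = res,
                          permSeed = permSeed)
    writeTsv(data.frame(observed = pt$observed, p = pt$p,
                        null = pt$null), paths$perm)
    outs <- c(paths$cv, paths$perm)
    kernelsUsed <- vapply(Filter(Negate(is.null), res$folds), `[[`,
                          character(1), "kernel")
    if (all(kernelsUsed == "linear")) {
      cw <- tryCatch(consensusWeights(res, mcv$top_weight_fraction),
                     error = function(e) NULL)
      if (is.null(cw)) {
        note("no consensus feature across folds; weight analysis skipped")
      } else {
        writeTsv(cw, paths$consensus)
        pats <- cohort$participants$group == "patient"
        fv <- featureMatrix(fds)[pats, cw$feature, drop = FALSE]
        colnames(fv) <- paste0("feature", cw$feature)
        cc <- clinicalCorrelation(
          fv, cohort$participants[pats, c("panss_total", "panss_positive",
                                          "panss_negative", "panss_general")])
        writeTsv(cc, paths$clinical)
        outs <- c(outs, paths$consensus, paths$clinical)
      }
    } else note("non-linear kernel chosen in some fold; consensus weights skipped")
    manifest$stages$mvpa <- list(outputs = hashFiles(outs))
  }

  if ("diffmap" %in% stages) {
    fds <- loadFeatures()
    covs <- cohort$participants[, c("age", "sex")]
    dp <- differenceProfile(fds, covs, alpha = cfg$assoc$alpha,
                            normality = TRUE)
    writeTsv(dp, paths$diffmap)
    manifest$stages$diffmap <- list(outputs = hashFiles(paths$diffmap))
  }

  if ("transcript" %in% stages) {
    needArtifact(paths$diffmap, "diffmap")
    tmap <- makeEffectMap(atlas, simCfg$effectRegions)
    be <- makeExpressionBundle(simCfg, atlas, tmap)
    writeProbeBundle(be$bundle, paths$bundleDir)
    se <- processExpressionBundle(
      be$bundle, parcellation = atlas,
      applyDS = cfg$transcript$apply_ds,
      rhoThreshold = cfg$transcript$rho_threshold,
      backgroundThreshold = cfg$transcript$background_threshold)
    writeTsv(as.data.frame(SummarizedExperiment::assay(se)), paths$expr,
             rowNames = TRUE)
    manifest$stages$transcript <- list(outputs = hashFiles(
      c(paths$expr, list.files(paths$bundleDir, full.names = TRUE))))
  }

  if ("modules" %in% stages) {
    needArtifact(paths$expr, "transcript")
    gx <- as.matrix(read.delim(paths$expr, row.names = 1,
                               check.names = FALSE))
    cm <- coexpressionModules(gx,
                              minModuleSize = cfg$modules$min_module_size,
                              cutHeight = cfg$modules$cut_height,
                              targetR2 = cfg$modules$target_r2)
    writeTsv(data.frame(gene = names(cm$partition$labels),
                        module = cm$partition$labels), paths$modules)
    writeTsv(as.data.frame(cm$eigengenes$eigengenes), paths$eigengenes,
             rowNames = TRUE)
    writeTsv(data.frame(beta = cm$beta,
                        fitR2 = cm$fitR2[as.character(cm$beta)],
                        nModules = cm$partition$nModules,
                        minModuleSize = cfg$modules$min_module_size,
                        cutHeight = cm$partition$cutHeight), paths$netmeta)
    manifest$stages$modules <- list(outputs = hashFiles(
      c(paths$modules, paths$eigengenes, paths$netmeta)))
  }

  if ("assoc" %in% stages) {
    needArtifact(paths$eigengenes, "modules")
    needArtifact(paths$diffmap, "diffmap")
    me <- as.matrix(read.delim(paths$eigengenes, row.names = 1,
                               check.names = FALSE))
    samples <- read.delim(file.path(paths$bundleDir, "samples.tsv"))
    dp <- read.delim(paths$diffmap)
    # sample-level t values: sphere means over a voxelised t surrogate
    tmap <- makeEffectMap(atlas, simCfg$effectRegions)
    tv <- sphereSampleT(tmap, samples, voxelAffine(atlas),
                        mask = brainMask(atlas),
                        radius = cfg$assoc$sphere_radius)
    at <- meTCorrelation(me, tv, samples$compartment)
    writeTsv(at, paths$assoc)
    writeTsv(compareDemographics(cohort$participants), paths$demo)
    manifest$stages$assoc <- list(outputs = hashFiles(
      c(paths$assoc, paths$demo)))
  }

  if ("enrich" %in% stages && !is.null(cfg$enrich$gmt)) {
    needArtifact(paths$modules, "modules")
    needArtifact(paths$assoc, "assoc")
    mods <- read.delim(paths$modules)
    at <- read.delim(paths$assoc)
    sig <- unique(sub("^ME", "", at$module[at$q < cfg$enrich$alpha]))
    query <- mods$gene[mods$module %in% as.integer(sig)]
    if (length(query)) {
      et <- oraTest(query, readGmt(cfg$enrich$gmt), universe = mods$gene)
      writeTsv(et, paths$enrich)
      manifest$stages$enrich <- list(outputs = hashFiles(paths$enrich))
    } else note("no significant module; enrichment skipped")
  }

  yaml::write_yaml(manifest[c("seed", "version", "stages", "warnings")],
                   file.path(out, "manifest.yaml"))
  invisible(manifest)
}
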