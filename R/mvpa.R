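#' Cross-validation configuration for the MVPA stage
#'
#' Defaults follow the study design: subject-level 10-fold
#' cross-validation; F-score feature selection at a series of feature
#' fractions; a grid search over C-SVC (C from 1 to 100 in steps of 5, 20
#' values) and nu-SVC (nu from 0.2 to 0.7 in steps of 0.1, 6 values) with
#' linear, polynomial and radial-basis kernels, tuned by inner
#' cross-validation on the training subjects only. The feature-fraction
#' series defaults to 10 thresholds at 10%..100%.
#'
#' @param nFolds outer folds (default 10).
#' @param featureFractions fractions in (0, 1\] of features kept by the
#'   F-score filter.
#' @param svmTypes subset of `c("C-SVC", "nu-SVC")`.
#' @param kernels subset of `c("linear", "polynomial", "rbf")`; the
#'   enumeration (and tie-break) order is linear < polynomial < rbf.
#' @param cGrid penalty values for C-SVC.
#' @param nuGrid nu values for nu-SVC.
#' @param innerFolds folds of the tuning cross-validation inside each
#'   training set (default 5).
#' @param seed seed controlling fold assignment and tuning splits.
#' @return object of class `CVConfig` (a validated list).
#' @export
cvConfig <- function(nFolds = 10L,
                     featureFractions = seq(0.1, 1, by = 0.1),
                     svmTypes = c("C-SVC", "nu-SVC"),
                     kernels = c("linear", "polynomial", "rbf"),
                     cGrid = seq(1, 100, by = 5),
                     nuGrid = seq(0.2, 0.7, by = 0.1),
                     innerFolds = 5L,
                     seed = 1L) {
  kernels <- intersect(c("linear", "polynomial", "rbf"), kernels)
  svmTypes <- intersect(c("C-SVC", "nu-SVC"), svmTypes)
  if (!length(kernels)) stop("at least one kernel required")
  if (!length(svmTypes)) stop("at least one SVM type required")
  if (any(featureFractions <= 0 | featureFractions > 1))
    stop("featureFractions must lie in (0, 1]")
  cfg <- list(nFolds = as.integer(nFolds),
              featureFractions = sort(featureFractions),
              svmTypes = svmTypes, kernels = kernels,
              cGrid = cGrid, nuGrid = nuGrid,
              innerFolds = as.integer(innerFolds), seed = as.integer(seed))
  class(cfg) <- "CVConfig"
  cfg
}

#' Construct a FeatureDataset
#'
#' @param features subjects x features numeric matrix.
#' @param labels vector coercible to a factor with levels
#'   `control, patient`.
#' @param subjectIds unique subject identifiers.
#' @param scale name of the spatial scale the features come from.
#' @return a [FeatureDataset-class].
#' @export
featureDataset <- function(features, labels, subjectIds,
                           scale = "unspecified") {
  new("FeatureDataset", features = as.matrix(features),
      labels = factor(labels, levels = c("control", "patient")),
      subjectIds = as.character(subjectIds), scale = scale)
}

#' Two-group ANOVA F score per feature
#'
#' Discriminative power of each feature between the two classes:
#' `F = MS_between / MS_within` from a one-way two-group ANOVA. Features
#' with zero within-group variance but distinct group means get `Inf`
#' (ranked first); features constant everywhere get 0.
#'
#' @param X subjects x features matrix.
#' @param y two-level factor (or vector) of class labels.
#' @return numeric vector of F scores, one per feature.
#' @export
fScore <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two groups")
  n <- tabulate(y)
  if (any(n < 2)) stop("both groups need at least 2 subjects")
  g1 <- y == levels(y)[1]
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  gm <- colMeans(X)
  ssb <- n[1] * (m1 - gm)^2 + n[2] * (m2 - gm)^2
  ssw <- colSums(sweep(X[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(X[!g1, , drop = FALSE], 2, m2)^2)
  dfw <- sum(n) - 2
  f <- (ssb / 1) / (ssw / dfw)
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- 0
  f
}

#' Select the top fraction of features by F score
#'
#' Keeps `ceiling(fraction * n)` features with the largest scores; ties
#' are broken by ascending feature index, so selection is deterministic.
#'
#' @param f numeric vector of scores.
#' @param fraction fraction in (0, 1\].
#' @return sorted integer vector of selected feature indices.
#' @export
selectFeatures <- function(f, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  m <- ceiling(fraction * length(f))
  ord <- order(-f, seq_along(f))
  sort(ord[seq_len(m)])
}

svmCombos <- function(config) {
  combos <- list()
  for (k in config$kernels) {
    for (ty in config$svmTypes) {
      pen <- if (ty == "C-SVC") config$cGrid else config$nuGrid
      for (p in pen) combos[[length(combos) + 1]] <-
          list(kernel = k, type = ty, penalty = p)
    }
  }
  combos
}

fitSvm <- function(X, y, combo) {
  kern <- c(linear = "linear", polynomial = "polynomial", rbf = "radial")
  args <- list(x = X, y = y, kernel = kern[[combo$kernel]], scale = FALSE)
  if (combo$type == "C-SVC") {
    args$type <- "C-classification"; args$cost <- combo$penalty
  } else {
    args$type <- "nu-classification"; args$nu <- combo$penalty
  }
  tryCatch(do.call(e1071::svm, args), error = function(e) NULL)
}

# Stratified fold assignment: within each class, subjects are shuffled
# (seeded) and dealt into folds round-robin.
assignFolds <- function(y, nFolds, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (lv in levels(factor(y))) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep(seq_len(nFolds), length.out = length(idx))
    }
  })
  fold
}

#' Grid search for SVM hyperparameters on training data only
#'
#' Evaluates every (kernel, SVM type, penalty) combination of the
#' configuration by inner cross-validation on the training set and
#' returns the model refit on the full training data with the best mean
#' accuracy. Ties go to the first combination in the documented
#' enumeration order (linear < polynomial < rbf; C-SVC before nu-SVC;
#' smaller penalty first). Inner folds whose training part has a single
#' class are skipped with a warning; a single-combination grid skips the
#' inner loop entirely.
#'
#' @param X training subjects x features matrix.
#' @param y training labels (two-level factor).
#' @param config a [cvConfig()].
#' @param seed seed for the inner fold split (defaults to `config$seed`).
#' @return list with `model` (the fitted `e1071::svm`), `kernel`, `type`,
#'   `penalty`, and `innerAccuracy`.
#' @export
gridSearchTrain <- function(X, y, config, seed = config$seed) {
  X <- as.matrix(X); y <- factor(y)
  combos <- svmCombos(config)
  if (length(combos) == 1) {
    best <- combos[[1]]; bestAcc <- NA_real_
  } else {
    fold <- assignFolds(y, min(config$innerFolds, length(y)), seed)
    accs <- vapply(combos, function(cmb) {
      a <- vapply(seq_len(max(fold)), function(f) {
        tr <- fold != f
        if (nlevels(droplevels(y[tr])) < 2) {
          warning("inner fold with one class skipped")
          return(NA_real_)
        }
        fit <- fitSvm(X[tr, , drop = FALSE], y[tr], cmb)
        if (is.null(fit)) return(NA_real_)
        mean(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
      }, numeric(1))
      mean(a, na.rm = TRUE)
    }, numeric(1))
    accs[is.nan(accs)] <- -Inf
    bestIdx <- which.max(accs)   # first maximum = enumeration-order tie-break
    best <- combos[[bestIdx]]; bestAcc <- accs[bestIdx]
  }
  model <- fitSvm(X, y, best)
  if (is.null(model)) stop("failed to fit the selected SVM configuration")
  list(model = model, kernel = best$kernel, type = best$type,
       penalty = best$penalty, innerAccuracy = bestAcc)
}

linearWeights <- function(model) {
  drop(crossprod(model$coefs, model$SV))
}

#' Subject-level cross-validated classification
#'
#' The full MVPA loop: subjects are partitioned into stratified folds (a
#' subject never appears in two folds); within each fold, F scores,
#' feature selection, and the hyperparameter grid search use the training
#' subjects only, and accuracy is measured on the held-out subjects. The
#' feature-fraction series is evaluated per fold and the fraction with
#' the best mean accuracy across folds is reported as the result.
#'
#' @param dataset a [FeatureDataset-class].
#' @param config a [cvConfig()].
#' @return object of class `CVResult`: a list with `accuracy` (mean
#'   across folds at the best fraction), `pooledAccuracy` (fraction of
#'   all held-out subjects classified correctly), `bestFraction`,
#'   `foldAccuracy` (fractions x folds matrix), `folds` (per-fold test
#'   ids, and at the best fraction the selected features, chosen
#'   hyperparameters, and linear primal weights when the linear kernel
#'   was chosen), and the `config`.
#' @export
runCV <- function(dataset, config = cvConfig()) {
  X <- featureMatrix(dataset)
  y <- droplevels(groupLabels(dataset))
  ids <- subjectId(dataset)
  if (nlevels(y) != 2) stop("dataset must contain both classes")
  nF <- config$nFolds
  fold <- assignFolds(y, nF, deriveSeed(config$seed, "folds"))
  if (anyDuplicated(ids)) stop("subject appears in more than one fold")

  fr <- config$featureFractions
  foldAcc <- matrix(NA_real_, length(fr), nF,
                    dimnames = list(sprintf("%g", fr), NULL))
  detail <- vector("list", nF)
  pooledOk <- matrix(NA, length(fr), length(y))
  for (f in seq_len(nF)) {
    tr <- fold != f
    if (!any(!tr)) next
    fs <- fScore(X[tr, , drop = FALSE], y[tr])
    perFrac <- vector("list", length(fr))
    for (j in seq_along(fr)) {
      sel <- selectFeatures(fs, fr[j])
      gs <- gridSearchTrain(X[tr, sel, drop = FALSE], y[tr], config,
                            seed = deriveSeed(config$seed,
                                              sprintf("inner%d", f)))
      pred <- predict(gs$model, X[!tr, sel, drop = FALSE])
      foldAcc[j, f] <- mean(pred == y[!tr])
      pooledOk[j, which(!tr)] <- pred == y[!tr]
      w <- if (gs$kernel == "linear")
        setNames(linearWeights(gs$model), sel) else NULL
      perFrac[[j]] <- list(selected = sel, kernel = gs$kernel,
                           type = gs$type, penalty = gs$penalty,
                           weights = w)
    }
    detail[[f]] <- list(testIds = ids[!tr], perFraction = perFrac)
  }
  meanAcc <- rowMeans(foldAcc, na.rm = TRUE)
  bestJ <- which.max(meanAcc)   # ties -> smallest fraction
  folds <- lapply(detail, function(dt) {
    c(list(testIds = dt$testIds), dt$perFraction[[bestJ]])
  })
  res <- list(accuracy = meanAcc[bestJ],
              pooledAccuracy = mean(pooledOk[bestJ, ], na.rm = TRUE),
              bestFraction = fr[bestJ],
              foldAccuracy = foldAcc,
              folds = folds,
              scale = dataset@scale,
              config = config)
  class(res) <- "CVResult"
  res
}

#' Permutation test of classification accuracy
#'
#' Builds an empirical null by rerunning the complete pipeline (feature
#' selection, grid search, cross-validation) on label permutations and
#' compares the observed accuracy against it with the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, which is never below
#' `1/(B+1)`.
#'
#' @param dataset a [FeatureDataset-class].
#' @param config a [cvConfig()].
#' @param B number of permutations (the study design uses 5000;
#'   test-scale runs use far fewer).
#' @param observed optionally a precomputed `CVResult` for the unshuffled
#'   labels, to avoid refitting it.
#' @param permSeed seed of the label shuffles (default `config$seed`),
#'   separate so permutation draws can be varied without touching the
#'   fold structure.
#' @return list with `observed` (accuracy), `null` (length-B vector),
#'   `p`.
#' @export
permutationTest <- function(dataset, config = cvConfig(), B = 199,
                            observed = NULL, permSeed = config$seed) {
  if (B < 1) stop("B must be >= 1")
  if (is.null(observed)) observed <- runCV(dataset, config)
  obs <- observed$accuracy
  y <- groupLabels(dataset)
  null <- vapply(seq_len(B), function(b) {
    perm <- withSeed(deriveSeed(permSeed, sprintf("perm%d", b)),
                     sample(length(y)))
    ds <- initialize(dataset, labels = y[perm])
    runCV(ds, config)$accuracy
  }, numeric(1))
  list(observed = obs, null = null, p = (1 + sum(null >= obs)) / (B + 1))
}

#' Consensus high-weight features across folds
#'
#' For linear-kernel results only: intersects the features selected in
#' every fold, averages the absolute primal weights across folds, and
#' returns the top fraction (default 20%) by mean absolute weight. With a
#' non-linear kernel in any fold the weights are not defined in feature
#' space and the function refuses.
#'
#' @param cvResult a `CVResult` from [runCV()].
#' @param topFraction fraction of the consensus set returned
#'   (default 0.2).
#' @return data.frame with columns `feature` (index) and `meanAbsWeight`,
#'   sorted by decreasing weight.
#' @export
consensusWeights <- function(cvResult, topFraction = 0.2) {
  folds <- Filter(Negate(is.null), cvResult$folds)
  kernels <- vapply(folds, `[[`, character(1), "kernel")
  if (any(kernels != "linear"))
    stop("feature weights require the linear kernel in every fold; fold(s) ",
         paste(which(kernels != "linear"), collapse = ", "),
         " used a non-linear kernel")
  common <- Reduce(intersect, lapply(folds, `[[`, "selected"))
  if (!length(common)) stop("no feature was selected in every fold")
  wmat <- vapply(folds, function(fd) {
    abs(fd$weights[as.character(common)])
  }, numeric(length(common)))
  wmat <- matrix(wmat, nrow = length(common))
  mw <- rowMeans(wmat)
  m <- ceiling(topFraction * length(common))
  ord <- order(-mw, common)
  sel <- ord[seq_len(m)]
  data.frame(feature = common[sel], meanAbsWeight = mw[sel])
}

#' Correlate feature values with clinical scores
#'
#' Pearson correlation of each feature (patients only) with each symptom
#' score, with Benjamini-Hochberg correction over all pairs tested.
#' Zero-variance vectors are skipped with a warning.
#'
#' @param featureValues patients x features matrix (named columns
#'   recommended).
#' @param clinicalScores patients x scores data.frame or matrix.
#' @return data.frame with columns `feature, score, n, r, p, q`.
#' @export
clinicalCorrelation <- function(featureValues, clinicalScores) {
  Xf <- as.matrix(featureValues)
  Sc <- as.data.frame(clinicalScores)
  if (nrow(Xf) != nrow(Sc)) stop("feature and score rows must align")
  fn <- colnames(Xf); if (is.null(fn)) fn <- paste0("f", seq_len(ncol(Xf)))
  rows <- list()
  for (i in seq_len(ncol(Xf))) {
    for (j in seq_len(ncol(Sc))) {
      ok <- stats::complete.cases(Xf[, i], Sc[, j])
      x <- Xf[ok, i]; s <- Sc[ok, j]
      if (sd(x) == 0 || sd(s) == 0) {
        warning("zero-variance pair skipped: ", fn[i], " / ",
                colnames(Sc)[j])
        next
      }
      ct <- cor.test(x, s, method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        feature = fn[i], score = colnames(Sc)[j], n = sum(ok),
        r = unname(ct$estimate), p = ct$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out
}
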