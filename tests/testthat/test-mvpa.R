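test_that("F scores match the two-group ANOVA and the t^2 identity", {
  X <- cbind(c(1, 2, 3, 4), c(5, 5, 5, 5) + c(0, 0.01, 0, 0.01))
  y <- c("control", "control", "patient", "patient")
  f <- fScore(X, y)
  expect_equal(f[1], 8)                        # SSB = 4 (df 1), SSW = 1 (df 2)
  expect_lt(f[2], 1)

  set.seed(2)
  Xr <- matrix(rnorm(40 * 5), 40, 5)
  yr <- rep(c("control", "patient"), each = 20)
  fr <- fScore(Xr, yr)
  t2 <- vapply(1:5, function(j)
    unname(t.test(Xr[yr == "control", j], Xr[yr == "patient", j],
                  var.equal = TRUE)$statistic^2), numeric(1))
  expect_equal(fr, t2, tolerance = 1e-10)

  # identical groups -> F ~ 0; zero within-variance -> Inf, ranked first
  expect_equal(fScore(rbind(X, X), rep(c("a", "b"), each = 4))[1], 0)
  Xz <- cbind(rep(c(0, 1), each = 3), rnorm(6))
  expect_equal(fScore(Xz, rep(c("a", "b"), each = 3))[1], Inf)
  expect_error(fScore(X, rep("a", 4)), "two groups")
})

test_that("feature selection uses ceiling counts and index tie-breaks", {
  f <- c(5, 3, 9, 1, 7, 2, 8, 4, 6, 0)
  expect_equal(selectFeatures(f, 1), 1:10)
  expect_length(selectFeatures(f, 0.25), 3)     # ceil(2.5) = 3
  expect_equal(selectFeatures(f, 0.25), sort(c(3, 7, 5)))
  ties <- c(1, 2, 2, 2, 0)
  expect_equal(selectFeatures(ties, 0.4), c(2, 3))   # lower index wins
  expect_error(selectFeatures(f, 0), "fraction")
})

test_that("the hyperparameter grid enumerates (20 + 6) x 3 combinations", {
  cfg <- cvConfig()
  expect_length(cfg$cGrid, 20)
  expect_length(cfg$nuGrid, 6)
  combos <- rehomics:::svmCombos(cfg)
  expect_length(combos, (20 + 6) * 3)
  # enumeration order: linear first, C-SVC before nu-SVC, penalty ascending
  expect_equal(combos[[1]]$kernel, "linear")
  expect_equal(combos[[1]]$type, "C-SVC")
  expect_equal(combos[[1]]$penalty, 1)
  expect_equal(combos[[21]]$type, "nu-SVC")
})

test_that("grid search is deterministic and aces separable data", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20 * 3, -3), 20, 3), matrix(rnorm(20 * 3, 3), 20, 3))
  y <- factor(rep(c("control", "patient"), each = 20))
  cfg <- cvConfig(cGrid = c(1, 10), nuGrid = 0.5, innerFolds = 3, seed = 3)
  g1 <- gridSearchTrain(X, y, cfg)
  g2 <- gridSearchTrain(X, y, cfg)
  expect_equal(g1$innerAccuracy, 1)
  expect_identical(g1[c("kernel", "type", "penalty")],
                   g2[c("kernel", "type", "penalty")])
  expect_equal(mean(predict(g1$model, X) == y), 1)
})

test_that("cross-validation never leaks test subjects into selection", {
  set.seed(9)
  n <- 24
  X <- matrix(rnorm(n * 12), n, 12)
  X[, 3] <- X[, 3] + rep(c(0, 2), each = n / 2)
  y <- rep(c("control", "patient"), each = n / 2)
  ds <- featureDataset(X, y, sprintf("s%02d", 1:n), "toy")
  cfg <- cvConfig(nFolds = 4, featureFractions = c(0.25, 1),
                  svmTypes = "C-SVC", kernels = "linear", cGrid = 1,
                  innerFolds = 2, seed = 11)
  res <- runCV(ds, cfg)

  # per fold, the selected features equal those recomputed from the
  # training subjects alone
  fold <- rehomics:::assignFolds(groupLabels(ds), 4,
                                 rehomics:::deriveSeed(11, "folds"))
  for (f in seq_along(res$folds)) {
    tr <- fold != f
    fs <- fScore(X[tr, , drop = FALSE], y[tr])
    expect_identical(res$folds[[f]]$selected,
                     selectFeatures(fs, res$bestFraction))
  }

  # corrupting held-out subjects' features leaves that fold's selection
  # and hyperparameters untouched
  testIds <- res$folds[[1]]$testIds
  X2 <- X
  X2[match(testIds, subjectId(ds)), ] <- 0
  res2 <- runCV(featureDataset(X2, y, subjectId(ds), "toy"), cfg)
  expect_identical(res2$folds[[1]]$selected, res$folds[[1]]$selected)
  expect_identical(res2$folds[[1]]$penalty, res$folds[[1]]$penalty)

  # feature-order permutation does not change the accuracy
  perm <- sample(ncol(X))
  res3 <- runCV(featureDataset(X[, perm], y, subjectId(ds), "toy"), cfg)
  expect_equal(res3$accuracy, res$accuracy)
})

test_that("pure-noise features classify at chance", {
  set.seed(13)
  n <- 40
  ds <- featureDataset(matrix(rnorm(n * 10), n, 10),
                       rep(c("control", "patient"), each = n / 2),
                       sprintf("s%02d", 1:n), "null")
  cfg <- cvConfig(nFolds = 5, featureFractions = 1, svmTypes = "C-SVC",
                  kernels = "linear", cGrid = 1, seed = 2)
  res <- runCV(ds, cfg)
  # binomial 95% band around 0.5 for 40 pooled held-out predictions
  expect_gt(res$pooledAccuracy, 0.5 - 1.96 * sqrt(0.25 / n))
  expect_lt(res$pooledAccuracy, 0.5 + 1.96 * sqrt(0.25 / n))
})

test_that("permutation p-values respect their bounds and calibrate", {
  set.seed(17)
  n <- 20
  ds <- featureDataset(matrix(rnorm(n * 5), n, 5),
                       rep(c("control", "patient"), each = n / 2),
                       sprintf("s%02d", 1:n), "null")
  cfg <- cvConfig(nFolds = 4, featureFractions = 1, svmTypes = "C-SVC",
                  kernels = "linear", cGrid = 1, seed = 5)
  pt <- permutationTest(ds, cfg, B = 19)
  expect_gte(pt$p, 1 / 20)
  expect_lte(pt$p, 1)

  # observed accuracy below every null value -> p = 1
  fake <- list(accuracy = -1)
  expect_equal(permutationTest(ds, cfg, B = 19, observed = fake)$p, 1)

  # null calibration: p approximately uniform over 50 seeds
  ps <- vapply(1:50, function(s) {
    withr::with_seed(1000 + s, {
      d <- featureDataset(matrix(rnorm(n * 5), n, 5),
                          rep(c("control", "patient"), each = n / 2),
                          sprintf("s%02d", 1:n), "null")
      permutationTest(d, cvConfig(nFolds = 4, featureFractions = 1,
                                  svmTypes = "C-SVC", kernels = "linear",
                                  cGrid = 1, seed = s), B = 39)$p
    })
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value,
            0.01)
})

test_that("consensus weights intersect folds and refuse non-linear kernels", {
  mkfold <- function(sel, w, kernel = "linear")
    list(testIds = "x", selected = sel, kernel = kernel, type = "C-SVC",
         penalty = 1, weights = setNames(w, sel))
  res <- list(folds = replicate(10, mkfold(1:10, c(10:2, 1) / 10),
                                simplify = FALSE))
  class(res) <- "CVResult"
  top <- consensusWeights(res, 0.2)
  expect_equal(sort(top$feature), c(1, 2))        # top 2 of 10

  # a feature unselected in one fold is ineligible
  res$folds[[4]] <- mkfold(2:10, (9:1) / 10)
  expect_false(1 %in% consensusWeights(res, 0.5)$feature)

  res$folds[[2]]$kernel <- "rbf"
  expect_error(consensusWeights(res), "non-linear")
})

test_that("clinical correlations match the covariance formula and flag ties", {
  x <- c(1, 2, 3, 4, 5)
  s <- c(2, 1, 4, 3, 6)
  out <- clinicalCorrelation(cbind(f1 = x), data.frame(sc = s))
  rOracle <- sum((x - mean(x)) * (s - mean(s))) /
    sqrt(sum((x - mean(x))^2) * sum((s - mean(s))^2))
  expect_equal(out$r, rOracle)

  out2 <- clinicalCorrelation(cbind(f1 = x), data.frame(sc = x))
  expect_equal(out2$r, 1)
  expect_lt(out2$p, 1e-8)

  expect_warning(
    clinicalCorrelation(cbind(f1 = rep(1, 5)), data.frame(sc = s)),
    "zero-variance")

  # q is the BH adjustment of the reported p values
  set.seed(3)
  many <- clinicalCorrelation(matrix(rnorm(40), 10, 4),
                              data.frame(a = rnorm(10), b = rnorm(10)))
  expect_equal(many$q, p.adjust(many$p, "BH"))
})
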