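test_that("Monte-Carlo Lilliefors normality test calibrates and has power", {
  # seeded draws: normal samples rarely rejected, exponential usually are
  pNorm <- vapply(1:20, function(s)
    withr::with_seed(s, ksNormality(rnorm(300), nsim = 400)$p),
    numeric(1))
  expect_gte(mean(pNorm > 0.05), 0.9)
  pExp <- vapply(1:20, function(s)
    withr::with_seed(s, ksNormality(rexp(300), nsim = 400)$p),
    numeric(1))
  expect_gte(mean(pExp < 0.05), 0.9)

  # agreement with the analytic Lilliefors implementation (oracle)
  x <- withr::with_seed(1, rexp(200))
  expect_lt(abs(ksNormality(x)$p - nortest::lillie.test(x)$p.value), 0.05)
  expect_equal(ksNormality(x)$statistic,
               unname(nortest::lillie.test(x)$statistic))

  # determinism and degenerate input
  y <- rnorm(50)
  expect_identical(ksNormality(y), ksNormality(y))
  expect_warning(p0 <- ksNormality(rep(1, 20)), "constant")
  expect_equal(p0$p, 0)
  expect_error(ksNormality(rnorm(5)), "at least 8")
})

test_that("covariate-adjusted t reduces to and extends the two-sample t", {
  set.seed(12)
  n <- 40
  g <- rep(c("control", "patient"), each = n / 2)
  y <- rnorm(n) + (g == "patient") * 0.8

  # no covariates: equals the pooled two-sample t
  plain <- adjustedTTest(y, g)
  tt <- t.test(y[g == "patient"], y[g == "control"], var.equal = TRUE)
  expect_equal(plain$t, unname(tt$statistic))
  expect_equal(plain$p, tt$p.value)

  # against the lm oracle with covariates
  age <- rnorm(n, 30, 5); sex <- sample(c("M", "F"), n, TRUE)
  out <- adjustedTTest(y, g, data.frame(age = age, sex = sex))
  fit <- summary(lm(y ~ I(g == "patient") + age + I(sex == "M")))
  expect_equal(out$t, fit$coefficients[2, "t value"])
  expect_equal(out$p, fit$coefficients[2, "Pr(>|t|)"])
  expect_equal(out$df, unname(fit$df[2]))

  # near-perfect separation
  yS <- as.numeric(g == "patient") + rnorm(n, sd = 1e-4)
  expect_lt(adjustedTTest(yS, g)$p, 1e-6)

  # invariance to affine rescaling of covariates
  out2 <- adjustedTTest(y, g, data.frame(age = 10 * age + 3, sex = sex))
  expect_equal(out2$t, out$t, tolerance = 1e-10)

  # collinear covariates are dropped with a warning
  expect_warning(adjustedTTest(y, g, data.frame(a = age, b = 2 * age)),
                 "collinear")
})

test_that("Bonferroni thresholds are alpha over m", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 272), 0.05 / 272)
  expect_error(bonferroniThreshold(0.05, 0), "at least 1")
})

test_that("sphere extraction averages the covered voxel centres", {
  d <- c(5, 5, 5)
  aff <- rehomics:::defaultAffine(d)       # 3 mm voxels
  set.seed(3)
  tmap <- array(rnorm(prod(d)), d)

  # radius below half the voxel size at a voxel centre: that voxel only
  w <- rehomics:::voxelToWorld(matrix(c(2, 3, 4), 1), aff)
  v1 <- sphereSampleT(tmap, data.frame(x = w[1], y = w[2], z = w[3]),
                      aff, radius = 1)
  expect_equal(v1, tmap[2, 3, 4])

  # midway between two voxels with both in radius: their mean
  w2 <- rehomics:::voxelToWorld(matrix(c(2, 3, 4), 1), aff)
  w3 <- rehomics:::voxelToWorld(matrix(c(3, 3, 4), 1), aff)
  mid <- (w2 + w3) / 2
  v2 <- sphereSampleT(tmap, data.frame(x = mid[1], y = mid[2], z = mid[3]),
                      aff, radius = 2)
  expect_equal(v2, mean(c(tmap[2, 3, 4], tmap[3, 3, 4])))

  # constant map: every sample returns the constant
  cm <- array(2.5, d)
  pts <- data.frame(x = rnorm(4), y = rnorm(4), z = rnorm(4))
  expect_equal(sphereSampleT(cm, pts, aff, radius = 6), rep(2.5, 4))

  # sphere covering nothing -> NA with a message
  expect_message(
    vNA <- sphereSampleT(tmap, data.frame(x = 100, y = 0, z = 0), aff,
                         radius = 1),
    "no voxel")
  expect_true(is.na(vNA))
  expect_error(sphereSampleT(tmap, pts, aff, radius = 0), "positive")
})

test_that("eigengene-t correlations split compartments and adjust within", {
  set.seed(21)
  n <- 30
  tv <- rnorm(n)
  comp <- rep(c("cortical", "subcortical"), c(20, 10))
  me <- rbind(ME1 = tv,                       # identical -> r = 1
              ME2 = rnorm(n))
  at <- meTCorrelation(me, tv, comp)
  expect_equal(at$r[at$module == "ME1" & at$compartment == "cortical"], 1)
  expect_equal(at$r[at$module == "ME1" & at$compartment == "subcortical"], 1)

  # n = 5 toy against the covariance formula
  a <- c(1, 4, 2, 5, 3); b <- c(2, 3, 1, 5, 4)
  at2 <- meTCorrelation(rbind(ME1 = a), b, rep("cortical", 5))
  rOracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(at2$r, rOracle)

  # affine transforms: r invariant, sign flips with negative scaling
  at3 <- meTCorrelation(rbind(ME1 = 2 * a + 1), b, rep("cortical", 5))
  expect_equal(at3$r, rOracle)
  at4 <- meTCorrelation(rbind(ME1 = -a), b, rep("cortical", 5))
  expect_equal(at4$r, -rOracle)

  # BH within compartment; undersized compartments are omitted
  expect_equal(at$q[at$compartment == "cortical"],
               p.adjust(at$p[at$compartment == "cortical"], "BH"))
  expect_message(
    atSmall <- meTCorrelation(me[, 1:22, drop = FALSE], tv[1:22],
                              comp[1:22]),
    "omitted")
  expect_false("subcortical" %in% atSmall$compartment)
})

test_that("demographics comparisons use pooled t and Pearson chi-square", {
  tab <- data.frame(
    group = rep(c("a", "b"), c(10, 10)),
    age = c(rnorm(10, 30), rnorm(10, 31)),
    sex = rep(c("M", "F"), 10))
  out <- compareDemographics(tab)
  tt <- t.test(age ~ group, data = tab, var.equal = TRUE)
  expect_equal(out$p[out$variable == "age"], tt$p.value)

  # balanced 2x2 -> chi-square 0, p 1
  bal <- chisqTest2x2(matrix(c(50, 50, 50, 50), 2))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)

  # diagonal 2x2: expected counts all 5, chi-square = 4 * 25 / 5 = 20
  diag2 <- chisqTest2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag2$statistic, 20)

  # agreement with the uncorrected chisq.test oracle
  m <- matrix(c(54, 45, 49, 65), 2)
  ours <- chisqTest2x2(m)
  ref <- chisq.test(m, correct = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)

  expect_error(chisqTest2x2(matrix(c(0, 0, 3, 4), 2)), "expected count")
  expect_error(compareDemographics(tab[, 1:2]), "columns")
})

test_that("difference profiles flag planted regions under Bonferroni", {
  cfg <- tinyConfig(seed = 33, nPerGroup = c(10, 10), synchronyEffect = 0.9)
  atlas <- makeAtlas(cfg)
  co <- makeCohort(cfg, atlas)
  fds <- cohortFeatures(co, atlas, scale = "scale2", preprocess = FALSE)
  dp <- differenceProfile(fds, co$participants[, c("age", "sex")],
                          normality = FALSE)
  expect_equal(attr(dp, "bonferroni"), 0.05 / 8)
  expect_true(all(cfg$effectRegions %in% dp$unit[dp$significant]))
  expect_gt(min(dp$t[cfg$effectRegions]), 0)
})
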