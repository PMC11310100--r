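test_that("atlas scales compose through merge maps and conserve voxels", {
  cfg <- tinyConfig(regionCounts = c(16, 4, 2))
  atlas <- makeAtlas(cfg)
  fine <- scaleLabels(atlas, "scale2")
  mm <- mergeMap(atlas, "scale2", "scale3")
  coarse <- scaleLabels(atlas, "scale3")
  sel <- fine > 0
  expect_identical(coarse[sel], mm[fine[sel]])

  # coarse voxel counts equal the sum over constituent fine regions
  rtF <- regionTable(atlas, "scale2")
  rtC <- regionTable(atlas, "scale3")
  for (cid in rtC$id)
    expect_equal(rtC$nVoxels[rtC$id == cid],
                 sum(rtF$nVoxels[mm[rtF$id] == cid]))
  expect_equal(sum(rtF$nVoxels), sum(rtC$nVoxels))

  # merge maps are surjective onto the coarse ids
  expect_setequal(unique(mm), rtC$id)
  # both hemispheres and compartments are represented at the fine scale
  expect_setequal(unique(rtF$hemisphere), c("L", "R"))
  expect_setequal(unique(rtF$compartment), c("cortical", "subcortical"))
})

test_that("identity merge map reproduces the fine labels", {
  atlas <- makeAtlas(tinyConfig())
  p2 <- atlas
  p2@mergeMaps[["scale2->scale2"]] <-
    seq_len(nrow(regionTable(atlas, "scale2")))
  expect_identical(mergeParcellation(p2, "scale2", "scale2"),
                   scaleLabels(atlas, "scale2"))
})

test_that("atlas refuses more regions than voxels", {
  expect_error(makeAtlas(tinyConfig(regionCounts = c(600, 10, 2))),
               "more regions")
})

test_that("cohort generation is deterministic and validates inputs", {
  cfg <- tinyConfig(seed = 7)
  atlas <- makeAtlas(cfg)
  a <- makeCohort(cfg, atlas)
  b <- makeCohort(cfg, atlas)
  expect_identical(a$participants, b$participants)
  expect_identical(boldData(a$runs[[3]]), boldData(b$runs[[3]]))
  expect_identical(motionParams(a$motion[[5]]), motionParams(b$motion[[5]]))
  expect_error(makeCohort(tinyConfig(nPerGroup = c(2, 6)), atlas),
               "at least 3")
})

test_that("synchrony 0 gives no group ReHo difference; 0.8 a strong one", {
  atlas0 <- makeAtlas(tinyConfig(seed = 21, synchronyEffect = 0))
  co0 <- makeCohort(tinyConfig(seed = 21, synchronyEffect = 0), atlas0)
  f0 <- cohortFeatures(co0, atlas0, scale = "scale2", preprocess = FALSE)
  eff <- tinyConfig()$effectRegions
  g <- groupLabels(f0)
  d0 <- colMeans(featureMatrix(f0)[g == "patient", eff, drop = FALSE]) -
    colMeans(featureMatrix(f0)[g == "control", eff, drop = FALSE])
  p0 <- t.test(rowMeans(featureMatrix(f0)[, eff, drop = FALSE]) ~ g,
               var.equal = TRUE)$p.value
  expect_gt(p0, 0.01)            # null case: difference within sampling error

  cfg8 <- tinyConfig(seed = 22, nPerGroup = c(8, 8), synchronyEffect = 0.8)
  atlas8 <- makeAtlas(cfg8)
  co8 <- makeCohort(cfg8, atlas8)
  f8 <- cohortFeatures(co8, atlas8, scale = "scale2", preprocess = FALSE)
  g8 <- groupLabels(f8)
  p8 <- t.test(rowMeans(featureMatrix(f8)[, eff, drop = FALSE]) ~ g8,
               var.equal = TRUE)$p.value
  expect_lt(p8, 0.05)            # planted-effect recovery
})

test_that("planted ReHo difference grows with the synchrony weight", {
  eff <- tinyConfig()$effectRegions
  diffAt <- function(w) {
    mean(vapply(1:3, function(s) {
      cfg <- tinyConfig(seed = 30 + s, nPerGroup = c(4, 4),
                        synchronyEffect = w)
      atlas <- makeAtlas(cfg)
      fd <- cohortFeatures(makeCohort(cfg, atlas), atlas, scale = "scale2",
                           preprocess = FALSE)
      g <- groupLabels(fd)
      mean(featureMatrix(fd)[g == "patient", eff]) -
        mean(featureMatrix(fd)[g == "control", eff])
    }, numeric(1)))
  }
  d <- vapply(c(0, 0.3, 0.6, 0.9), diffAt, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("clinical scores track the latent effect strength at the target r", {
  cfg <- tinyConfig(seed = 5, nPerGroup = c(3, 60),
                    clinicalLink = c(negative = 0.4))
  atlas <- makeAtlas(cfg)
  co <- makeCohort(cfg, atlas)
  pat <- co$participants$group == "patient"
  r <- cor(co$participants$panss_negative[pat],
           co$truth$subjectEffect[pat])
  expect_lt(abs(r - 0.4), 0.25)
  # unlinked scores stay near zero correlation
  r0 <- cor(co$participants$panss_positive[pat],
            co$truth$subjectEffect[pat])
  expect_lt(abs(r0), 0.35)
})

test_that("expression bundle is deterministic and warns below 15 samples", {
  cfg <- tinyConfig(seed = 9)
  atlas <- makeAtlas(cfg)
  tmap <- makeEffectMap(atlas, cfg$effectRegions)
  a <- makeExpressionBundle(cfg, atlas, tmap)
  b <- makeExpressionBundle(cfg, atlas, tmap)
  expect_identical(probeExpr(a$bundle), probeExpr(b$bundle))
  expect_identical(sampleAnnotation(a$bundle), sampleAnnotation(b$bundle))
  expect_warning(
    makeExpressionBundle(tinyConfig(seed = 9, nSamples = 9), atlas, tmap),
    "fewer than 15")
})

test_that("noise-free single-probe bundle round-trips exactly", {
  cfg <- tinyConfig(seed = 13, noiseSd = 0, probesPerGene = 1,
                    backgroundFraction = 0)
  atlas <- makeAtlas(cfg)
  tmap <- makeEffectMap(atlas, cfg$effectRegions)
  be <- makeExpressionBundle(cfg, atlas, tmap)
  gx <- selectRepresentativeProbes(be$bundle)
  generating <- probeExpr(be$bundle)
  rownames(generating) <- probeTable(be$bundle)$gene
  expect_identical(gx[rownames(generating), ], generating)
})

test_that("bundle samples sit in the left hemisphere with both compartments", {
  cfg <- tinyConfig(seed = 2, nSamples = 60)
  atlas <- makeAtlas(cfg)
  be <- makeExpressionBundle(cfg, atlas, makeEffectMap(atlas, c(2, 5)))
  ann <- sampleAnnotation(be$bundle)
  expect_true(all(ann$hemisphere == "L"))
  expect_true(all(ann$x < 3))    # world x of the left half (+ jitter)
  expect_gt(length(unique(ann$donor)), 1)
})
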