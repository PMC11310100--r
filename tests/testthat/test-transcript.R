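test_that("background filter applies the strict >50% rule", {
  expr <- matrix(rnorm(4 * 6), 4, 6,
                 dimnames = list(paste0("p", 1:4), paste0("S", 1:6)))
  calls <- rbind(rep(1, 6),                 # present everywhere -> kept
                 c(1, 1, 1, 0, 0, 0),       # exactly 50% -> excluded
                 c(1, 1, 1, 1, 0, 0),       # 4/6 -> kept
                 rep(0, 6))                 # absent -> excluded
  dimnames(calls) <- dimnames(expr)
  b <- toyBundle(expr, calls, genes = c("gA", "gA", "gB", "gB"))
  expect_setequal(filterProbesBackground(b), c("p1", "p3"))
})

test_that("representative probes follow the rho filter and argmax rule", {
  rna <- 1:6
  # p1: monotone transform of the RNA-seq profile -> rho 1
  # p2: same gene, noisier ordering -> lower rho
  # p3/p4 (gene gB): both anti-ranked -> rho < 0.2, gene dropped
  expr <- rbind(p1 = exp(rna / 2),
                p2 = c(1, 3, 2, 4, 6, 5),
                p3 = rev(rna),
                p4 = rev(rna) + 0.1)
  colnames(expr) <- paste0("S", 1:6)
  rnaseq <- rbind(gA = rna, gB = rna)
  colnames(rnaseq) <- colnames(expr)
  b <- toyBundle(expr, rnaseq = rnaseq)
  gx <- selectRepresentativeProbes(b)
  expect_identical(rownames(gx), "gA")
  expect_identical(unname(attr(gx, "probe")["gA"]), "p1")
  expect_equal(unname(gx["gA", ]), unname(expr["p1", ]))

  # a rho of exactly 0.2 is kept ("below 0.2" is strict): ranks
  # (3,4,1,2,5) against (1,2,3,4,5) give rho = 1 - 6*16/120 = 0.2
  expr2 <- rbind(p1 = c(3, 4, 1, 2, 5), p2 = c(5, 4, 3, 2, 1))
  colnames(expr2) <- paste0("S", 1:5)
  rna2 <- rbind(gA = 1:5, gB = 1:5)
  colnames(rna2) <- colnames(expr2)
  b2 <- toyBundle(expr2, genes = c("gA", "gB"), rnaseq = rna2,
                  samples = data.frame(sample_id = paste0("S", 1:5),
                                       donor = "D1", x = -1, y = 0, z = 0,
                                       hemisphere = "L",
                                       compartment = "cortical"))
  gx2 <- selectRepresentativeProbes(b2)
  expect_identical(rownames(gx2), "gA")

  # constant probes are dropped with a warning
  expr3 <- rbind(p1 = rep(1, 6), p2 = c(1, 2, 3, 4, 5, 6))
  colnames(expr3) <- paste0("S", 1:6)
  rna3 <- rbind(gA = 1:6); colnames(rna3) <- colnames(expr3)
  b3 <- toyBundle(expr3, genes = c("gA", "gA"), rnaseq = rna3)
  expect_warning(gx3 <- selectRepresentativeProbes(b3), "constant")
  expect_identical(unname(attr(gx3, "probe")["gA"]), "p2")

  # too few shared samples is refused
  exprS <- matrix(rnorm(6), 2, 3,
                  dimnames = list(c("p1", "p2"), paste0("S", 1:3)))
  rnaS <- matrix(rnorm(3), 1, 3, dimnames = list("gA", paste0("S", 1:3)))
  bS <- toyBundle(exprS, genes = c("gA", "gA"), rnaseq = rnaS,
                  samples = data.frame(sample_id = paste0("S", 1:3),
                                       donor = "D1", x = -1, y = 0, z = 0,
                                       hemisphere = "L",
                                       compartment = "cortical"))
  expect_error(selectRepresentativeProbes(bS), "shared samples")
})

test_that("probes for genes without RNA-seq measures are removed", {
  expr <- rbind(p1 = 1:6, p2 = c(2, 1, 4, 3, 6, 5))
  colnames(expr) <- paste0("S", 1:6)
  rna <- rbind(gA = 1:6); colnames(rna) <- colnames(expr)
  b <- toyBundle(expr, genes = c("gA", "gNoRna"), rnaseq = rna)
  gx <- selectRepresentativeProbes(b)
  expect_identical(rownames(gx), "gA")
})

test_that("differential stability averages donor-pair profile correlations", {
  # 2 donors, 4 regions; identical profiles -> DS 1, reversed -> DS -1
  expr <- rbind(g1 = c(1, 2, 3, 4, 1, 2, 3, 4),
                g2 = c(1, 2, 3, 4, 4, 3, 2, 1),
                g3 = c(2, 4, 6, 8, 1.5, 2.5, 3.5, 4.5))
  donors <- rep(c("D1", "D2"), each = 4)
  regions <- rep(1:4, 2)
  ds <- differentialStability(expr, donors, regions)
  expect_equal(unname(ds$ds["g1"]), 1)
  expect_equal(unname(ds$ds["g2"]), -1)
  expect_equal(unname(ds$ds["g3"]), 1)      # correlation is scale-free
  expect_setequal(ds$retained, c("g1", "g3"))   # top half = ceil(3/2) = 2

  # hand-computed non-trivial pair
  e2 <- rbind(g1 = c(1, 3, 2, 5, 2, 2, 4, 4))
  d2 <- differentialStability(e2, donors, regions)
  expect_equal(unname(d2$ds["g1"]),
               cor(c(1, 3, 2, 5), c(2, 2, 4, 4)))

  # donor pair with too few common regions is skipped
  regions3 <- c(1, 2, 3, 4, 1, 2, NA, NA)
  expect_message(
    expect_error(differentialStability(expr, donors, regions3),
                 "no donor pair"),
    "skipped")
  expect_error(differentialStability(expr, rep("D1", 8), regions),
               "2 donors")
})

test_that("samples are assigned to the nearest labelled voxel", {
  atlas <- makeAtlas(tinyConfig())
  aff <- voxelAffine(atlas)
  lab <- scaleLabels(atlas, "scale2")

  # a sample exactly at a voxel centre gets that voxel's region
  vox <- c(2, 3, 4)
  w <- rehomics:::voxelToWorld(matrix(vox, 1), aff)
  ann <- data.frame(x = w[1], y = w[2], z = w[3])
  asg <- assignSamples(ann, atlas, "scale2")
  expect_equal(asg$region, lab[2, 3, 4])
  expect_equal(asg$distance, 0)

  # brute-force oracle over every voxel for random samples
  set.seed(4)
  pts <- data.frame(x = runif(3, -12, 12), y = runif(3, -12, 12),
                    z = runif(3, -12, 12))
  asg2 <- assignSamples(pts, atlas, "scale2", maxDistance = Inf)
  idx <- which(lab > 0, arr.ind = TRUE)
  centres <- rehomics:::voxelToWorld(idx, aff)
  for (i in 1:3) {
    d2 <- rowSums(sweep(centres, 2, as.numeric(pts[i, ]))^2)
    cand <- lab[idx[d2 <= min(d2) + 1e-9, , drop = FALSE]]
    expect_equal(asg2$region[i], min(cand))
  }

  # far-away samples stay unassigned
  far <- data.frame(x = 500, y = 500, z = 500)
  expect_message(asgF <- assignSamples(far, atlas, "scale2"), "unassigned")
  expect_true(is.na(asgF$region))
})

test_that("regional expression averages assigned samples", {
  expr <- rbind(g1 = c(1, 3, 5, 7), g2 = c(0, 2, 4, 6))
  colnames(expr) <- paste0("S", 1:4)
  out <- regionalExpression(expr, c(1, 1, 2, 2))
  expect_equal(unname(out["g1", ]), c(2, 6))
  expect_equal(unname(out["g2", ]), c(1, 5))

  # one sample per region: columns re-indexed
  out1 <- regionalExpression(expr, c(2, 1, 4, 3))
  expect_equal(unname(out1["g1", c("1", "2", "3", "4")]), c(3, 1, 7, 5))

  expect_message(regionalExpression(expr, c(1, 1, 2, 2), regionIds = 1:3),
                 "no samples")
})

test_that("the fixed pipeline order matters: background before rho", {
  # probe pA1 tracks RNA-seq perfectly but is absent in most samples;
  # pA2 is weaker but reliably detected. The fixed order (background
  # filter first) must select pA2; rho-first would pick pA1 and lose the
  # gene to the background filter afterwards.
  rna <- 1:8
  expr <- rbind(pA1 = as.numeric(rna),
                pA2 = c(1, 2, 4, 3, 5, 7, 6, 8))
  colnames(expr) <- paste0("S", 1:8)
  calls <- rbind(pA1 = c(1, 1, 1, 0, 0, 0, 0, 0),
                 pA2 = rep(1, 8))
  dimnames(calls) <- dimnames(expr)
  rnaseq <- rbind(gA = rna); colnames(rnaseq) <- colnames(expr)
  b <- toyBundle(expr, calls, genes = c("gA", "gA"), rnaseq = rnaseq,
                 samples = data.frame(sample_id = paste0("S", 1:8),
                                      donor = rep(c("D1", "D2"), 4),
                                      x = -1, y = 0, z = 0,
                                      hemisphere = "L",
                                      compartment = "cortical"))
  keep <- filterProbesBackground(b)
  expect_identical(keep, "pA2")
  gx <- selectRepresentativeProbes(b, probeIds = keep)
  expect_identical(unname(attr(gx, "probe")["gA"]), "pA2")
  # the other order would have chosen pA1
  gxAll <- selectRepresentativeProbes(b)
  expect_identical(unname(attr(gxAll, "probe")["gA"]), "pA1")
})

test_that("full bundle processing round-trips a noiseless bundle", {
  cfg <- tinyConfig(seed = 31, noiseSd = 0, probesPerGene = 2,
                    backgroundFraction = 0.3)
  atlas <- makeAtlas(cfg)
  be <- makeExpressionBundle(cfg, atlas, makeEffectMap(atlas, c(2, 5)))
  se <- processExpressionBundle(be$bundle, applyDS = FALSE)
  gx <- SummarizedExperiment::assay(se)
  generating <- probeExpr(be$bundle)
  first <- !duplicated(probeTable(be$bundle)$gene)
  generating <- generating[first, ]
  rownames(generating) <- probeTable(be$bundle)$gene[first]
  expect_equal(gx, generating[rownames(gx), colnames(gx)])
  expect_equal(nrow(gx), cfg$nGenes)
  # metadata records the processing log
  expect_false(S4Vectors::metadata(se)$processing$donorNormalise)
})
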