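#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort and expression-bundle
#' generators, validated once. Defaults encode the study conditions the
#' rest of the package is tested against: a 16^3 grid of 3 mm voxels, 150
#' volumes at TR 2 s, 30 patients + 30 controls, a shared-signal
#' synchrony effect of 0.8 in three planted regions, a hierarchical
#' 16 -> 4 -> 2 region atlas, and a 3-module expression bundle over 200
#' left-hemisphere samples from 4 pseudo-donors whose planted module
#' tracks the effect map at correlation 0.7.
#'
#' @param seed integer root seed; every stochastic output is a pure
#'   function of it.
#' @param gridDims 3 integers (>= 8 each): voxels per axis.
#' @param nTimepoints number of volumes (>= 60).
#' @param trSeconds repetition time, seconds.
#' @param nPerGroup integer pair (controls, patients), each >= 3.
#' @param regionCounts region counts fine -> coarse for the label scales
#'   (default `c(16, 4, 2)`); scale names are `scale2, scale3, scale4`
#'   (scale 1 being the voxel level).
#' @param effectRegions fine-scale region ids carrying the planted group
#'   effect.
#' @param synchronyEffect mixing weight w in \[0, 1\] of the region-shared
#'   latent series added in patients (`x <- (1 - w) noise + w latent`,
#'   re-standardised).
#' @param clinicalLink named numeric vector: target correlation between a
#'   PANSS score (`total, positive, negative, general`) and the subject's
#'   latent effect strength.
#' @param subcorticalFraction fraction of regions (per hemisphere, per
#'   scale) whose centroids lie nearest the grid centre and are marked
#'   subcortical; the outer shell is cortical.
#' @param nGenes,nModules,moduleSizes,plantedModule gene layer: number of
#'   genes, number of co-expression modules, their sizes (sum <= nGenes;
#'   leftover genes are unassigned noise), and the index of the module
#'   whose latent profile tracks the effect map.
#' @param plantedCor target Pearson correlation between the planted
#'   module's latent and the effect-map value at each sample.
#' @param noiseSd residual SD added to gene expression (0 gives an exact,
#'   noise-free bundle).
#' @param nSamples,nDonors expression samples and pseudo-donors.
#' @param probesPerGene probes simulated per gene (>= 1).
#' @param backgroundFraction fraction of secondary probes whose detection
#'   calls fall below background in most samples.
#' @param rnaseqCoverage fraction of genes carrying RNA-seq measurements.
#' @return object of class `SimulationConfig` (a validated list).
#' @export
simulationConfig <- function(seed = 1L,
                             gridDims = c(16L, 16L, 16L),
                             nTimepoints = 150L,
                             trSeconds = 2,
                             nPerGroup = c(30L, 30L),
                             regionCounts = c(16L, 4L, 2L),
                             effectRegions = c(2L, 7L, 11L),
                             synchronyEffect = 0.8,
                             clinicalLink = c(negative = 0.4),
                             subcorticalFraction = 0.25,
                             nGenes = 200L,
                             nModules = 3L,
                             moduleSizes = c(70L, 70L, 60L),
                             plantedModule = 1L,
                             plantedCor = 0.7,
                             noiseSd = 0.5,
                             nSamples = 200L,
                             nDonors = 4L,
                             probesPerGene = 2L,
                             backgroundFraction = 0.2,
                             rnaseqCoverage = 1) {
  cfg <- list(seed = as.integer(seed), gridDims = as.integer(gridDims),
              nTimepoints = as.integer(nTimepoints), trSeconds = trSeconds,
              nPerGroup = as.integer(nPerGroup),
              regionCounts = as.integer(regionCounts),
              effectRegions = as.integer(effectRegions),
              synchronyEffect = synchronyEffect,
              clinicalLink = clinicalLink,
              subcorticalFraction = subcorticalFraction,
              nGenes = as.integer(nGenes), nModules = as.integer(nModules),
              moduleSizes = as.integer(moduleSizes),
              plantedModule = as.integer(plantedModule),
              plantedCor = plantedCor, noiseSd = noiseSd,
              nSamples = as.integer(nSamples), nDonors = as.integer(nDonors),
              probesPerGene = as.integer(probesPerGene),
              backgroundFraction = backgroundFraction,
              rnaseqCoverage = rnaseqCoverage)
  if (length(cfg$gridDims) != 3 || any(cfg$gridDims < 8))
    stop("gridDims must be 3 integers, each >= 8")
  if (cfg$nTimepoints < 60) stop("nTimepoints must be >= 60")
  if (cfg$trSeconds <= 0) stop("trSeconds must be positive")
  if (length(cfg$nPerGroup) != 2) stop("nPerGroup must be a pair")
  if (cfg$synchronyEffect < 0 || cfg$synchronyEffect > 1)
    stop("synchronyEffect must lie in [0, 1]")
  if (sum(cfg$moduleSizes) > cfg$nGenes)
    stop("moduleSizes must sum to at most nGenes")
  if (length(cfg$moduleSizes) != cfg$nModules)
    stop("moduleSizes must have nModules entries")
  if (cfg$plantedModule < 1 || cfg$plantedModule > cfg$nModules)
    stop("plantedModule out of range")
  if (any(diff(cfg$regionCounts) >= 0))
    stop("regionCounts must be strictly decreasing (fine to coarse)")
  if (cfg$noiseSd < 0) stop("noiseSd must be non-negative")
  if (cfg$probesPerGene < 1) stop("probesPerGene must be >= 1")
  class(cfg) <- "SimulationConfig"
  cfg
}

# Default 3 mm isotropic affine with the world origin at the grid centre,
# so the x-midplane separates hemispheres.
defaultAffine <- function(dims, voxelSize = 3) {
  aff <- diag(c(rep(voxelSize, 3), 1))
  aff[1:3, 4] <- -voxelSize * (dims - 1) / 2
  aff
}

# Split n items into k nearly-equal consecutive chunks; returns the chunk
# index per item.
chunkIndex <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(k), times = sizes)
}

#' Generate a hierarchical block parcellation
#'
#' Partitions the grid into contiguous fine-scale regions, split evenly
#' between left and right hemispheres (x below / above the midplane), and
#' merges them into successively coarser scales through surjective merge
#' maps, so every coarse region is the union of its fine regions. Region
#' metadata records the hemisphere (sign of the centroid x world
#' coordinate) and the compartment: within each hemisphere, the
#' `subcorticalFraction` of regions whose centroids lie nearest the grid
#' centre are subcortical (a central shell), the rest cortical.
#'
#' @param config a [simulationConfig()].
#' @return a [HierarchicalParcellation-class] with scales
#'   `scale2, scale3, scale4, ...` (one per entry of `regionCounts`).
#' @export
makeAtlas <- function(config) {
  d <- config$gridDims
  counts <- config$regionCounts
  nvox <- prod(d)
  if (counts[1] > nvox) stop("more regions requested than voxels")
  mask <- array(TRUE, d)
  aff <- defaultAffine(d)

  ijk <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  left <- ijk[, 1] <= d[1] / 2
  nL <- ceiling(counts[1] / 2)
  nR <- counts[1] - nL
  fine <- integer(nvox)
  ordL <- which(left)   # raster order within hemisphere -> contiguous runs
  ordR <- which(!left)
  fine[ordL] <- chunkIndex(length(ordL), nL)
  fine[ordR] <- nL + chunkIndex(length(ordR), nR)

  scaleNamesAll <- paste0("scale", seq_along(counts) + 1)
  labels <- list(array(fine, d))
  names(labels) <- scaleNamesAll[1]
  mergeMaps <- list()
  # per-scale merge: group consecutive ids hemisphere-wise
  hemiOf <- c(rep("L", nL), rep("R", nR))
  idsByScale <- list(seq_len(counts[1]))
  hemiByScale <- list(hemiOf)
  for (s in seq_along(counts)[-1]) {
    prevIds <- idsByScale[[s - 1]]
    prevHemi <- hemiByScale[[s - 1]]
    kL <- ceiling(counts[s] / 2)
    kR <- counts[s] - kL
    mm <- integer(length(prevIds))
    iL <- which(prevHemi == "L"); iR <- which(prevHemi == "R")
    if (length(iL) < kL || length(iR) < kR)
      stop("cannot split ", counts[s], " coarse regions across hemispheres")
    mm[iL] <- chunkIndex(length(iL), kL)
    mm[iR] <- kL + chunkIndex(length(iR), kR)
    key <- paste0(scaleNamesAll[s - 1], "->", scaleNamesAll[s])
    mergeMaps[[key]] <- mm
    lab <- labels[[s - 1]]
    out <- lab
    out[lab > 0] <- mm[lab[lab > 0]]
    labels[[scaleNamesAll[s]]] <- out
    idsByScale[[s]] <- seq_len(counts[s])
    hemiByScale[[s]] <- c(rep("L", kL), rep("R", kR))
  }
  # composite maps (fine -> every coarser scale)
  if (length(counts) >= 3) {
    for (s in 3:length(counts)) {
      comp <- idsByScale[[1]]
      for (t in 2:s) {
        key <- paste0(scaleNamesAll[t - 1], "->", scaleNamesAll[t])
        comp <- mergeMaps[[key]][comp]
      }
      mergeMaps[[paste0(scaleNamesAll[1], "->", scaleNamesAll[s])]] <- comp
    }
  }

  centre <- (d + 1) / 2
  regions <- list()
  for (s in seq_along(counts)) {
    lab <- labels[[s]]
    ids <- seq_len(counts[s])
    labVec <- factor(as.vector(lab), levels = ids)
    cen <- cbind(tapply(ijk[, 1], labVec, mean),
                 tapply(ijk[, 2], labVec, mean),
                 tapply(ijk[, 3], labVec, mean))
    dd <- sqrt(rowSums(sweep(cen, 2, centre)^2))
    world <- voxelToWorld(cen, aff)
    hemi <- ifelse(world[, 1] < 0, "L", "R")
    comp <- rep("cortical", length(ids))
    for (h in unique(hemi)) {
      sel <- which(hemi == h)
      k <- round(config$subcorticalFraction * length(sel))
      if (k > 0) comp[sel[order(dd[sel])][seq_len(k)]] <- "subcortical"
    }
    regions[[names(labels)[s]]] <- data.frame(
      id = ids,
      name = paste0(names(labels)[s], "_r", ids),
      hemisphere = hemi,
      compartment = comp,
      nVoxels = as.integer(tabulate(as.vector(lab), counts[s])),
      row.names = NULL)
  }

  new("HierarchicalParcellation", labels = labels, mergeMaps = mergeMaps,
      regions = regions, mask = mask, affine = aff)
}

#' Generate a synthetic case-control resting-state cohort
#'
#' Each subject's voxel time series is independent Gaussian noise; inside
#' the planted effect regions, patients additionally receive a
#' region-shared latent series mixed in with weight
#' `w_i = synchronyEffect * e_i` (clipped to \[0, 1\]), where `e_i` is the
#' subject's latent effect strength, and the mixed series are
#' re-standardised. Local rank concordance - and hence ReHo - therefore
#' rises with the synchrony weight in patients only. PANSS-like symptom
#' scores are generated for patients, correlated with `e_i` at the target
#' correlations in `clinicalLink` via the closed-form mixture
#' `z_score = r z_e + sqrt(1 - r^2) z_noise`. Motion traces are smooth
#' random walks with occasional one-volume spikes exceeding the 0.5 mm
#' scrubbing threshold. Output is a pure function of `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @param atlas the matching [makeAtlas()] parcellation.
#' @return list with elements `runs` (list of [BoldRun-class]), `motion`
#'   (list of [MotionTrace-class]), `participants` (data.frame: id, group,
#'   age, sex, PANSS total/positive/negative/general), and `truth`
#'   (effect region ids, per-subject effect strength and mixing weight,
#'   clinical targets).
#' @export
makeCohort <- function(config, atlas) {
  if (any(config$nPerGroup < 3))
    stop("need at least 3 subjects per group for cross-validation")
  d <- config$gridDims
  nt <- config$nTimepoints
  fine <- scaleLabels(atlas, scaleNames(atlas)[1])
  if (!all(config$effectRegions %in% regionTable(atlas, scaleNames(atlas)[1])$id))
    stop("effectRegions must be region ids of the fine atlas scale")
  nC <- config$nPerGroup[1]; nP <- config$nPerGroup[2]
  ids <- c(sprintf("C%03d", seq_len(nC)), sprintf("P%03d", seq_len(nP)))
  group <- c(rep("control", nC), rep("patient", nP))
  aff <- voxelAffine(atlas)
  effVox <- lapply(config$effectRegions, function(r) which(fine == r))

  withSeed(deriveSeed(config$seed, "cohort"), {
    # latent effect strength, patients only
    e <- pmin(pmax(rnorm(nP, 1, 0.25), 0.2), 1.8)
    w <- pmin(pmax(config$synchronyEffect * e, 0), 1)

    runs <- vector("list", length(ids))
    motion <- vector("list", length(ids))
    for (s in seq_along(ids)) {
      x <- array(rnorm(prod(d) * nt), c(prod(d), nt))
      if (group[s] == "patient" && config$synchronyEffect > 0) {
        wi <- w[s - nC]
        for (vox in effVox) {
          latent <- rnorm(nt)
          mixed <- (1 - wi) * x[vox, , drop = FALSE] +
            matrix(wi * latent, length(vox), nt, byrow = TRUE)
          mixed <- t(apply(mixed, 1, unitScale))
          x[vox, ] <- mixed
        }
      }
      runs[[s]] <- new("BoldRun", subjectId = ids[s],
                       data = array(x, c(d, nt)),
                       trSeconds = config$trSeconds, affine = aff)
      mp <- apply(matrix(rnorm(nt * 6,
                               sd = rep(c(0.02, 0.0004), each = nt * 3)),
                         nt, 6), 2, cumsum)
      spikes <- which(runif(nt - 1) < 0.03) + 1
      mp[spikes, 1] <- mp[spikes, 1] + 0.7
      colnames(mp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
      motion[[s]] <- new("MotionTrace", subjectId = ids[s], params = mp)
    }

    age <- round(c(rnorm(nC, 33.7, 11.0), rnorm(nP, 33.9, 9.6)))
    age <- pmin(pmax(age, 18), 65)
    sex <- c(ifelse(runif(nC) < 45 / 110, "M", "F"),
             ifelse(runif(nP) < 54 / 103, "M", "F"))
    panssDist <- c(total = 71.1, positive = 16.8, negative = 20.0,
                   general = 34.3)
    panssSD <- c(total = 22.3, positive = 7.7, negative = 8.9,
                 general = 10.5)
    ze <- unitScale(e)
    panss <- sapply(names(panssDist), function(sc) {
      r <- if (sc %in% names(config$clinicalLink))
        config$clinicalLink[[sc]] else 0
      z <- r * ze + sqrt(1 - r^2) * rnorm(nP)
      round(panssDist[sc] + panssSD[sc] * z)
    })
    participants <- data.frame(
      id = ids, group = group, age = age, sex = sex,
      panss_total = c(rep(NA, nC), panss[, "total"]),
      panss_positive = c(rep(NA, nC), panss[, "positive"]),
      panss_negative = c(rep(NA, nC), panss[, "negative"]),
      panss_general = c(rep(NA, nC), panss[, "general"]))

    truth <- list(effectRegionIds = config$effectRegions,
                  subjectEffect = setNames(c(rep(NA_real_, nC), e), ids),
                  mixingWeight = setNames(c(rep(0, nC), w), ids),
                  clinicalLink = config$clinicalLink)
    list(runs = runs, motion = motion, participants = participants,
         truth = truth)
  })
}

#' Planted case-control effect map
#'
#' A smooth synthetic difference map: Gaussian bumps of the given
#' amplitude centred on the effect-region centroids, over a weak smooth
#' background. Used as the spatial profile the planted expression module
#' tracks, and as a stand-in t-map in association tests.
#'
#' @param atlas a [HierarchicalParcellation-class].
#' @param effectRegions fine-scale region ids.
#' @param amplitude bump height (default 3, a typical peak t value).
#' @param sigmaVoxels Gaussian width in voxels (default 2.5).
#' @return 3D numeric array on the atlas grid.
#' @export
makeEffectMap <- function(atlas, effectRegions, amplitude = 3,
                          sigmaVoxels = 2.5) {
  d <- dim(brainMask(atlas))
  fineScale <- scaleNames(atlas)[1]
  fine <- scaleLabels(atlas, fineScale)
  ijk <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  tmap <- array(0, d)
  for (r in effectRegions) {
    vox <- which(fine == r)
    cen <- colMeans(ijk[vox, , drop = FALSE])
    dd2 <- rowSums(sweep(ijk, 2, cen)^2)
    tmap <- tmap + amplitude * array(exp(-dd2 / (2 * sigmaVoxels^2)), d)
  }
  tmap
}

#' Generate a synthetic probe-level expression bundle
#'
#' Emulates an Allen-atlas-style bundle: samples are placed at random
#' left-hemisphere in-mask locations across `nDonors` pseudo-donors; each
#' co-expression module has a latent profile over samples, and gene
#' expression is `loading * latent + noise`. The planted module's latent
#' is an affine function of the local effect-map value at each sample,
#' mixed so its correlation with the map is `plantedCor` in expectation.
#' The probe layer carries `probesPerGene` probes per gene (the first
#' noise-free relative to the gene signal, later ones noisier), a
#' configurable fraction of secondary probes with below-background
#' detection calls, and an RNA-seq twin equal to a monotone (exponential)
#' transform of the gene signal plus noise.
#'
#' @param config a [simulationConfig()].
#' @param atlas the matching [makeAtlas()] parcellation.
#' @param effectTmap 3D array on the atlas grid (e.g. [makeEffectMap()]
#'   output or a fitted difference map).
#' @return list with elements `bundle` (a [ProbeBundle-class]) and
#'   `truth` (gene-to-module assignment, module latents, planted module
#'   index and target correlation, sample voxel indices).
#' @export
makeExpressionBundle <- function(config, atlas, effectTmap) {
  d <- config$gridDims
  if (!identical(dim(effectTmap), d))
    stop("effectTmap must be defined on the atlas grid")
  if (config$nSamples < 15)
    warning("fewer than 15 samples: downstream co-expression network ",
            "analysis will refuse this bundle")
  fineScale <- scaleNames(atlas)[1]
  fine <- scaleLabels(atlas, fineScale)
  rt <- regionTable(atlas, fineScale)
  mask <- brainMask(atlas)
  aff <- voxelAffine(atlas)
  ijk <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  leftVox <- which(mask & array(ijk[, 1] <= d[1] / 2, d))

  withSeed(deriveSeed(config$seed, "expression"), {
    nS <- config$nSamples
    vox <- sample(leftVox, nS, replace = nS > length(leftVox))
    world <- voxelToWorld(ijk[vox, , drop = FALSE], aff) +
      matrix(runif(nS * 3, -1, 1), nS, 3)
    donor <- paste0("D", sample(seq_len(config$nDonors), nS, replace = TRUE))
    compartment <- rt$compartment[fine[vox]]
    samples <- data.frame(
      sample_id = sprintf("S%04d", seq_len(nS)), donor = donor,
      x = world[, 1], y = world[, 2], z = world[, 3],
      hemisphere = "L", compartment = compartment)

    G <- config$nGenes
    M <- config$nModules
    latents <- matrix(rnorm(M * nS), M, nS)
    tvals <- effectTmap[vox]
    r0 <- config$plantedCor
    latents[config$plantedModule, ] <-
      r0 * unitScale(tvals) + sqrt(1 - r0^2) * rnorm(nS)

    geneModule <- integer(G)
    geneModule[seq_len(sum(config$moduleSizes))] <-
      rep(seq_len(M), times = config$moduleSizes)
    loading <- 0.25 + 0.75 * runif(G)^3
    geneNames <- sprintf("G%04d", seq_len(G))
    signal <- matrix(0, G, nS, dimnames = list(geneNames, samples$sample_id))
    assigned <- geneModule > 0
    signal[assigned, ] <- loading[assigned] * latents[geneModule[assigned], ]
    expr <- signal + config$noiseSd * matrix(rnorm(G * nS), G, nS)
    expr[!assigned, ] <- expr[!assigned, , drop = FALSE] +
      matrix(rnorm(sum(!assigned) * nS, sd = mean(loading)), sum(!assigned), nS)

    P <- config$probesPerGene
    probeId <- as.vector(t(outer(seq_len(G), seq_len(P),
                                 function(g, p) sprintf("G%04d_p%d", g, p))))
    probeGene <- rep(geneNames, each = P)
    pexpr <- matrix(0, G * P, nS, dimnames = list(probeId, samples$sample_id))
    for (p in seq_len(P)) {
      rows <- seq(p, G * P, by = P)
      pexpr[rows, ] <- expr +
        (p - 1) * 0.5 * config$noiseSd * matrix(rnorm(G * nS), G, nS)
    }
    calls <- matrix(1, G * P, nS, dimnames = dimnames(pexpr))
    if (P > 1 && config$backgroundFraction > 0) {
      secondary <- which(rep(seq_len(P), G) > 1)
      nBg <- round(config$backgroundFraction * length(secondary))
      bg <- sample(secondary, nBg)
      calls[bg, ] <- matrix(rbinom(nBg * nS, 1, 0.3), nBg, nS)
    }

    covered <- sort(sample(seq_len(G), round(config$rnaseqCoverage * G)))
    rnaseq <- exp(expr[covered, , drop = FALSE] / 2)
    if (config$noiseSd > 0)
      rnaseq <- rnaseq + 0.2 * config$noiseSd *
        matrix(rnorm(length(covered) * nS), length(covered), nS)
    rownames(rnaseq) <- geneNames[covered]

    bundle <- new("ProbeBundle", expr = pexpr,
                  probes = data.frame(probe_id = probeId, gene = probeGene),
                  calls = calls, rnaseq = rnaseq, samples = samples)
    truth <- list(geneModule = setNames(geneModule, geneNames),
                  plantedModule = config$plantedModule,
                  plantedCor = r0, latents = latents, sampleVoxels = vox,
                  loading = setNames(loading, geneNames))
    list(bundle = bundle, truth = truth)
  })
}

#' Mean-signal nuisance series from a synthetic run
#'
#' Convenience extractor for the synthetic pipeline: global mean over the
#' mask, a white-matter proxy (mean over subcortical-region voxels) and a
#' CSF proxy (mean over the outermost voxel shell).
#'
#' @param run a [BoldRun-class].
#' @param atlas the matching parcellation.
#' @return list with numeric vectors `global`, `wm`, `csf` (one value per
#'   volume).
#' @export
extractNuisanceSignals <- function(run, atlas) {
  x <- boldData(run)
  d <- dim(x)
  xm <- matrix(x, prod(d[1:3]), d[4])
  mask <- brainMask(atlas)
  fineScale <- scaleNames(atlas)[1]
  fine <- scaleLabels(atlas, fineScale)
  rt <- regionTable(atlas, fineScale)
  sub <- fine %in% rt$id[rt$compartment == "subcortical"]
  shell <- array(FALSE, d[1:3])
  shell[c(1, d[1]), , ] <- TRUE
  shell[, c(1, d[2]), ] <- TRUE
  shell[, , c(1, d[3])] <- TRUE
  wmSel <- if (any(sub)) sub & as.vector(mask) else as.vector(mask)
  list(global = colMeans(xm[as.vector(mask), , drop = FALSE]),
       wm = colMeans(xm[wmSel, , drop = FALSE]),
       csf = colMeans(xm[as.vector(shell & mask), , drop = FALSE]))
}
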