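#' Background (present/absent) probe filter
#'
#' Keeps a probe only if it is called above background in strictly more
#' than half of the samples; a probe present in exactly 50% of samples is
#' excluded.
#'
#' @param bundle a [ProbeBundle-class].
#' @param threshold minimum fraction of above-background calls, exclusive
#'   (default 0.5).
#' @return character vector of retained probe ids.
#' @export
filterProbesBackground <- function(bundle, threshold = 0.5) {
  frac <- rowMeans(probeCalls(bundle))
  rownames(probeExpr(bundle))[frac > threshold]
}

#' Representative-probe selection against the RNA-seq twin
#'
#' For each candidate probe, Spearman's rho against its gene's RNA-seq
#' profile over the shared samples; probes with rho < `rhoThreshold` are
#' excluded, genes with no RNA-seq measurements are removed, and per gene
#' the probe with the highest rho is kept (ties to the lexicographically
#' lowest probe id). Constant probes, whose rho is undefined, are dropped
#' with a warning; fewer than `minSharedSamples` shared samples is
#' refused, as rank correlations on so few points are not stable.
#'
#' @param bundle a [ProbeBundle-class].
#' @param probeIds candidate probes (e.g. from
#'   [filterProbesBackground()]); defaults to all probes.
#' @param rhoThreshold minimum Spearman rho (default 0.2; values >= the
#'   threshold are kept).
#' @param minSharedSamples minimum shared samples for a rho (default 4).
#' @return gene x sample numeric matrix of the selected probes'
#'   intensities, with attribute `"probe"` naming the representative
#'   probe per gene.
#' @export
selectRepresentativeProbes <- function(bundle, probeIds = NULL,
                                       rhoThreshold = 0.2,
                                       minSharedSamples = 4) {
  expr <- probeExpr(bundle)
  rna <- rnaseqExpr(bundle)
  pt <- probeTable(bundle)
  if (is.null(probeIds)) probeIds <- rownames(expr)
  pt <- pt[pt$probe_id %in% probeIds & pt$gene %in% rownames(rna), ,
           drop = FALSE]
  shared <- intersect(colnames(expr), colnames(rna))
  if (is.null(colnames(expr)) || is.null(colnames(rna)))
    shared <- seq_len(min(ncol(expr), ncol(rna)))
  if (length(shared) < minSharedSamples)
    stop("only ", length(shared), " shared samples; at least ",
         minSharedSamples, " required for a stable Spearman rho")
  rho <- vapply(seq_len(nrow(pt)), function(i) {
    x <- expr[pt$probe_id[i], shared]
    yv <- rna[pt$gene[i], shared]
    if (sd(x) == 0 || sd(yv) == 0) return(NA_real_)
    cor(x, yv, method = "spearman")
  }, numeric(1))
  if (anyNA(rho))
    warning(sum(is.na(rho)), " constant probe(s) dropped (rho undefined)")
  keep <- !is.na(rho) & rho >= rhoThreshold - 1e-12
  pt <- pt[keep, , drop = FALSE]
  rho <- rho[keep]
  if (!nrow(pt)) stop("no probe passed the RNA-seq concordance filter")
  ord <- order(pt$gene, -rho, pt$probe_id)
  pt <- pt[ord, , drop = FALSE]
  best <- pt[!duplicated(pt$gene), , drop = FALSE]
  out <- expr[best$probe_id, , drop = FALSE]
  rownames(out) <- best$gene
  attr(out, "probe") <- setNames(best$probe_id, best$gene)
  out
}

#' Differential stability of gene expression across donors
#'
#' Reliability of each gene's spatial expression pattern: for every donor
#' pair, the Pearson correlation between the two donors' regional-mean
#' expression profiles over the regions both donors sampled; DS is the
#' mean over pairs. Genes are ranked by DS and the top half (ceiling)
#' retained. Donor pairs with fewer than `minCommonRegions` common
#' regions are skipped with a message.
#'
#' @param expr gene x sample matrix.
#' @param donors donor id per sample.
#' @param regionIds region assignment per sample (NA = unassigned).
#' @param minCommonRegions minimum common regions per donor pair
#'   (default 3).
#' @return list with `ds` (named per-gene score), `retained` (gene names,
#'   top half by DS, ties by gene order), and `pairsUsed`.
#' @export
differentialStability <- function(expr, donors, regionIds,
                                  minCommonRegions = 3) {
  expr <- as.matrix(expr)
  donors <- as.character(donors)
  if (length(donors) != ncol(expr) || length(regionIds) != ncol(expr))
    stop("donors and regionIds must align with the expression columns")
  ud <- unique(donors)
  if (length(ud) < 2) stop("differential stability needs at least 2 donors")
  # per-donor regional mean profiles
  profiles <- lapply(ud, function(dn) {
    sel <- donors == dn & !is.na(regionIds)
    if (!any(sel)) return(NULL)
    f <- factor(regionIds[sel])
    means <- t(apply(expr[, sel, drop = FALSE], 1, function(v)
      tapply(v, f, mean)))
    if (nlevels(f) == 1) means <- matrix(means, ncol = 1,
                                         dimnames = list(rownames(expr),
                                                         levels(f)))
    means
  })
  names(profiles) <- ud
  pairs <- utils::combn(ud, 2, simplify = FALSE)
  cors <- matrix(NA_real_, nrow(expr), length(pairs))
  used <- logical(length(pairs))
  for (i in seq_along(pairs)) {
    a <- profiles[[pairs[[i]][1]]]; b <- profiles[[pairs[[i]][2]]]
    if (is.null(a) || is.null(b)) next
    common <- intersect(colnames(a), colnames(b))
    if (length(common) < minCommonRegions) {
      message("donor pair ", paste(pairs[[i]], collapse = "/"),
              " skipped: only ", length(common), " common regions")
      next
    }
    used[i] <- TRUE
    av <- a[, common, drop = FALSE]; bv <- b[, common, drop = FALSE]
    cors[, i] <- vapply(seq_len(nrow(expr)), function(g) {
      if (sd(av[g, ]) == 0 || sd(bv[g, ]) == 0) return(NA_real_)
      cor(av[g, ], bv[g, ])
    }, numeric(1))
  }
  if (!any(used)) stop("no donor pair had enough common regions")
  ds <- rowMeans(cors[, used, drop = FALSE], na.rm = TRUE)
  names(ds) <- rownames(expr)
  nKeep <- ceiling(nrow(expr) / 2)
  ord <- order(-ds, seq_along(ds))
  list(ds = ds, retained = rownames(expr)[sort(ord[seq_len(nKeep)])],
       pairsUsed = pairs[used])
}

#' Assign tissue samples to parcellation regions
#'
#' Each sample is assigned to the region of the labelled voxel whose
#' world-space centre is nearest (Euclidean mm) to the sample
#' coordinates. Samples farther than `maxDistance` from any labelled
#' voxel remain unassigned (NA) with a message; exact distance ties go to
#' the lowest region id.
#'
#' @param annotations data.frame with columns `x, y, z` (world mm), e.g.
#'   [sampleAnnotation()] output.
#' @param parcellation a [HierarchicalParcellation-class].
#' @param scale atlas scale name.
#' @param maxDistance assignment cap in mm; defaults to twice the voxel
#'   size.
#' @return data.frame with columns `region` (id or NA) and `distance`
#'   (mm), one row per sample.
#' @export
assignSamples <- function(annotations, parcellation, scale,
                          maxDistance = NULL) {
  lab <- scaleLabels(parcellation, scale)
  aff <- voxelAffine(parcellation)
  vsize <- max(sqrt(colSums(aff[1:3, 1:3]^2)))
  if (is.null(maxDistance)) maxDistance <- 2 * vsize
  idx <- which(lab > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("parcellation has no labelled voxels at this scale")
  centres <- voxelToWorld(idx, aff)
  regs <- lab[idx]
  pts <- as.matrix(annotations[, c("x", "y", "z")])
  region <- integer(nrow(pts)); distance <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- (centres[, 1] - pts[i, 1])^2 + (centres[, 2] - pts[i, 2])^2 +
      (centres[, 3] - pts[i, 3])^2
    dmin <- min(d2)
    cand <- regs[d2 <= dmin + 1e-9]
    region[i] <- min(cand)
    distance[i] <- sqrt(dmin)
  }
  far <- distance > maxDistance
  if (any(far)) {
    message(sum(far), " sample(s) beyond ", signif(maxDistance, 3),
            " mm left unassigned")
    region[far] <- NA_integer_
  }
  data.frame(region = region, distance = distance)
}

#' Average sample expression within regions
#'
#' Region value = mean over the samples assigned to it; regions with no
#' assigned samples are dropped and listed in a message.
#'
#' @param expr gene x sample matrix.
#' @param assignments region id per sample (NA samples are ignored), e.g.
#'   `assignSamples(...)$region`.
#' @param regionIds optional full region id set, to report empty regions.
#' @return gene x region matrix (columns named by region id).
#' @export
regionalExpression <- function(expr, assignments, regionIds = NULL) {
  expr <- as.matrix(expr)
  if (length(assignments) != ncol(expr))
    stop("one assignment per sample required")
  ok <- !is.na(assignments)
  f <- factor(assignments[ok])
  out <- t(apply(expr[, ok, drop = FALSE], 1, function(v) tapply(v, f, mean)))
  if (nrow(expr) == 1) out <- matrix(out, nrow = 1,
                                     dimnames = list(rownames(expr),
                                                     levels(f)))
  if (!is.null(regionIds)) {
    empty <- setdiff(as.character(regionIds), levels(f))
    if (length(empty))
      message("region(s) with no samples dropped: ",
              paste(empty, collapse = ", "))
  }
  out
}

#' Full expression-bundle processing pipeline
#'
#' The fixed processing order: probe-to-gene reassignment (table-driven,
#' from the bundle's probe map), background filter, removal of genes
#' without RNA-seq measures, RNA-seq concordance (rho) filter,
#' representative-probe collapse, then optionally differential-stability
#' filtering (top half) using regional assignments at `dsScale`. Only
#' left-hemisphere samples are retained.
#'
#' @param bundle a [ProbeBundle-class].
#' @param parcellation parcellation used for the DS regional profiles
#'   (required when `applyDS`).
#' @param applyDS apply the differential-stability top-half filter
#'   (default TRUE when a parcellation is given).
#' @param dsScale atlas scale for DS regional profiles (default the
#'   finest label scale).
#' @param rhoThreshold,backgroundThreshold,minSharedSamples see the
#'   individual steps.
#' @param donorNormalise z-score each gene within donor before output
#'   (default FALSE; recorded in the metadata).
#' @return a [SummarizedExperiment::SummarizedExperiment] (assay
#'   `"expr"`, genes x samples) with the sample annotations as `colData`
#'   and a processing log in `metadata()`.
#' @export
processExpressionBundle <- function(bundle, parcellation = NULL,
                                    applyDS = !is.null(parcellation),
                                    dsScale = NULL,
                                    rhoThreshold = 0.2,
                                    backgroundThreshold = 0.5,
                                    minSharedSamples = 4,
                                    donorNormalise = FALSE) {
  ann <- sampleAnnotation(bundle)
  keepS <- ann$hemisphere == "L"
  log <- list(nSamplesIn = nrow(ann), nLeftHemisphere = sum(keepS))
  probes <- filterProbesBackground(bundle, threshold = backgroundThreshold)
  log$nProbesAfterBackground <- length(probes)
  gx <- selectRepresentativeProbes(bundle, probeIds = probes,
                                   rhoThreshold = rhoThreshold,
                                   minSharedSamples = minSharedSamples)
  log$nGenesAfterRho <- nrow(gx)
  gx <- gx[, keepS, drop = FALSE]
  ann <- ann[keepS, , drop = FALSE]
  if (applyDS) {
    if (is.null(parcellation))
      stop("differential stability needs a parcellation")
    if (is.null(dsScale)) dsScale <- scaleNames(parcellation)[1]
    asg <- assignSamples(ann, parcellation, dsScale)
    ds <- differentialStability(gx, ann$donor, asg$region)
    gx <- gx[ds$retained, , drop = FALSE]
    log$nGenesAfterDS <- nrow(gx)
    log$dsScale <- dsScale
  }
  if (donorNormalise) {
    for (dn in unique(ann$donor)) {
      sel <- ann$donor == dn
      gx[, sel] <- t(apply(gx[, sel, drop = FALSE], 1, unitScale))
    }
  }
  log$donorNormalise <- donorNormalise
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = gx),
    colData = S4Vectors::DataFrame(ann, row.names = ann$sample_id),
    metadata = list(processing = log))
}
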