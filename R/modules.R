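#' Choose the soft-thresholding power for a signed network
#'
#' Evaluates candidate powers by the scale-free topology fit: the
#' signed-adjacency connectivities are binned, and the fit is the R^2 of
#' the regression of log10(frequency) on log10(mean connectivity),
#' sign-corrected so an increasing degree distribution counts against the
#' fit. The smallest power reaching `targetR2` is returned; if none does,
#' the fallback power 12 is used with a warning. Fewer than `minUnits`
#' units (samples or regions) is refused outright - co-expression
#' networks estimated on so few spatial units are unreliable, which is
#' why the coarsest (9-unit) scale is excluded from this analysis.
#'
#' @param expr gene x unit matrix.
#' @param candidatePowers integer powers tried (default 1:20).
#' @param targetR2 scale-free fit target (default 0.8).
#' @param minUnits refusal threshold (default 15).
#' @param nBins connectivity histogram bins (default 10).
#' @return chosen power (integer), with attribute `"fitR2"` giving the
#'   fit per candidate.
#' @export
pickSoftPower <- function(expr, candidatePowers = 1:20, targetR2 = 0.8,
                          minUnits = 15, nBins = 10) {
  expr <- as.matrix(expr)
  if (ncol(expr) < minUnits)
    stop("only ", ncol(expr), " units; at least ", minUnits,
         " samples/regions are required for co-expression network analysis")
  cm <- cor(t(expr))
  fits <- vapply(candidatePowers, function(b) {
    A <- signedAdjacency(cm, b)
    k <- rowSums(A) - 1
    scaleFreeFit(k, nBins)
  }, numeric(1))
  ok <- which(fits >= targetR2)
  if (length(ok)) {
    beta <- candidatePowers[ok[1]]
  } else {
    warning("no candidate power reached the scale-free fit target (best ",
            signif(max(fits), 3), "); falling back to power 12")
    beta <- 12L
  }
  attr(beta, "fitR2") <- setNames(fits, candidatePowers)
  beta
}

# Sign-corrected scale-free topology fit R^2 of a connectivity vector.
scaleFreeFit <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  breaks <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  centre <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(0)
  x <- log10(centre[keep]); yv <- log10(freq[keep] / length(k))
  fit <- lm(yv ~ x)
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Signed adjacency from a correlation matrix
#'
#' `A_ij = ((1 + cor_ij) / 2)^beta`, the signed transform that maps
#' correlation -1 to 0 and +1 to 1 instead of folding negative
#' correlations in; the diagonal is forced to 1.
#'
#' @param corMatrix gene x gene correlation matrix.
#' @param beta positive soft-thresholding power.
#' @return adjacency matrix in \[0, 1\].
#' @export
signedAdjacency <- function(corMatrix, beta) {
  if (beta <= 0) stop("beta must be positive")
  cm <- as.matrix(corMatrix)
  if (any(cm < -1 - 1e-9 | cm > 1 + 1e-9))
    stop("correlations must lie in [-1, 1]")
  A <- ((1 + pmin(pmax(cm, -1), 1)) / 2)^beta
  diag(A) <- 1
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)` with
#' the sum over u distinct from i and j and k the connectivity (row sums
#' minus the diagonal); `TOM_ii = 1`. Shared-neighbour smoothing of the
#' adjacency, used as the clustering similarity.
#'
#' @param A adjacency matrix from [signedAdjacency()].
#' @return TOM matrix in \[0, 1\].
#' @export
topologicalOverlap <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("adjacency must be symmetric")
  k <- rowSums(A) - diag(A)
  num <- A %*% A - 2 * A   # removes the u = i and u = j diagonal terms
  num <- num + A           # + A_ij
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  pmin(pmax(tom, 0), 1)
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM
#' with a static tree cut; clusters smaller than `minModuleSize` are
#' assigned to the unassigned ("grey") module 0, and the remaining
#' modules are renumbered by decreasing size. By default the cut is
#' placed at 99% of the dendrogram's top merge height: TOM
#' dissimilarities concentrate just below their between-module merges
#' (more so at higher soft powers), so a relative cut separates modules
#' across power regimes where any fixed absolute height fails.
#'
#' @param tom TOM (or any similarity in \[0, 1\]).
#' @param minModuleSize smallest retained module (default 30).
#' @param cutHeight static tree-cut height on 1 - TOM; `NULL` (default)
#'   uses 0.99 x the maximum merge height.
#' @return list of class `ModulePartition`: `labels` (integer per gene,
#'   0 = grey), `sizes` (named module sizes), `nModules`, `dendrogram`.
#' @export
detectModules <- function(tom, minModuleSize = 30, cutHeight = NULL) {
  tom <- as.matrix(tom)
  dis <- as.dist(1 - tom)
  hc <- hclust(dis, method = "average")
  if (is.null(cutHeight)) cutHeight <- 0.99 * max(hc$height)
  raw <- cutree(hc, h = cutHeight)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= minModuleSize]
  labels <- integer(length(raw))
  if (length(keep)) {
    kept <- sizes[keep]
    ord <- names(kept)[order(-as.integer(kept), as.integer(names(kept)))]
    for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- i
  } else {
    warning("all genes unassigned (grey): no cluster reached the minimum size")
  }
  names(labels) <- rownames(tom)
  out <- list(labels = labels,
              sizes = setNames(tabulate(labels), seq_len(max(labels, 0))),
              nModules = max(labels, 0), cutHeight = cutHeight,
              dendrogram = hc)
  class(out) <- "ModulePartition"
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene x unit expression submatrix (genes standardised first), scaled to
#' unit variance across units, with the sign chosen so that the mean
#' correlation with the member genes is non-negative. The fraction of
#' variance explained by the component is recorded. The grey module (0)
#' is excluded unless requested.
#'
#' @param expr gene x unit matrix (rownames must cover the partition).
#' @param partition a `ModulePartition` from [detectModules()], or an
#'   integer vector of module labels.
#' @param includeGrey also compute an eigengene for module 0
#'   (default FALSE).
#' @return list of class `EigengeneMatrix`: `eigengenes` (module x unit
#'   matrix, rows `ME1, ME2, ...`), `varianceExplained` (per module).
#' @export
moduleEigengenes <- function(expr, partition, includeGrey = FALSE) {
  labels <- if (inherits(partition, "ModulePartition")) partition$labels
  else as.integer(partition)
  expr <- as.matrix(expr)
  if (length(labels) != nrow(expr))
    stop("partition must label every gene (row) of expr")
  mods <- sort(unique(labels[labels > 0]))
  if (includeGrey && any(labels == 0)) mods <- c(0, mods)
  if (!length(mods)) stop("no modules to summarise")
  me <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    sub <- expr[labels == mods[i], , drop = FALSE]
    if (nrow(sub) < 2) stop("module ", mods[i], " has fewer than 2 genes")
    sdv <- apply(sub, 1, sd)
    if (any(sdv == 0))
      stop("module ", mods[i], " contains constant gene(s); ",
           "cannot standardise")
    subs <- (sub - rowMeans(sub)) / sdv
    sv <- svd(t(subs), nu = 1, nv = 0)
    scores <- sv$u[, 1] * sv$d[1]
    scores <- scores / sd(scores)
    if (mean(cor(scores, t(subs))) < 0) scores <- -scores
    me[i, ] <- scores
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  out <- list(eigengenes = me, varianceExplained = ve)
  class(out) <- "EigengeneMatrix"
  out
}

#' One-call signed co-expression decomposition
#'
#' Convenience wrapper chaining [pickSoftPower()], [signedAdjacency()],
#' [topologicalOverlap()], [detectModules()] and [moduleEigengenes()].
#'
#' @param expr gene x unit matrix.
#' @param minModuleSize,cutHeight passed to [detectModules()].
#' @param ... passed to [pickSoftPower()].
#' @return list with `beta`, `fitR2`, `partition`, `eigengenes` (an
#'   `EigengeneMatrix`).
#' @export
coexpressionModules <- function(expr, minModuleSize = 30, cutHeight = NULL,
                                ...) {
  expr <- as.matrix(expr)
  beta <- pickSoftPower(expr, ...)
  A <- signedAdjacency(cor(t(expr)), as.numeric(beta))
  tom <- topologicalOverlap(A)
  part <- detectModules(tom, minModuleSize = minModuleSize,
                        cutHeight = cutHeight)
  eg <- if (part$nModules > 0) moduleEigengenes(expr, part) else NULL
  list(beta = as.integer(beta), fitR2 = attr(beta, "fitR2"),
       partition = part, eigengenes = eg)
}
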