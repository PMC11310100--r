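# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# A small but non-degenerate simulation: 8^3 grid, 60 volumes, 6+6
# subjects, 8 -> 4 -> 2 region hierarchy.
tinyConfig <- function(seed = 1, ...) {
  args <- list(seed = seed, gridDims = c(8, 8, 8), nTimepoints = 60,
               nPerGroup = c(6, 6), regionCounts = c(8, 4, 2),
               effectRegions = c(2, 5), nSamples = 40, nGenes = 60,
               moduleSizes = c(20, 20, 20))
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationConfig, args)
}

# A BoldRun built directly from an array (identity-scaled 3 mm affine).
boldRunFrom <- function(x, tr = 2) {
  d <- dim(x)
  new("BoldRun", subjectId = "test", data = x, trSeconds = tr,
      affine = rehomics:::defaultAffine(d[1:3]))
}

# Hand-built probe bundle: 2 genes x 2 probes x 6 samples, with
# controllable probe values, calls and RNA-seq twin.
toyBundle <- function(expr, calls = NULL, rnaseq = NULL,
                      genes = c("gA", "gA", "gB", "gB"),
                      samples = NULL) {
  nS <- ncol(expr)
  if (is.null(calls)) calls <- matrix(1, nrow(expr), nS,
                                      dimnames = dimnames(expr))
  if (is.null(samples))
    samples <- data.frame(sample_id = paste0("S", seq_len(nS)),
                          donor = rep(c("D1", "D2"), length.out = nS),
                          x = -seq_len(nS), y = 0, z = 0,
                          hemisphere = "L", compartment = "cortical")
  if (is.null(rnaseq)) {
    rnaseq <- expr[!duplicated(genes), , drop = FALSE]
    rownames(rnaseq) <- unique(genes)
  }
  colnames(rnaseq) <- colnames(expr)
  new("ProbeBundle", expr = expr,
      probes = data.frame(probe_id = rownames(expr), gene = genes),
      calls = calls, rnaseq = rnaseq, samples = samples)
}

# Adjusted Rand index (used when mclust is unavailable it is skipped at
# the call site; mclust is the independent oracle in the suite).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Planted 3-module expression matrix built outside the package generator,
# as an independent construction for module-detection tests.
plantedExpression <- function(seed, nGenes = 120, sizes = c(40, 40, 40),
                              nUnits = 60, loading = 1, noise = 0) {
  set.seed(seed)
  lat <- matrix(rnorm(length(sizes) * nUnits), length(sizes), nUnits)
  gm <- rep(seq_along(sizes), sizes)
  X <- loading * lat[gm, , drop = FALSE]
  if (noise > 0) X <- X + matrix(rnorm(length(X), sd = noise), nrow(X))
  extra <- nGenes - sum(sizes)
  if (extra > 0) {
    X <- rbind(X, matrix(rnorm(extra * nUnits), extra))
    gm <- c(gm, rep(0L, extra))
  }
  rownames(X) <- sprintf("g%03d", seq_len(nGenes))
  list(expr = X, modules = gm)
}
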