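# Internal helpers: seeded RNG scoping and small numeric utilities.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic package operations go
# through this so identical seeds give bit-identical output without
# clobbering the user's RNG stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-stage seed from a root seed; keeps results < 2^31 and
# decorrelates stages that share a root.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483587L)
}

# Population standard deviation (divide by N, not N-1).
popSD <- function(x) sqrt(mean((x - mean(x))^2))

# Column ranks of a time x voxel matrix (average ranks for ties).
colRanks <- function(x) apply(x, 2, rank, ties.method = "average")

# 3D voxel (1-based i,j,k) -> world mm using a NIfTI-style affine that maps
# 0-based voxel indices.
voxelToWorld <- function(ijk, affine) {
  ijk0 <- cbind(ijk - 1, 1)
  t(affine %*% t(ijk0))[, 1:3, drop = FALSE]
}

# Standardise a vector to mean 0, sample SD 1 (returns zeros if constant).
unitScale <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Benjamini-Hochberg adjusted p-values (thin wrapper, one place to call).
bhAdjust <- function(p) p.adjust(p, method = "BH")
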