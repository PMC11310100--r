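#' Kendall's coefficient of concordance (W)
#'
#' Agreement of K "raters" (time series) over n "items" (timepoints).
#' Each series is converted to ranks over time (average ranks for ties);
#' with rank sums R_i per timepoint,
#' `W = 12 * sum((R_i - mean(R))^2) / (K^2 * (n^3 - n))`.
#' W is 1 for identical rank orderings and 0 when rank sums are constant.
#' No tie-correction term is applied: BOLD series are continuous and ties
#' arise only from degenerate inputs, which average ranks handle.
#'
#' @param series numeric matrix, K series x n timepoints.
#' @return W in \[0, 1\]. All-constant input returns 0 with a warning.
#' @examples
#' kendallW(rbind(1:4, 1:4, 1:4))  # 1
#' @export
kendallW <- function(series) {
  series <- as.matrix(series)
  k <- nrow(series)
  n <- ncol(series)
  if (k < 2) stop("need at least 2 series (raters)")
  if (n < 2) stop("need at least 2 timepoints")
  if (all(series == series[, 1])) {
    warning("all series constant over time; W undefined, returning 0")
    return(0)
  }
  ranks <- t(apply(series, 1, rank, ties.method = "average"))
  ri <- colSums(ranks)
  s <- sum((ri - mean(ri))^2)
  w <- 12 * s / (k^2 * (n^3 - n))
  min(max(w, 0), 1)
}

# Offsets for the three standard 3D voxel neighbourhoods.
neighbourOffsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = d == 1,
                 "18" = d >= 1 & d <= 2,
                 "26" = d >= 1)
  g[keep, , drop = FALSE]
}

#' Regional homogeneity map (voxelwise Kendall's W)
#'
#' For every in-mask voxel, Kendall's W of the voxel's time series with
#' the time series of its in-mask neighbours under the chosen
#' connectivity (nominally 26, i.e. K = 27 raters in the interior). At
#' mask borders the available in-mask neighbours are used (variable K);
#' voxels with fewer than `minNeighbours` in-mask neighbours are set to 0
#' and flagged invalid (`nRaters` 0). The default threshold of 7 applies
#' to the 26- and 18-neighbour schemes; for 6-connectivity, where a full
#' interior voxel has only 6 neighbours, the default tightens to 6.
#'
#' The computation is vectorised: series are rank-transformed once, then
#' neighbourhood rank sums are accumulated by array shifts, so the map is
#' exact, not an approximation.
#'
#' @param run a [BoldRun-class] (residual-cleaned, band-passed).
#' @param mask logical 3D array; defaults to all voxels.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param minNeighbours minimum in-mask neighbours for a valid voxel
#'   (default `min(7, connectivity)`).
#' @return a [ReHoMap-class] with raw W values.
#' @export
rehoMap <- function(run, mask = NULL, connectivity = 26,
                    minNeighbours = NULL) {
  if (is.null(minNeighbours)) minNeighbours <- min(7, connectivity)
  x <- boldData(run)
  d <- dim(x)
  nt <- d[4]
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask must match the spatial grid")
  mask <- array(as.logical(mask), d[1:3])
  if (!any(mask)) stop("mask is empty")
  offs <- neighbourOffsets(connectivity)

  # ranks over time, per voxel; constant voxels get tied (constant) ranks
  xm <- matrix(x, nrow = prod(d[1:3]), ncol = nt)
  ranks <- matrix(0, nrow(xm), nt)
  inIdx <- which(mask)
  ranks[inIdx, ] <- t(apply(xm[inIdx, , drop = FALSE], 1, rank,
                            ties.method = "average"))
  rank4 <- array(ranks, c(d[1:3], nt))

  padRank <- array(0, c(d[1:3] + 2, nt))
  padMask <- array(FALSE, d[1:3] + 2)
  padRank[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), ] <- rank4 *
    array(rep(mask, nt), c(d[1:3], nt))
  padMask[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask

  rsum <- rank4 * array(rep(mask, nt), c(d[1:3], nt))  # self term
  kcount <- array(as.integer(mask), d[1:3])
  ix <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); iz <- 2:(d[3] + 1)
  for (o in seq_len(nrow(offs))) {
    sx <- ix + offs[o, 1]; sy <- iy + offs[o, 2]; sz <- iz + offs[o, 3]
    rsum <- rsum + padRank[sx, sy, sz, , drop = FALSE]
    kcount <- kcount + padMask[sx, sy, sz]
  }

  kv <- as.vector(kcount)
  rs <- matrix(rsum, nrow = prod(d[1:3]), ncol = nt)
  rbar <- kv * (nt + 1) / 2
  s <- rowSums((rs - rbar)^2)
  w <- 12 * s / (kv^2 * (nt^3 - nt))
  w[!is.finite(w)] <- 0
  w <- pmin(pmax(w, 0), 1)

  valid <- mask & (kcount - 1L) >= minNeighbours
  w[!as.vector(valid)] <- 0
  kcount[!valid] <- 0L
  # constant in-mask voxels have zero rank variance at the self term only
  # if all raters are constant; kendallW convention (W = 0) emerges from
  # s = 0 there, no special-casing needed.
  new("ReHoMap",
      values = array(w, d[1:3]), mask = mask,
      nRaters = kcount, zStandardised = FALSE, affine = voxelAffine(run))
}

#' z-standardise a ReHo map over the mask
#'
#' Subtracts the in-mask mean and divides by the in-mask population
#' standard deviation (divide by N); out-of-mask voxels are zero. Only
#' valid voxels (those with enough neighbours) enter the statistics.
#'
#' @param map a raw [ReHoMap-class].
#' @return a [ReHoMap-class] with `zStandardised = TRUE`.
#' @export
zscoreMap <- function(map) {
  if (isZStandardised(map)) stop("map is already z-standardised")
  v <- mapValues(map)
  sel <- brainMask(map) & map@nRaters > 0
  x <- v[sel]
  s <- popSD(x)
  if (s == 0) stop("constant ReHo map; cannot standardise")
  out <- array(0, dim(v))
  out[sel] <- (x - mean(x)) / s
  initialize(map, values = out, zStandardised = TRUE)
}

#' Regional mean ReHo profile
#'
#' Mean map value over the in-mask, valid voxels of each region at the
#' requested parcellation scale. Regions with no valid voxels get NA with
#' a warning.
#'
#' @param map a [ReHoMap-class].
#' @param parcellation a [HierarchicalParcellation-class] on the same grid.
#' @param scale scale name.
#' @return data.frame with columns `id, value` (one row per region, in
#'   region-id order).
#' @export
regionalMeans <- function(map, parcellation, scale) {
  lab <- scaleLabels(parcellation, scale)
  v <- mapValues(map)
  if (!identical(dim(lab), dim(v)))
    stop("map and parcellation must share the grid")
  ids <- regionTable(parcellation, scale)$id
  sel <- brainMask(map) & map@nRaters > 0 & lab > 0
  sums <- tapply(v[sel], factor(lab[sel], levels = ids), sum)
  cnts <- tapply(rep(1, sum(sel)), factor(lab[sel], levels = ids), sum)
  vals <- as.numeric(sums / cnts)
  if (anyNA(vals))
    warning("region(s) with no valid voxels: ",
            paste(ids[is.na(vals)], collapse = ", "))
  data.frame(id = ids, value = vals)
}
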