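#' Framewise displacement from realignment parameters
#'
#' Scalar head-motion summary per volume: the sum of absolute backward
#' differences of the six rigid-body parameters, with rotations (radians)
#' converted to mm of arc on a sphere of radius `rotationRadius`. The
#' first volume has FD 0 by convention.
#'
#' @param motion a [MotionTrace-class], or a volumes x 6 numeric matrix
#'   (`tx ty tz rx ry rz`; translations mm, rotations radians).
#' @param rotationRadius sphere radius in mm used to convert rotations to
#'   displacement (default 50 mm).
#' @return numeric vector of FD values (mm), one per volume, `FD[1] = 0`.
#' @examples
#' m <- matrix(0, 10, 6); m[5, 1] <- 0.1
#' computeFD(m)[5]  # 0.1
#' @export
computeFD <- function(motion, rotationRadius = 50) {
  p <- if (is(motion, "MotionTrace")) motionParams(motion) else as.matrix(motion)
  if (ncol(p) != 6)
    stop("motion parameters must have 6 columns (3 translations, 3 rotations)")
  if (nrow(p) < 2) stop("need at least 2 volumes to compute FD")
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               rotationRadius * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Build the nuisance regressor matrix
#'
#' Assembles the design used for residual cleaning of BOLD time series:
#' intercept, linear drift, the Friston-24 motion expansion (the six
#' parameters, their one-volume backshifts, and both sets squared), white
#' matter and CSF signals, optionally the global mean signal, and one
#' spike-indicator column per volume whose framewise displacement exceeds
#' `fdThreshold`. Spike regression (rather than volume deletion) keeps the
#' time-series grid intact for the concordance statistic computed later.
#'
#' @param motion a [MotionTrace-class] or volumes x 6 matrix.
#' @param tissueSignals volumes x 2 matrix (columns white matter, CSF), or
#'   a named list/data.frame with elements `wm` and `csf`.
#' @param globalSignal numeric vector of the global mean signal, used iff
#'   `includeGlobal`.
#' @param fd framewise displacement series; computed from `motion` when
#'   `NULL`.
#' @param fdThreshold spike threshold in mm (default 0.5).
#' @param includeGlobal logical; include the global signal column. The
#'   analysis can be run with and without global signal regression for
#'   comparison.
#' @return numeric matrix with named columns; attribute `"spikes"` holds
#'   the indices of flagged volumes.
#' @export
buildNuisance <- function(motion, tissueSignals, globalSignal = NULL,
                          fd = NULL, fdThreshold = 0.5,
                          includeGlobal = !is.null(globalSignal)) {
  p <- if (is(motion, "MotionTrace")) motionParams(motion) else as.matrix(motion)
  if (ncol(p) != 6) stop("motion parameters must have 6 columns")
  n <- nrow(p)
  ts <- if (is.list(tissueSignals) && !is.data.frame(tissueSignals))
    cbind(wm = tissueSignals$wm, csf = tissueSignals$csf)
  else as.matrix(tissueSignals)
  if (nrow(ts) != n) stop("tissue signals must have one row per volume")
  if (is.null(fd)) fd <- computeFD(p)
  if (length(fd) != n) stop("fd must have one value per volume")

  back <- rbind(0, p[-n, , drop = FALSE])  # one-volume backshift
  friston24 <- cbind(p, back, p^2, back^2)
  colnames(friston24) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_lag"),
                           paste0("mp", 1:6, "_sq"),
                           paste0("mp", 1:6, "_lagsq"))
  X <- cbind(intercept = 1, trend = seq_len(n) - (n + 1) / 2, friston24,
             wm = ts[, 1], csf = ts[, 2])
  if (includeGlobal) {
    if (is.null(globalSignal)) stop("includeGlobal = TRUE needs globalSignal")
    if (length(globalSignal) != n)
      stop("globalSignal must have one value per volume")
    X <- cbind(X, global = globalSignal)
  }
  spikes <- which(fd > fdThreshold)
  if (length(spikes) == n) stop("every volume exceeds the FD threshold; no data left")
  for (s in spikes) {
    col <- numeric(n); col[s] <- 1
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- paste0("spike", s)
  }
  attr(X, "spikes") <- spikes
  X
}

#' Regress nuisance covariates out of a time-series matrix
#'
#' Ordinary least-squares residualisation of every column of `ts` against
#' the regressor matrix. Constant-zero columns are removed first; if the
#' remaining design is rank deficient, linearly dependent columns are
#' dropped with a warning. Residuals are orthogonal to every retained
#' regressor.
#'
#' @param ts numeric matrix, timepoints x series (voxels).
#' @param regressors numeric matrix from [buildNuisance()] (or any design
#'   with the same number of rows).
#' @return residual matrix of the same shape as `ts`.
#' @export
regressNuisance <- function(ts, regressors) {
  ts <- as.matrix(ts)
  X <- as.matrix(regressors)
  if (nrow(ts) != nrow(X))
    stop("time series and regressors must have the same number of rows")
  keep <- apply(X, 2, function(v) any(v != v[1])) | colnames(X) == "intercept"
  if (!any(keep)) keep[1] <- TRUE
  X <- X[, keep, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[seq(qx$rank + 1, ncol(X))]
    warning("dropping ", length(drop), " linearly dependent regressor(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    qx <- qr(X)
  }
  qr.resid(qx, ts)
}

#' Band-pass filter BOLD time series
#'
#' Ideal (frequency-domain) band-pass: Fourier components with frequency
#' inside `[lowHz, highHz]` are retained, all others (including the DC
#' term) are zeroed. This preserves pass-band amplitude and fully
#' suppresses out-of-band components on the DFT grid.
#'
#' @param ts numeric matrix, timepoints x series (a vector is treated as
#'   one series).
#' @param trSeconds sampling interval (repetition time) in seconds.
#' @param lowHz,highHz pass-band edges in Hz (defaults 0.01 and 0.08, the
#'   conventional resting-state band).
#' @return filtered matrix (or vector) of the same shape.
#' @export
bandpass <- function(ts, trSeconds, lowHz = 0.01, highHz = 0.08) {
  vec <- is.null(dim(ts))
  x <- if (vec) matrix(ts, ncol = 1) else as.matrix(ts)
  n <- nrow(x)
  nyquist <- 1 / (2 * trSeconds)
  if (lowHz >= highHz) stop("lowHz must be below highHz")
  if (highHz > nyquist)
    stop(sprintf("highHz (%.3g) exceeds the Nyquist frequency (%.3g)",
                 highHz, nyquist))
  freqs <- seq(0, n - 1) / (n * trSeconds)
  freqs <- pmin(freqs, 1 / trSeconds - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= lowHz & freqs <= highHz
  xf <- mvfft(x)
  xf[!keep, ] <- 0
  out <- Re(mvfft(xf, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

#' Merge a fine label volume into a coarser scale
#'
#' Applies a parcellation's merge map: each in-mask voxel's coarse label
#' is the merge-map image of its fine label; background (0) is preserved.
#'
#' @param parcellation a [HierarchicalParcellation-class].
#' @param from,to scale names (fine, coarse) for which a merge map exists.
#' @return integer 3D label array at the coarse scale.
#' @export
mergeParcellation <- function(parcellation, from, to) {
  fine <- scaleLabels(parcellation, from)
  mm <- mergeMap(parcellation, from, to)
  present <- sort(unique(fine[fine > 0]))
  missing <- present[present > length(mm) | is.na(mm[present])]
  if (length(missing))
    stop("fine label(s) missing from merge map: ",
         paste(missing, collapse = ", "))
  out <- fine
  sel <- fine > 0
  out[sel] <- mm[fine[sel]]
  out
}
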