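#' Residual preprocessing of a single run
#'
#' Applies the residual cleaning chain in the fixed order nuisance
#' regression (including spike regressors) then band-pass filtering, and
#' returns a cleaned [BoldRun-class]. Tissue and global signals default
#' to the synthetic-atlas extractors.
#'
#' @param run a [BoldRun-class].
#' @param motion the subject's [MotionTrace-class].
#' @param atlas a [HierarchicalParcellation-class] supplying the mask and
#'   nuisance-signal compartments.
#' @param fdThreshold scrubbing threshold in mm (default 0.5).
#' @param includeGlobal include global signal regression (default TRUE).
#' @param lowHz,highHz pass band (defaults 0.01-0.08 Hz).
#' @return a cleaned [BoldRun-class].
#' @export
preprocessRun <- function(run, motion, atlas, fdThreshold = 0.5,
                          includeGlobal = TRUE, lowHz = 0.01, highHz = 0.08) {
  sig <- extractNuisanceSignals(run, atlas)
  X <- buildNuisance(motion, tissueSignals = list(wm = sig$wm, csf = sig$csf),
                     globalSignal = sig$global, fdThreshold = fdThreshold,
                     includeGlobal = includeGlobal)
  x <- boldData(run)
  d <- dim(x)
  tsm <- t(matrix(x, prod(d[1:3]), d[4]))     # time x voxel
  res <- suppressWarnings(regressNuisance(tsm, X))
  filt <- bandpass(res, trSeconds(run), lowHz = lowHz, highHz = highHz)
  initialize(run, data = array(t(filt), d))
}

#' ReHo feature matrix for a whole cohort
#'
#' Runs each subject through residual preprocessing, the Kendall's-W map,
#' z-standardisation, and (for regional scales) parcellation averaging,
#' and assembles the subjects x features matrix used by the MVPA stage.
#'
#' @param cohort output of [makeCohort()] (or any list with `runs`,
#'   `motion`, `participants`).
#' @param atlas a [HierarchicalParcellation-class].
#' @param scale `"voxel"` for voxel-level features, otherwise an atlas
#'   scale name (e.g. `"scale2"`).
#' @param connectivity neighbourhood for the ReHo map (default 26).
#' @param zscore standardise maps before feature extraction
#'   (default TRUE).
#' @param preprocess apply [preprocessRun()] first (default TRUE).
#' @param ... further arguments to [preprocessRun()].
#' @return a [FeatureDataset-class].
#' @export
cohortFeatures <- function(cohort, atlas, scale = "scale2",
                           connectivity = 26, zscore = TRUE,
                           preprocess = TRUE, ...) {
  mask <- brainMask(atlas)
  feats <- lapply(seq_along(cohort$runs), function(s) {
    run <- cohort$runs[[s]]
    if (preprocess) run <- preprocessRun(run, cohort$motion[[s]], atlas, ...)
    m <- rehoMap(run, mask = mask, connectivity = connectivity)
    if (zscore) m <- zscoreMap(m)
    if (identical(scale, "voxel")) {
      sel <- brainMask(m) & m@nRaters > 0
      mapValues(m)[sel]
    } else {
      regionalMeans(m, atlas, scale)$value
    }
  })
  X <- do.call(rbind, feats)
  featureDataset(X, cohort$participants$group, cohort$participants$id,
                 scale = if (identical(scale, "voxel")) "scale1" else scale)
}
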