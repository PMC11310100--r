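#' @import methods
#' @importFrom stats approx cor cor.test cutree dist fft hclust lm mvfft
#'   p.adjust pchisq pf phyper pnorm prcomp pt qnorm quantile rbinom rnorm
#'   runif sd setNames t.test var predict coef ecdf
#' @importFrom utils head read.delim write.table
NULL

#' BoldRun: a single subject's 4D resting-state acquisition
#'
#' Voxel time series on a regular grid, together with the repetition time
#' and the voxel-to-world affine. Data are assumed already realigned and
#' spatially normalised; this package performs only residual (nuisance)
#' preprocessing.
#'
#' @slot subjectId character scalar.
#' @slot data 4D numeric array, dimensions x, y, z, t.
#' @slot trSeconds repetition time in seconds.
#' @slot affine 4x4 voxel-to-world transform (0-based voxel indices).
#' @exportClass BoldRun
setClass("BoldRun",
  representation(
    subjectId = "character",
    data = "array",
    trSeconds = "numeric",
    affine = "matrix"
  )
)

setValidity("BoldRun", function(object) {
  d <- dim(object@data)
  if (length(d) != 4) return("data must be a 4D array (x, y, z, t)")
  if (d[4] < 2) return("need at least 2 volumes")
  if (!all(dim(object@affine) == c(4, 4))) return("affine must be 4x4")
  if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
  if (object@trSeconds <= 0) return("trSeconds must be positive")
  TRUE
})

#' MotionTrace: per-volume rigid-body motion parameters
#'
#' Six realignment parameters per volume (3 translations in mm, 3
#' rotations in radians). Framewise displacement is derived with
#' [computeFD()].
#'
#' @slot subjectId character scalar.
#' @slot params numeric matrix, volumes x 6, columns
#'   `tx ty tz rx ry rz`.
#' @exportClass MotionTrace
setClass("MotionTrace",
  representation(subjectId = "character", params = "matrix")
)

setValidity("MotionTrace", function(object) {
  if (ncol(object@params) != 6) return("params must have 6 columns")
  if (nrow(object@params) < 2) return("need at least 2 volumes")
  TRUE
})

#' HierarchicalParcellation: nested label volumes linked by merge maps
#'
#' A set of integer label volumes on one grid, ordered fine to coarse,
#' with merge maps sending each fine region id to its coarse parent and a
#' region table (hemisphere, cortical/subcortical compartment) per scale.
#' Label 0 is background at every scale.
#'
#' @slot labels named list of integer 3D arrays, fine to coarse.
#' @slot mergeMaps named list; element `"B->C"` is an integer vector
#'   indexed by the fine-scale region id giving the coarse id.
#' @slot regions named list of per-scale data.frames with columns
#'   `id, name, hemisphere, compartment, nVoxels`.
#' @slot mask logical 3D array; labels are 0 outside the mask.
#' @slot affine 4x4 voxel-to-world transform.
#' @exportClass HierarchicalParcellation
setClass("HierarchicalParcellation",
  representation(
    labels = "list",
    mergeMaps = "list",
    regions = "list",
    mask = "array",
    affine = "matrix"
  )
)

setValidity("HierarchicalParcellation", function(object) {
  sc <- names(object@labels)
  if (is.null(sc) || any(sc == "")) return("label volumes must be named")
  if (!identical(sc, names(object@regions)))
    return("labels and regions must share scale names")
  for (s in sc) {
    lab <- object@labels[[s]]
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids) && !identical(as.integer(ids), seq_along(ids)))
      return(sprintf("region ids at scale '%s' must be contiguous from 1", s))
    if (!identical(sort(object@regions[[s]]$id), as.integer(ids)) &&
        length(ids) > 0)
      return(sprintf("region table at scale '%s' does not match labels", s))
  }
  # coarser labels must equal the merge-map image of finer labels
  for (nm in names(object@mergeMaps)) {
    parts <- strsplit(nm, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% sc))
      return(sprintf("merge map '%s' does not name two known scales", nm))
    fine <- object@labels[[parts[1]]]
    coarse <- object@labels[[parts[2]]]
    mm <- object@mergeMaps[[nm]]
    sel <- fine > 0
    if (!all(coarse[sel] == mm[fine[sel]]))
      return(sprintf("labels at '%s' are not the merge image of '%s'",
                     parts[2], parts[1]))
  }
  TRUE
})

#' ReHoMap: per-voxel Kendall's W (regional homogeneity)
#'
#' Kendall's coefficient of concordance of a voxel's time series with its
#' in-mask neighbours, optionally z-standardised over the mask.
#'
#' @slot values 3D numeric array; raw W in \[0,1\] or z-values.
#' @slot mask logical 3D array.
#' @slot nRaters integer 3D array: the K (voxel + in-mask neighbours)
#'   actually used per voxel; 0 where flagged invalid.
#' @slot zStandardised logical flag.
#' @slot affine 4x4 voxel-to-world transform.
#' @exportClass ReHoMap
setClass("ReHoMap",
  representation(
    values = "array",
    mask = "array",
    nRaters = "array",
    zStandardised = "logical",
    affine = "matrix"
  )
)

setValidity("ReHoMap", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must share dimensions")
  v <- object@values[object@mask & object@nRaters > 0]
  if (!object@zStandardised && length(v) &&
      (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    return("raw W values must lie in [0, 1]")
  TRUE
})

#' FeatureDataset: subjects x features with class labels
#'
#' One per spatial scale; rows are subjects, columns voxel or regional
#' ReHo features. Input to the MVPA stage.
#'
#' @slot features numeric matrix, subjects x features.
#' @slot labels factor with levels `control`, `patient`.
#' @slot subjectIds character vector, unique.
#' @slot scale character scalar naming the spatial scale.
#' @exportClass FeatureDataset
setClass("FeatureDataset",
  representation(
    features = "matrix",
    labels = "factor",
    subjectIds = "character",
    scale = "character"
  )
)

setValidity("FeatureDataset", function(object) {
  n <- nrow(object@features)
  if (length(object@labels) != n) return("labels must match rows")
  if (length(object@subjectIds) != n) return("subjectIds must match rows")
  if (anyDuplicated(object@subjectIds)) return("subject ids must be unique")
  if (nlevels(object@labels) != 2)
    return("labels must have exactly two levels")
  if (anyNA(object@features)) return("features must not contain NA")
  TRUE
})

#' ProbeBundle: microarray probe layer with RNA-seq twin
#'
#' Raw Allen-atlas-style expression bundle: probe x sample intensities,
#' probe-to-gene map, present/absent detection calls, an RNA-seq gene x
#' sample twin used for probe concordance filtering, and per-sample
#' annotations (donor, world coordinates, hemisphere, compartment).
#'
#' @slot expr numeric matrix, probes x samples (rownames = probe ids).
#' @slot probes data.frame with columns `probe_id, gene`.
#' @slot calls 0/1 matrix, same shape as `expr` (1 = above background).
#' @slot rnaseq numeric matrix, genes x samples (rownames = genes).
#' @slot samples data.frame with columns
#'   `sample_id, donor, x, y, z, hemisphere, compartment`.
#' @exportClass ProbeBundle
setClass("ProbeBundle",
  representation(
    expr = "matrix",
    probes = "data.frame",
    calls = "matrix",
    rnaseq = "matrix",
    samples = "data.frame"
  )
)

setValidity("ProbeBundle", function(object) {
  if (!identical(dim(object@expr), dim(object@calls)))
    return("calls must have the same shape as expr")
  if (nrow(object@probes) != nrow(object@expr))
    return("probe table must match expr rows")
  if (anyDuplicated(object@probes$probe_id))
    return("probe ids must be unique (each probe maps to at most one gene)")
  if (nrow(object@samples) != ncol(object@expr))
    return("sample table must match expr columns")
  TRUE
})

setMethod("show", "BoldRun", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldRun '%s': %dx%dx%d grid, %d volumes, TR %.3g s\n",
              object@subjectId, d[1], d[2], d[3], d[4], object@trSeconds))
})

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf("MotionTrace '%s': %d volumes, max |translation| %.3g mm\n",
              object@subjectId, nrow(object@params),
              max(abs(object@params[, 1:3]))))
})

setMethod("show", "HierarchicalParcellation", function(object) {
  cat("HierarchicalParcellation on grid",
      paste(dim(object@mask), collapse = "x"), "\n")
  for (s in names(object@labels))
    cat(sprintf("  %s: %d regions\n", s, nrow(object@regions[[s]])))
})

setMethod("show", "ReHoMap", function(object) {
  cat(sprintf("ReHoMap (%s): %s grid, %d in-mask voxels\n",
              if (object@zStandardised) "z-standardised" else "raw W",
              paste(dim(object@values), collapse = "x"),
              sum(object@mask)))
})

setMethod("show", "FeatureDataset", function(object) {
  cat(sprintf("FeatureDataset [%s]: %d subjects x %d features (%s)\n",
              object@scale, nrow(object@features), ncol(object@features),
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels)), collapse = ", ")))
})

setMethod("show", "ProbeBundle", function(object) {
  cat(sprintf(
    "ProbeBundle: %d probes / %d genes x %d samples, %d donors\n",
    nrow(object@expr), length(unique(object@probes$gene)),
    ncol(object@expr), length(unique(object@samples$donor))))
})
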