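# NIfTI / TSV input-output for the package's data types. Volumes use
# NIfTI-1 via RNifti; tables are plain TSV. Voxel indices are 0-based in
# the affine convention; world coordinates come from the NIfTI transform.

#' Write and read a BOLD run as NIfTI
#'
#' @param run a [BoldRun-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `writeBoldRun` returns `path` invisibly; `readBoldRun` a
#'   [BoldRun-class].
#' @export
writeBoldRun <- function(run, path) {
  img <- RNifti::asNifti(boldData(run))
  RNifti::pixdim(img) <- c(sqrt(colSums(voxelAffine(run)[1:3, 1:3]^2)),
                           trSeconds(run))
  img <- RNifti::`sform<-`(img, structure(voxelAffine(run), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeBoldRun
#' @param subjectId subject id to attach on read.
#' @param trSeconds repetition time override; taken from the header when
#'   NULL.
#' @export
readBoldRun <- function(path, subjectId = basename(path), trSeconds = NULL) {
  img <- RNifti::readNifti(path)
  tr <- if (is.null(trSeconds)) RNifti::pixdim(img)[4] else trSeconds
  new("BoldRun", subjectId = subjectId,
      data = array(as.numeric(img), dim(img)),
      trSeconds = tr, affine = matrix(RNifti::xform(img), 4, 4))
}

#' Write a 3D volume (mask, labels, map) as NIfTI
#'
#' @param volume 3D array.
#' @param affine 4x4 voxel-to-world transform.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, affine, path) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume written by [writeVolume()]
#' @param path NIfTI path.
#' @return list with `data` (array) and `affine`.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       affine = matrix(RNifti::xform(img), 4, 4))
}

#' Write motion parameters as TSV
#'
#' Six columns `tx ty tz rx ry rz` (translations mm, rotations radians),
#' one row per volume.
#'
#' @param motion a [MotionTrace-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeMotionTSV <- function(motion, path) {
  write.table(as.data.frame(motionParams(motion)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMotionTSV
#' @param subjectId subject id to attach on read.
#' @export
readMotionTSV <- function(path, subjectId = basename(path)) {
  m <- as.matrix(read.delim(path))
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  new("MotionTrace", subjectId = subjectId, params = m)
}

#' Write / read a probe bundle as a directory of TSV files
#'
#' Files mirror the usual expression-bundle roles: `probes.tsv`
#' (probe_id, gene), `expression.tsv` (probe x sample), `pacalls.tsv`
#' (0/1), `rnaseq.tsv` (gene x sample), `samples.tsv`
#' (sample_id, donor, x, y, z, hemisphere, compartment).
#'
#' @param bundle a [ProbeBundle-class].
#' @param dir directory to write into (created if missing).
#' @return `dir` (write) or a [ProbeBundle-class] (read).
#' @export
writeProbeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f, rn = TRUE) write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = rn, col.names = NA)
  write.table(probeTable(bundle), file.path(dir, "probes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  wt(probeExpr(bundle), "expression.tsv")
  wt(probeCalls(bundle), "pacalls.tsv")
  wt(rnaseqExpr(bundle), "rnaseq.tsv")
  write.table(sampleAnnotation(bundle), file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeProbeBundle
#' @export
readProbeBundle <- function(dir) {
  rd <- function(f) {
    x <- read.delim(file.path(dir, f), row.names = 1, check.names = FALSE)
    as.matrix(x)
  }
  new("ProbeBundle",
      expr = rd("expression.tsv"),
      probes = read.delim(file.path(dir, "probes.tsv")),
      calls = rd("pacalls.tsv"),
      rnaseq = rd("rnaseq.tsv"),
      samples = read.delim(file.path(dir, "samples.tsv")))
}
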