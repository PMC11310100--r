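#' Normality test with estimated parameters (Monte-Carlo Lilliefors)
#'
#' One-sample Kolmogorov-Smirnov test of the values against a normal
#' distribution with the sample mean and SD. Because the parameters are
#' estimated, the usual KS null is invalid; the p-value is therefore
#' calibrated by a seeded Monte-Carlo null (normal samples of the same
#' size, each standardised the same way), i.e. a Lilliefors correction.
#'
#' @param values numeric vector, n >= 8.
#' @param nsim Monte-Carlo draws (default 2000).
#' @param seed seed of the null simulation; fixed so identical input
#'   gives identical p.
#' @return list with `statistic` (KS D), `p`.
#' @export
ksNormality <- function(values, nsim = 2000, seed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) stop("need at least 8 values")
  if (sd(values) == 0) {
    warning("constant input: not normal by convention, p = 0")
    return(list(statistic = Inf, p = 0))
  }
  ksD <- function(x) {
    z <- sort((x - mean(x)) / sd(x))
    pz <- pnorm(z)
    i <- seq_along(z)
    max(i / length(z) - pz, pz - (i - 1) / length(z))
  }
  d <- ksD(values)
  null <- withSeed(seed, vapply(seq_len(nsim), function(b)
    ksD(rnorm(n)), numeric(1)))
  list(statistic = d, p = (1 + sum(null >= d)) / (nsim + 1))
}

#' Covariate-adjusted two-sample t statistic
#'
#' Linear model `y ~ group + covariates` (with intercept); returns the t
#' statistic and two-sided p of the group coefficient with residual
#' degrees of freedom n - rank. Collinear covariates are dropped with a
#' warning. With covariates orthogonal to both group and outcome this
#' reduces to the pooled two-sample t-test.
#'
#' @param y numeric outcome (e.g. regional ReHo per subject).
#' @param group two-level factor or vector; the reported contrast is the
#'   second level minus the first.
#' @param covariates data.frame or matrix of nuisance covariates (e.g.
#'   age, sex), or NULL.
#' @return list with `t`, `p`, `df`, `estimate`.
#' @export
adjustedTTest <- function(y, group, covariates = NULL) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  X <- cbind(intercept = 1, group = as.numeric(g == levels(g)[2]))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    for (nm in names(cv)) {
      v <- cv[[nm]]
      if (!is.numeric(v)) v <- as.numeric(factor(v))
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- nm
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[seq(qx$rank + 1, ncol(X))]
    if (2 %in% drop) stop("group indicator is collinear with covariates")
    warning("dropping collinear covariate(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    qx <- qr(X)
  }
  n <- length(y)
  df <- n - qx$rank
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  sigma2 <- sum(res^2) / df
  xtxInv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot)]
  se <- sqrt(sigma2 * xtxInv[2, 2])
  tval <- unname(beta[2] / se)
  list(t = tval, p = 2 * pt(-abs(tval), df), df = df,
       estimate = unname(beta[2]))
}

#' Case-control difference profile at a regional scale
#'
#' Covariate-adjusted t statistics of the patient-control difference per
#' region, from a [FeatureDataset-class] of regional values, together
#' with per-region normality p-values and the Bonferroni threshold for
#' the scale.
#'
#' @param dataset a [FeatureDataset-class] (regional features).
#' @param covariates data.frame of per-subject covariates (age, sex).
#' @param alpha family-wise level for the Bonferroni threshold
#'   (default 0.05).
#' @param normality also run [ksNormality()] per region (default TRUE).
#' @return data.frame with columns `unit, t, p, normalityP, significant`;
#'   attribute `"bonferroni"` holds the threshold used.
#' @export
differenceProfile <- function(dataset, covariates, alpha = 0.05,
                              normality = TRUE) {
  X <- featureMatrix(dataset)
  g <- groupLabels(dataset)
  m <- ncol(X)
  thr <- bonferroniThreshold(alpha, m)
  rows <- lapply(seq_len(m), function(j) {
    tt <- adjustedTTest(X[, j], g, covariates)
    np <- if (normality) ksNormality(X[, j])$p else NA_real_
    data.frame(unit = j, t = tt$t, p = tt$p, normalityP = np)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < thr
  attr(out, "bonferroni") <- thr
  out
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level.
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroniThreshold(0.05, 272)  # 1.84e-4
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Mean t value in a sphere around each tissue sample
#'
#' For each sample coordinate, the mean of the map over the in-mask
#' voxels whose world-space centres lie within `radius` mm. Samples whose
#' sphere covers no voxel are returned as NA and listed in a message.
#'
#' @param tmap 3D numeric array (e.g. a t-statistic map).
#' @param sampleCoords data.frame or matrix with columns `x, y, z`
#'   (world mm).
#' @param affine 4x4 voxel-to-world transform of the map.
#' @param mask logical 3D array (default: all voxels).
#' @param radius sphere radius in mm (default 6).
#' @return numeric vector, one mean t per sample.
#' @export
sphereSampleT <- function(tmap, sampleCoords, affine, mask = NULL,
                          radius = 6) {
  if (radius <= 0) stop("radius must be positive")
  d <- dim(tmap)
  if (is.null(mask)) mask <- array(TRUE, d)
  idx <- which(mask, arr.ind = TRUE)
  centres <- voxelToWorld(idx, affine)
  vals <- tmap[idx]
  pts <- as.matrix(as.data.frame(sampleCoords)[, c("x", "y", "z")])
  out <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (centres[, 1] - pts[i, 1])^2 + (centres[, 2] - pts[i, 2])^2 +
      (centres[, 3] - pts[i, 3])^2
    sel <- d2 <= radius^2
    if (!any(sel)) return(NA_real_)
    mean(vals[sel])
  }, numeric(1))
  if (anyNA(out))
    message(sum(is.na(out)), " sample(s) with no voxel inside the sphere")
  out
}

#' Correlate module eigengenes with case-control t values
#'
#' Pearson correlation of each module eigengene with the t values across
#' units (samples or regions), separately within the cortical and
#' subcortical compartments, whose expression profiles differ too
#' sharply to pool. Benjamini-Hochberg correction is applied within each
#' compartment across modules; raw p-values are reported alongside.
#' Compartments with fewer than 3 units are omitted with a message.
#'
#' @param eigengenes module x unit matrix (an `EigengeneMatrix`'s
#'   `eigengenes` component, or any numeric matrix).
#' @param tValues numeric vector of t values aligned with the units.
#' @param compartments character vector (`"cortical"`/`"subcortical"`)
#'   per unit.
#' @return data.frame with columns
#'   `module, compartment, n_units, r, p, q`.
#' @export
meTCorrelation <- function(eigengenes, tValues, compartments) {
  if (inherits(eigengenes, "EigengeneMatrix"))
    eigengenes <- eigengenes$eigengenes
  eigengenes <- as.matrix(eigengenes)
  if (ncol(eigengenes) != length(tValues) ||
      length(tValues) != length(compartments))
    stop("eigengenes, tValues and compartments must align on units")
  ok <- !is.na(tValues)
  rows <- list()
  for (cp in unique(compartments[ok])) {
    sel <- ok & compartments == cp
    if (sum(sel) < 3) {
      message("compartment '", cp, "' omitted: fewer than 3 units")
      next
    }
    for (m in rownames(eigengenes)) {
      ct <- cor.test(eigengenes[m, sel], tValues[sel], method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        module = m, compartment = cp, n_units = sum(sel),
        r = unname(ct$estimate), p = ct$p.value)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no compartment had enough units")
  out$q <- NA_real_
  for (cp in unique(out$compartment))
    out$q[out$compartment == cp] <- bhAdjust(out$p[out$compartment == cp])
  out
}

#' Group comparison of demographics
#'
#' Age by pooled two-sample t-test; sex by Pearson chi-square on the 2x2
#' count table (df = 1, no continuity correction).
#'
#' @param table data.frame with columns `group`, `age`, `sex`.
#' @return data.frame with rows `age` and `sex` and columns
#'   `statistic, df, p`.
#' @export
compareDemographics <- function(table) {
  need <- c("group", "age", "sex")
  if (!all(need %in% names(table)))
    stop("table must have columns group, age, sex")
  g <- factor(table$group)
  if (nlevels(g) != 2) stop("exactly two groups required")
  tt <- t.test(table$age ~ g, var.equal = TRUE)
  counts <- base::table(g, factor(table$sex))
  chi <- chisqTest2x2(counts)
  data.frame(
    variable = c("age", "sex"),
    statistic = c(unname(tt$statistic), chi$statistic),
    df = c(unname(tt$parameter), 1),
    p = c(tt$p.value, chi$p))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, df = 1:
#' `X^2 = sum (O - E)^2 / E` with expected counts from the margins.
#'
#' @param counts 2x2 matrix of counts.
#' @return list with `statistic`, `p`, `expected`.
#' @examples
#' chisqTest2x2(matrix(c(54, 45, 49, 65), 2))  # p = 0.092
#' @export
chisqTest2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) stop("empty margin: expected count of 0")
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expected)
}
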