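#' Filter variants by minor allele frequency
#'
#' Retains variants with MAF strictly greater than `threshold`;
#' monomorphic variants (MAF 0 or undefined) are always removed.
#'
#' @param g a [GenotypeMatrix-class].
#' @param threshold MAF threshold (default 0.05; retained iff
#'   `maf > threshold`).
#' @return A filtered [GenotypeMatrix-class].
#' @export
variantMafFilter <- function(g, threshold = 0.05) {
  maf <- mafs(g)
  keep <- !is.na(maf) & maf > threshold & maf > 0
  g[, which(keep)]
}

#' Genomic relationship (kinship) matrix
#'
#' `K = Z Z' / M` with `Z` the column-standardized dosage matrix (each
#' variant mean 0, unit variance) and `M` the number of variants.
#' Missing dosages are mean-imputed per variant before standardizing
#' (the GRM only; association scans use complete cases).
#'
#' @param g a [GenotypeMatrix-class] with at least 2 polymorphic
#'   variants.
#' @return symmetric n x n matrix with sample ids as dimnames.
#' @export
computeGrm <- function(g) {
  d <- dosages(g)
  mu <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mu[j]
  }
  sds <- apply(d, 2, stats::sd)
  poly <- sds > 0
  if (sum(poly) < 2)
    stop("computeGrm needs >= 2 variants with nonzero variance")
  Z <- scale(d[, poly, drop = FALSE])
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}

#' Genomic principal components from a kinship matrix
#'
#' Top eigenvectors of the kinship matrix by eigenvalue, with a
#' deterministic sign convention: in each PC the loading of largest
#' magnitude is positive.
#'
#' @param k symmetric kinship matrix (PSD up to -1e-8).
#' @param n_pcs number of components (default 3; must be <
#'   `nrow(k)`).
#' @return matrix n x n_pcs with columns `PC1..PCn` (orthonormal).
#' @export
genomicPcs <- function(k, n_pcs = 3) {
  if (n_pcs >= nrow(k)) stop("n_pcs must be < number of samples")
  if (max(abs(k - t(k))) > 1e-8) stop("kinship matrix must be symmetric")
  e <- eigen((k + t(k)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(1, max(abs(e$values))))
    stop("kinship matrix is not positive semi-definite within tolerance")
  V <- e$vectors[, seq_len(n_pcs), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(rownames(k), paste0("PC", seq_len(n_pcs)))
  V
}

#' Remove covariate effects from a phenotype by linear regression
#'
#' OLS residuals of the phenotype on an intercept plus the covariate
#' columns (typically age, sex, PC1..PC3). Missing phenotype values
#' propagate; covariates must be complete for samples with phenotype.
#'
#' @param y numeric phenotype vector (may contain `NA`).
#' @param covariates data.frame or matrix of covariates, rows aligned
#'   with `y`.
#' @return numeric vector of residuals, `NA` where `y` was missing.
#' @export
residualizeCovariates <- function(y, covariates) {
  X <- cbind(1, as.matrix(covariates))
  ok <- !is.na(y) & stats::complete.cases(X)
  if (qr(X[ok, , drop = FALSE])$rank < ncol(X))
    stop("covariate design matrix is rank-deficient")
  fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
  out <- rep(NA_real_, length(y))
  out[ok] <- fit$residuals
  out
}

#' Rank-based inverse normal transform (Blom offsets)
#'
#' `z_i = qnorm((rank_i - 3/8) / (n + 1/4))` with average ranks for
#' ties, applied to the non-missing values of the vector; missing
#' values stay missing. Strictly rank-monotone on distinct values.
#'
#' @param values numeric vector with >= 3 non-missing values, not all
#'   identical.
#' @return transformed numeric vector.
#' @examples
#' round(inverseNormalTransform(c(10, 20, 30)), 4)
#' @export
inverseNormalTransform <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3)
    stop("inverse normal transform needs >= 3 non-missing values")
  if (length(unique(x)) == 1)
    stop("all values identical: ranks undefined")
  n <- length(x)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) /
                      (n + 1 / 4))
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}

#' Build the scan-ready phenotype matrix
#'
#' Applies the two-stage transform to every row of a
#' [RatioPhenotypeTable-class] (or any phenotype matrix): covariate
#' residualization first, then the rank-based inverse normal transform.
#'
#' @param ratios a [RatioPhenotypeTable-class] or numeric matrix
#'   (phenotypes x samples).
#' @param covariates data.frame/matrix of covariates (age, sex,
#'   PC1..PC3), rows aligned with the samples.
#' @return numeric matrix of transformed phenotypes (rows as input).
#' @export
preparePhenotypes <- function(ratios, covariates) {
  m <- if (methods::is(ratios, "SummarizedExperiment"))
    SummarizedExperiment::assay(ratios) else ratios
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    r <- residualizeCovariates(m[i, ], covariates)
    out[i, ] <- inverseNormalTransform(r)
  }
  out
}
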