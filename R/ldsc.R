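#' Harmonize GWAS summary statistics against a reference variant panel
#'
#' Matches variants by id and allele pair in either orientation,
#' flipping the sign of `beta`/`z` when the alleles are swapped
#' relative to the reference. Strand-ambiguous variants (A/T, C/G) are
#' dropped, as are variants falling in configured exclusion regions
#' (e.g. the MHC). A `chi2 = z^2` column is attached.
#'
#' @param ss sumstats data.frame ([readSumstats()] layout).
#' @param reference data.frame with `variant_id`, `effect_allele`,
#'   `other_allele` (e.g. built from [variantInfo()]: ALT as effect
#'   allele) and optionally `chrom`, `pos`.
#' @param exclusion_regions optional data.frame `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @return harmonized sumstats data.frame in reference orientation with
#'   `chi2`; errors when fewer than 10 variants survive.
#' @export
mungeHarmonize <- function(ss, reference, exclusion_regions = NULL) {
  i <- match(ss$variant_id, reference$variant_id)
  keep <- !is.na(i)
  ss <- ss[keep, , drop = FALSE]
  ref <- reference[i[keep], , drop = FALSE]
  ea <- toupper(ss$effect_allele); oa <- toupper(ss$other_allele)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- ea == comp[oa]
  same <- ea == ref$effect_allele & oa == ref$other_allele
  swapped <- ea == ref$other_allele & oa == ref$effect_allele
  keep2 <- (same | swapped) & !ambiguous
  ss <- ss[keep2, , drop = FALSE]
  flip <- swapped[keep2]
  ss$beta[flip] <- -ss$beta[flip]
  ss$z[flip] <- -ss$z[flip]
  tmp <- ss$effect_allele[flip]
  ss$effect_allele[flip] <- ss$other_allele[flip]
  ss$other_allele[flip] <- tmp
  if (!is.null(exclusion_regions) && nrow(ss) > 0) {
    excl <- rep(FALSE, nrow(ss))
    for (r in seq_len(nrow(exclusion_regions))) {
      er <- exclusion_regions[r, ]
      excl <- excl | (!is.na(ss$chrom) & ss$chrom == er$chrom &
                        !is.na(ss$pos) & ss$pos >= er$start &
                        ss$pos <= er$end)
    }
    ss <- ss[!excl, , drop = FALSE]
  }
  if (nrow(ss) < 10)
    stop("fewer than 10 variants survive harmonization")
  ss$chi2 <- ss$z^2
  rownames(ss) <- NULL
  ss
}

#' Windowed per-annotation LD scores
#'
#' For variant j and annotation c,
#' `l(j, c) = sum_k a_kc * r2_adj(j, k)` over variants k within
#' `window_bp` of j (self-pair included). With `adjusted = TRUE` the
#' squared correlation is bias-corrected as
#' `r2 - (1 - r2) / (n - 2)` (unbiased under independence); the
#' self-pair stays exactly 1. Missing dosages are mean-imputed.
#'
#' @param g a [GenotypeMatrix-class] (the LD reference panel).
#' @param ann numeric matrix variants x annotations (row order matching
#'   `g`), binary or non-negative weights; include a base column of 1s
#'   for the all-SNP annotation.
#' @param window_bp symmetric physical window in bp (> 0). On the
#'   synthetic genome the genetic map is 1 cM/Mb, so the conventional
#'   1-cM window is `1e6`.
#' @param adjusted use the bias-adjusted r-squared (default TRUE).
#' @return data.frame `variant_id` plus one LD-score column per
#'   annotation.
#' @export
computeLdScores <- function(g, ann, window_bp = 1e6, adjusted = TRUE) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  d <- dosages(g)
  v <- variantInfo(g)
  m <- ncol(d)
  if (nrow(ann) != m) stop("annotation rows must match variants")
  ann <- as.matrix(ann)
  mu <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(m)) {
    nas <- is.na(d[, j]); if (any(nas)) d[nas, j] <- mu[j]
  }
  n <- nrow(d)
  Z <- scale(d)
  Z[is.na(Z)] <- 0   # monomorphic columns contribute r = 0
  denom <- n - 1
  ell <- matrix(0, m, ncol(ann),
                dimnames = list(colnames(d), colnames(ann)))
  chunk <- 256L
  for (s in seq(1L, m, by = chunk)) {
    cols <- s:min(s + chunk - 1L, m)
    lo <- min(v$pos[cols]) - window_bp
    hi <- max(v$pos[cols]) + window_bp
    widx <- which(v$chrom %in% unique(v$chrom[cols]) &
                    v$pos >= lo & v$pos <= hi)
    R <- crossprod(Z[, widx, drop = FALSE], Z[, cols, drop = FALSE]) / denom
    R2 <- R^2
    if (adjusted) R2 <- R2 - (1 - R2) / (n - 2)
    for (k in seq_along(cols)) {
      j <- cols[k]
      inwin <- v$chrom[widx] == v$chrom[j] &
        abs(v$pos[widx] - v$pos[j]) <= window_bp
      r2 <- R2[inwin, k]
      self <- widx[inwin] == j
      r2[self] <- 1   # exact self-pair, untouched by adjustment
      ell[j, ] <- colSums(ann[widx[inwin], , drop = FALSE] * r2)
    }
  }
  data.frame(variant_id = colnames(d), ell, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Stratified LD score regression fit
#'
#' Regresses GWAS chi-square statistics on per-annotation LD scores,
#' `E[chi2_j] = N * sum_c tau_c * l(j, c) + intercept` (intercept
#' free), with the two-step LDSC weighting scheme: a first unweighted
#' pass yields a rough total heritability, then weights
#' `1 / max(l_base, 1) * 1 / (1 + N * h2bar * l_base / M)^2` correct
#' for over-counting and heteroskedasticity. Per-annotation
#' heritability is `h2_c = sum_{j in c} sum_c' tau_c' a_jc'`, the
#' enrichment score is the proportion of h2 divided by the proportion
#' of SNPs, and standard errors come from a delete-one block jackknife
#' over contiguous variant blocks. The one-sided p-value for
#' enrichment > 1 is computed from the annotation coefficient's
#' jackknife z-statistic (for a binary annotation fitted on top of the
#' all-SNP base, enrichment > 1 is equivalent to tau > 0, and the tau
#' statistic is well calibrated where the enrichment-ratio statistic is
#' conservative); it is `NA` for the base annotation, whose enrichment
#' is identically 1. Block length should be large relative to the LD
#' correlation length for trustworthy jackknife errors.
#'
#' @param ss harmonized sumstats with `chi2` and `n`
#'   ([mungeHarmonize()]).
#' @param ld LD-score table from [computeLdScores()].
#' @param ann annotation matrix (variants x annotations) aligned with
#'   `ld` rows; first column should be the all-1 base annotation.
#' @param n_blocks jackknife blocks (default 200, capped at the number
#'   of variants).
#' @return An [SLDSCFit-class].
#' @export
sldscFit <- function(ss, ld, ann, n_blocks = 200) {
  i <- match(ld$variant_id, ss$variant_id)
  use <- !is.na(i)
  chi2 <- ss$chi2[i[use]]
  N <- stats::median(ss$n[i[use]], na.rm = TRUE)
  L <- as.matrix(ld[use, -1, drop = FALSE])
  A <- as.matrix(ann)[use, , drop = FALSE]
  if (!identical(colnames(L), colnames(A)))
    L <- L[, colnames(A), drop = FALSE]
  M <- nrow(A)
  X <- cbind(`(intercept)` = 1, N * L)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_c <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear annotation LD scores: ",
         paste(drop_c, collapse = ", "))
  }
  base <- L[, 1]
  tau0 <- qr.coef(qrX, chi2)[-1]
  h2bar <- min(max(sum(A %*% tau0), 1e-3), 1)
  w <- 1 / pmax(base, 1) * 1 / (1 + N * h2bar * base / M)^2
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- chi2 * sw
  XtX <- crossprod(Xw)
  Xty <- crossprod(Xw, yw)
  coefs <- solve(XtX, Xty)[, 1]
  n_blocks <- as.integer(min(n_blocks, M))
  bnd <- floor(seq(0, M, length.out = n_blocks + 1))
  per_snp_h2 <- function(tau) as.vector(A %*% tau)
  summarize <- function(tau) {
    psh <- per_snp_h2(tau)
    h2_tot <- sum(psh)
    h2_c <- as.vector(crossprod(A, psh))
    prop_snps <- colSums(A) / M
    prop_h2 <- h2_c / h2_tot
    enr <- prop_h2 / prop_snps
    list(h2_tot = h2_tot, h2_c = h2_c, enr = enr,
         prop_h2 = prop_h2, prop_snps = prop_snps)
  }
  full <- summarize(coefs[-1])
  # delete-one-block estimates from block-wise sufficient statistics
  theta <- matrix(NA_real_, n_blocks, length(coefs) - 1)
  enr_jk <- matrix(NA_real_, n_blocks, ncol(A))
  h2_jk <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- (bnd[b] + 1):bnd[b + 1]
    Xb <- Xw[rows, , drop = FALSE]
    cf_b <- solve(XtX - crossprod(Xb),
                  Xty - crossprod(Xb, yw[rows]))[, 1]
    tau_b <- cf_b[-1]
    theta[b, ] <- tau_b
    sm <- summarize(tau_b)
    enr_jk[b, ] <- sm$enr
    h2_jk[b] <- sm$h2_tot
  }
  jk_se <- function(est) {
    mns <- colMeans(est)
    sqrt((n_blocks - 1) / n_blocks *
           colSums(sweep(est, 2, mns)^2))
  }
  tau_se <- jk_se(theta)
  enr_se <- jk_se(enr_jk)
  # one-sided test of enrichment > 1 through the annotation coefficient:
  # for a binary annotation on top of the all-SNP base, enrichment > 1
  # is equivalent to tau > 0, and the tau jackknife z-statistic is much
  # better calibrated than the enrichment-ratio statistic. NA for base
  # (its enrichment is identically 1).
  p1 <- stats::pnorm((coefs[-1]) / tau_se, lower.tail = FALSE)
  p1[!is.finite(tau_se) | tau_se == 0] <- NA_real_
  p1[1] <- NA_real_
  tab <- data.frame(annotation = colnames(A), h2 = full$h2_c,
                    prop_h2 = full$prop_h2, prop_snps = full$prop_snps,
                    enrichment = full$enr, jackknife_se = enr_se,
                    p_one_sided = p1, stringsAsFactors = FALSE)
  methods::new("SLDSCFit",
    tau = stats::setNames(coefs[-1], colnames(A)),
    tauSE = stats::setNames(tau_se, colnames(A)),
    intercept = unname(coefs[1]), h2Total = full$h2_tot, table = tab,
    nBlocks = n_blocks,
    meta = list(N = N, M = M,
                h2_total_se = stats::sd(h2_jk) *
                  sqrt((n_blocks - 1)^2 / n_blocks)))
}

#' Schedule of enrichment tests over tissues and traits
#'
#' One stratified-LDSC enrichment test is scheduled per (tissue,
#' trait) pair; 13 tissue annotations by 114 traits gives 1,482 tests.
#'
#' @param tissues character vector of tissue annotation ids.
#' @param traits character vector of trait ids.
#' @return data.frame with columns `tissue`, `trait`, one row per
#'   scheduled test.
#' @export
enrichmentTestPlan <- function(tissues, traits) {
  grid <- expand.grid(tissue = tissues, trait = traits,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid[order(grid$tissue, grid$trait), , drop = FALSE]
}

#' One-sided enrichment tests with per-tissue FDR
#'
#' `p = P(Z > (enrichment - 1) / se)` tests enrichment > 1; the FDR is
#' Benjamini-Hochberg within each tissue across its traits.
#'
#' @param tab data.frame with columns `tissue`, `trait`, `enrichment`,
#'   `se` (jackknife SE of the enrichment).
#' @return `tab` with `p_one_sided` and `fdr` columns; zero SEs yield
#'   `NA` p-values (flagged, not dropped).
#' @export
enrichmentTestAndFdr <- function(tab) {
  p <- stats::pnorm((tab$enrichment - 1) / tab$se, lower.tail = FALSE)
  p[is.na(tab$se) | tab$se <= 0] <- NA_real_
  tab$p_one_sided <- p
  tab$fdr <- NA_real_
  for (ts in unique(tab$tissue)) {
    sel <- tab$tissue == ts & !is.na(tab$p_one_sided)
    tab$fdr[sel] <- stats::p.adjust(tab$p_one_sided[sel], method = "BH")
  }
  tab
}

#' Relative heritability enrichment of two gene sets (delta method)
#'
#' Ratio of two enrichment scores (e.g. irQTL genes vs other genes)
#' with a first-order delta-method standard error assuming the two fits
#' are independent:
#' `se^2 = se_num^2 / denom^2 + num^2 * se_denom^2 / denom^4`.
#'
#' @param enr_num,se_num enrichment and SE of the numerator gene set.
#' @param enr_denom,se_denom enrichment and SE of the denominator set
#'   (`enr_denom` must be > 0).
#' @return list with `ratio`, `se` and a `meta` note on the
#'   independence assumption.
#' @export
relativeEnrichmentDelta <- function(enr_num, se_num, enr_denom,
                                    se_denom) {
  if (enr_denom <= 0) stop("denominator enrichment must be > 0")
  ratio <- enr_num / enr_denom
  se <- sqrt(se_num^2 / enr_denom^2 +
               enr_num^2 * se_denom^2 / enr_denom^4)
  list(ratio = ratio, se = se,
       meta = "delta-method SE assuming independent fits")
}
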