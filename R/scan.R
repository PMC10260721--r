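#' Cis window around a gene
#'
#' `[gene_start - half_width, gene_end + half_width]`, clamped at 1;
#' both endpoints inclusive.
#'
#' @param gene one-row gene-model record (or list) with `start`, `end`.
#' @param half_width window half-width in bp (default 1e6).
#' @return integer vector `c(window_start, window_end)`.
#' @examples
#' cisWindow(list(start = 2e6, end = 2.1e6))
#' @export
cisWindow <- function(gene, half_width = 1e6) {
  c(max(1, gene$start - half_width), gene$end + half_width)
}

#' Vectorized per-variant simple linear regression scan
#'
#' Regresses one phenotype on each variant's dosage with the
#' closed-form simple-regression solution, computed from sufficient
#' statistics in one vectorized pass: `beta = cov(x, y) / var(x)`,
#' `se = sqrt(RSS / ((n - 2) * sum((x - xbar)^2)))`, `t = beta / se`,
#' and a two-sided Student-t p-value with `n - 2` df. Missing dosages
#' are handled pairwise (complete cases per variant). Variants with
#' zero dosage variance among complete cases, or fewer than 3 complete
#' cases, yield `NA` records rather than errors. p-values below the
#' smallest positive normal double are floored there, never 0.
#'
#' @param y numeric phenotype vector aligned with the samples of `g`
#'   (pre-residualized and inverse-normal transformed upstream).
#' @param g a [GenotypeMatrix-class].
#' @return data.frame with one row per variant: `variant_id`, `chrom`,
#'   `pos`, `maf`, `beta`, `se`, `t`, `p`, `n`.
#' @export
fastOlsScan <- function(y, g) {
  X <- dosages(g)
  stopifnot(length(y) == nrow(X))
  v <- variantInfo(g)
  yok <- !is.na(y)
  X <- X[yok, , drop = FALSE]
  yy <- y[yok]
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  n <- colSums(M)
  Sx <- colSums(X0)
  Sxx <- colSums(X0^2)
  Sxy <- as.vector(crossprod(X0, yy))
  Sy <- as.vector(crossprod(M, yy))
  Syy <- as.vector(crossprod(M, yy^2))
  Sxx_c <- Sxx - Sx^2 / n
  Sxy_c <- Sxy - Sx * Sy / n
  Syy_c <- Syy - Sy^2 / n
  ok <- n >= 3 & Sxx_c > 1e-12
  beta <- ifelse(ok, Sxy_c / Sxx_c, NA_real_)
  rss <- pmax(Syy_c - beta^2 * Sxx_c, 0)
  se <- ifelse(ok, sqrt(rss / ((n - 2) * Sxx_c)), NA_real_)
  tstat <- ifelse(se > 0, beta / se, ifelse(ok, sign(beta) * Inf, NA_real_))
  p <- 2 * stats::pt(abs(tstat), df = pmax(n - 2, 1), lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  p[!ok] <- NA_real_
  data.frame(variant_id = colnames(X0), chrom = v$chrom, pos = v$pos,
             maf = v$maf, beta = beta, se = se, t = tstat, p = p,
             n = as.integer(n), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select the lead variant of a locus
#'
#' The variant with the smallest p-value; ties are broken by smaller
#' absolute distance to the TSS, then lexicographic variant id. The
#' signed TSS distance is measured in the direction of transcription:
#' `pos - tss` on the `+` strand, `tss - pos` on the `-` strand.
#'
#' @param records association records of one locus ([fastOlsScan()]
#'   rows).
#' @param tss gene TSS (1-based bp).
#' @param strand `"+"` or `"-"`.
#' @return one-row data.frame (the lead record with
#'   `distance_to_tss`), or `NULL` when every record is `NA` (the
#'   locus is dropped, with a message).
#' @export
selectLeadVariant <- function(records, tss, strand = "+") {
  ok <- !is.na(records$p)
  if (!any(ok)) {
    message("selectLeadVariant: all records NA, locus dropped")
    return(NULL)
  }
  r <- records[ok, , drop = FALSE]
  dist <- if (strand == "+") r$pos - tss else tss - r$pos
  o <- order(r$p, abs(dist), r$variant_id)
  lead <- r[o[1], , drop = FALSE]
  lead$distance_to_tss <- dist[o[1]]
  rownames(lead) <- NULL
  lead
}

#' Retain significant loci and estimate the FDR of the scan
#'
#' Loci whose lead p-value is strictly below `alpha` are retained. The
#' scan-wide FDR is the plug-in expected-false-positive ratio
#' `alpha * n_tests / n_significant_records`, undefined (NA) when
#' nothing is significant.
#'
#' @param loci data.frame of loci with a `lead_p` column.
#' @param p numeric vector of all association p-values of the scan.
#' @param alpha genome-wide significance threshold (default 5e-8).
#' @param n_tests total number of tests (default `length(p)`).
#' @return list with `loci` (retained rows) and `diagnostics` (list:
#'   `lambda_median`, `lambda_q25`, `n_tests`, `n_significant`,
#'   `fdr_estimate`).
#' @export
significantLociAndFdr <- function(loci, p, alpha = 5e-8,
                                  n_tests = length(p)) {
  if (n_tests < length(p))
    stop("n_tests must be at least the number of records")
  keep <- !is.na(loci$lead_p) & loci$lead_p < alpha
  n_sig <- sum(p < alpha, na.rm = TRUE)
  fdr <- if (n_sig > 0) alpha * n_tests / n_sig else NA_real_
  pp <- p[!is.na(p)]
  diagnostics <- list(
    lambda_median = if (length(pp)) inflationFactor(pp, 0.5) else NA_real_,
    lambda_q25 = if (length(pp)) inflationFactor(pp, 0.25) else NA_real_,
    n_tests = n_tests, n_significant = n_sig, fdr_estimate = fdr)
  list(loci = loci[keep, , drop = FALSE], diagnostics = diagnostics)
}

#' Genomic inflation factor
#'
#' `lambda_q`: the q-quantile of the observed chi-square(1) statistics
#' (`qchisq(1 - p, 1)`) divided by the q-quantile of the chi-square(1)
#' distribution. The median chi-square(1) is about 0.45494; a
#' well-calibrated null gives `lambda ~= 1`.
#'
#' @param p vector of p-values in (0, 1].
#' @param q quantile (default 0.5, the median).
#' @return numeric inflation factor.
#' @export
inflationFactor <- function(p, q = 0.5) {
  p <- p[!is.na(p)]
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (length(p) < 100)
    warning("fewer than 100 p-values; inflation estimate unstable")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  as.numeric(stats::quantile(chi, q) / stats::qchisq(q, df = 1))
}

#' Cis scan of a phenotype matrix with locus and lead-variant calling
#'
#' For every phenotype row, scans the variants inside the cis window of
#' the phenotype's gene (gene body +/- `half_width`) with
#' [fastOlsScan()], then calls the lead variant per (phenotype, locus)
#' pair. One (phenotype, locus) pair with its lead variant is the unit
#' of a QTL here.
#'
#' @param phenos numeric matrix, phenotypes x samples (rows named),
#'   already residualized and transformed (see [preparePhenotypes()]).
#' @param genotypes a [GenotypeMatrix-class], samples aligned with
#'   `phenos` columns.
#' @param models gene-model table ([readGeneModels()] format).
#' @param pheno2gene character vector mapping each phenotype row to its
#'   gene id (default: rows are gene ids themselves).
#' @param half_width cis half-width in bp (default 1e6).
#' @return list with `loci` (data.frame: one row per phenotype-locus
#'   with lead fields) and `p` (numeric vector of all association
#'   p-values computed).
#' @export
mapCisLoci <- function(phenos, genotypes, models,
                       pheno2gene = rownames(phenos),
                       half_width = 1e6) {
  v <- variantInfo(genotypes)
  out <- vector("list", nrow(phenos))
  pvals <- vector("list", nrow(phenos))
  for (i in seq_len(nrow(phenos))) {
    gid <- pheno2gene[i]
    gene <- models[models$gene_id == gid, , drop = FALSE]
    if (nrow(gene) != 1) stop("phenotype maps to unknown gene: ", gid)
    win <- cisWindow(gene, half_width)
    idx <- which(v$chrom == gene$chrom & v$pos >= win[1] & v$pos <= win[2])
    if (length(idx) == 0) next
    rec <- fastOlsScan(phenos[i, ], genotypes[, idx])
    pvals[[i]] <- rec$p
    lead <- selectLeadVariant(rec, gene$tss, gene$strand)
    if (is.null(lead)) next
    out[[i]] <- data.frame(
      phenotype_id = rownames(phenos)[i], gene_id = gid,
      chrom = gene$chrom, window_start = win[1], window_end = win[2],
      lead_variant = lead$variant_id, lead_p = lead$p,
      lead_beta = lead$beta, lead_se = lead$se,
      lead_pos = lead$pos, distance_to_tss = lead$distance_to_tss,
      n = lead$n, n_variants = length(idx),
      stringsAsFactors = FALSE)
  }
  list(loci = do.call(rbind, out),
       p = unlist(pvals, use.names = FALSE))
}
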