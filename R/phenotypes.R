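#' Convert isoform counts to TPM
#'
#' `TPM_t = (count_t / length_t) / sum_u(count_u / length_u) * 1e6` per
#' sample. A sample whose counts are all zero has no defined TPM and
#' becomes an all-missing column, with a warning.
#'
#' @param counts an [ExpressionTable-class] with unit `"counts"`.
#' @param lengths named numeric vector of isoform lengths in bp (> 0),
#'   covering every isoform in `counts`.
#' @return An [ExpressionTable-class] with unit `"tpm"`.
#' @examples
#' m <- matrix(c(3, 1), 2, 1, dimnames = list(c("i1", "i2"), "s1"))
#' et <- ExpressionTable(m, "counts")
#' SummarizedExperiment::assay(countsToTpm(et, c(i1 = 300, i2 = 100)))
#' @export
countsToTpm <- function(counts, lengths) {
  if (expressionUnit(counts) != "counts")
    stop("countsToTpm expects a counts table")
  m <- SummarizedExperiment::assay(counts)
  miss <- setdiff(rownames(m), names(lengths))
  if (length(miss))
    stop("missing isoform length(s): ", paste(utils::head(miss, 5),
                                              collapse = ", "))
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop("isoform lengths must be > 0")
  rate <- m / len
  tot <- colSums(rate, na.rm = TRUE)
  zero <- tot == 0
  if (any(zero))
    warning(sprintf("%d sample(s) with all-zero counts set to missing: %s",
                    sum(zero),
                    paste(utils::head(colnames(m)[zero], 5), collapse = ", ")))
  tpm <- sweep(rate, 2, ifelse(zero, NA_real_, tot), "/") * 1e6
  ExpressionTable(tpm, unit = "tpm",
                  isoform_info = SummarizedExperiment::rowData(counts))
}

#' Sample-level quality control on zero-count genes
#'
#' A sample is removed when the fraction of genes with zero total count
#' is half or more (strictly `>= 0.5`); gene totals are sums of the
#' gene's isoform counts.
#'
#' @param counts an [ExpressionTable-class] with unit `"counts"`.
#' @param models gene-model table from [readGeneModels()] (or the
#'   simulator).
#' @return character vector of retained sample ids (possibly empty,
#'   with a warning).
#' @export
sampleQc <- function(counts, models) {
  if (expressionUnit(counts) != "counts")
    stop("sampleQc operates on the pre-TPM counts table")
  m <- SummarizedExperiment::assay(counts)
  map <- tx2gene(models)
  gene_of <- map$gene_id[match(rownames(m), map$isoform_id)]
  if (anyNA(gene_of))
    stop("isoform(s) not assigned to any gene: ",
         paste(utils::head(rownames(m)[is.na(gene_of)], 5), collapse = ", "))
  gene_tot <- rowsum(m, gene_of)
  frac_zero <- colMeans(gene_tot == 0)
  keep <- frac_zero < 0.5
  if (!any(keep)) warning("sampleQc retained no samples")
  colnames(m)[keep]
}

#' Compute isoform-ratio phenotypes from TPM
#'
#' For every multi-isoform gene, the gene-level TPM is the sum of its
#' isoforms' TPM and each isoform's ratio is its TPM divided by that
#' sum. Single-isoform genes are excluded. Samples where a gene's total
#' TPM is zero get missing ratios for that gene (the gene's per-sample
#' mask).
#'
#' @param tpm an [ExpressionTable-class] with unit `"tpm"`.
#' @param models gene-model table from [readGeneModels()].
#' @return A [RatioPhenotypeTable-class].
#' @export
computeIsoformRatios <- function(tpm, models) {
  if (expressionUnit(tpm) != "tpm")
    stop("computeIsoformRatios expects a TPM table")
  m <- SummarizedExperiment::assay(tpm)
  map <- tx2gene(models)
  gene_of <- map$gene_id[match(rownames(m), map$isoform_id)]
  if (anyNA(gene_of))
    stop("isoform(s) not assigned to any gene: ",
         paste(utils::head(rownames(m)[is.na(gene_of)], 5), collapse = ", "))
  multi <- names(which(table(gene_of) >= 2))
  keep <- gene_of %in% multi
  m <- m[keep, , drop = FALSE]
  gene_of <- gene_of[keep]
  ord <- order(match(gene_of, models$gene_id))
  m <- m[ord, , drop = FALSE]
  gene_of <- gene_of[ord]
  gene_tot <- rowsum(ifelse(is.na(m), 0, m), gene_of)[gene_of, , drop = FALSE]
  gene_tot[gene_tot == 0] <- NA_real_
  ratios <- m / gene_tot
  RatioPhenotypeTable(ratios, gene_id = gene_of, isoform_id = rownames(m))
}
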