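#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GenotypeMatrix: sample-by-variant dosage matrix with variant metadata
#'
#' Container for hard-call allele dosages (counts of the effect allele,
#' 0/1/2 or `NA`) together with per-variant metadata: chromosome, 1-based
#' position, reference and effect alleles, and minor allele frequency
#' computed over non-missing calls.
#'
#' @slot dosages numeric matrix, samples in rows, variants in columns;
#'   entries in \{0, 1, 2, NA\}. Row names are sample identifiers, column
#'   names variant identifiers.
#' @slot variants [S4Vectors::DataFrame] with one row per variant and
#'   columns `chrom`, `pos`, `ref`, `alt`, `maf`. `alt` is the effect
#'   (dosage-counted) allele.
#'
#' @details Validity enforces dosages in \{0,1,2,NA\}, stored MAF equal to
#'   the MAF recomputed from the dosages (to 1e-12), and non-decreasing
#'   positions within each chromosome.
#'
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", variants = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  v <- object@variants
  msg <- character()
  needed <- c("chrom", "pos", "ref", "alt", "maf")
  if (!all(needed %in% colnames(v)))
    msg <- c(msg, paste("variants must have columns:",
                        paste(setdiff(needed, colnames(v)), collapse = ", ")))
  if (ncol(d) != nrow(v))
    msg <- c(msg, "ncol(dosages) must equal nrow(variants)")
  dv <- d[!is.na(d)]
  if (length(dv) && !all(dv %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg) == 0 && ncol(d) > 0) {
    maf <- .maf_from_dosages(d)
    comparable <- !is.na(maf) & !is.na(v$maf)
    if (any(abs(maf[comparable] - v$maf[comparable]) > 1e-12))
      msg <- c(msg, "stored maf does not match maf recomputed from dosages")
    for (chr in unique(v$chrom)) {
      p <- v$pos[v$chrom == chr]
      if (is.unsorted(p)) {
        msg <- c(msg, sprintf("positions not non-decreasing on %s", chr))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

.maf_from_dosages <- function(d) {
  n <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * n)
  maf <- pmin(f, 1 - f)
  maf[n == 0] <- NA_real_
  maf
}

#' Construct a GenotypeMatrix
#'
#' @param dosages samples x variants matrix of effect-allele dosages
#'   (0/1/2/NA) with row and column names.
#' @param variants data.frame or DataFrame with columns `chrom`, `pos`,
#'   `ref`, `alt` (and optionally `maf`; recomputed when absent).
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' d <- matrix(c(0, 1, 2, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("v1", "v2")))
#' v <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G")
#' GenotypeMatrix(d, v)
#' @export
GenotypeMatrix <- function(dosages, variants) {
  variants <- as(variants, "DataFrame")
  if (is.null(variants$maf))
    variants$maf <- .maf_from_dosages(dosages)
  rownames(variants) <- colnames(dosages)
  new("GenotypeMatrix", dosages = dosages, variants = variants)
}

#' ExpressionTable: isoform-by-sample expression values
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding non-negative
#' isoform expression (rows = isoforms, columns = samples) with a unit
#' flag: `"counts"` or `"tpm"`. For TPM tables every column with any
#' non-missing value sums to 1e6 (to 1e-3 relative tolerance).
#'
#' @slot unit character, `"counts"` or `"tpm"`.
#' @export
setClass("ExpressionTable",
  contains = "SummarizedExperiment",
  representation(unit = "character"))

setValidity("ExpressionTable", function(object) {
  msg <- character()
  if (length(object@unit) != 1 || !object@unit %in% c("counts", "tpm"))
    msg <- c(msg, "unit must be 'counts' or 'tpm'")
  x <- SummarizedExperiment::assay(object)
  if (any(x < 0, na.rm = TRUE))
    msg <- c(msg, "expression values must be non-negative")
  if (length(msg) == 0 && identical(object@unit, "tpm") && ncol(x) > 0) {
    cs <- colSums(x, na.rm = TRUE)
    live <- colSums(!is.na(x)) > 0
    if (any(abs(cs[live] - 1e6) > 1e-3 * 1e6))
      msg <- c(msg, "TPM columns must sum to 1e6 (1e-3 relative)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionTable
#'
#' @param values isoform x sample matrix, row names isoform ids, column
#'   names sample ids.
#' @param unit `"counts"` or `"tpm"`.
#' @param isoform_info optional data.frame of per-isoform metadata
#'   (e.g. `gene_id`), one row per isoform.
#' @return An [ExpressionTable-class].
#' @export
ExpressionTable <- function(values, unit = c("counts", "tpm"),
                            isoform_info = NULL) {
  unit <- match.arg(unit)
  rd <- if (is.null(isoform_info)) DataFrame(row.names = rownames(values))
        else as(isoform_info, "DataFrame")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = values), rowData = rd)
  new("ExpressionTable", se, unit = unit)
}

#' RatioPhenotypeTable: per-isoform usage-ratio phenotypes
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `ratio` holds, for each (gene, isoform) row and each sample, the
#' isoform's share of its gene's total TPM (in \[0, 1\], or `NA` where the
#' gene is unexpressed in that sample). Row metadata carries `gene_id`
#' and `isoform_id`; only multi-isoform genes are admitted, and within
#' each gene the non-missing ratios of a sample sum to 1 (to 1e-9).
#'
#' @export
setClass("RatioPhenotypeTable", contains = "SummarizedExperiment")

setValidity("RatioPhenotypeTable", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("gene_id", "isoform_id") %in% colnames(rd)))
    return("rowData must have gene_id and isoform_id")
  x <- SummarizedExperiment::assay(object)
  if (any(x < -1e-12 | x > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "ratios must lie in [0, 1]")
  tab <- table(rd$gene_id)
  if (any(tab < 2))
    msg <- c(msg, "single-isoform genes are not allowed")
  if (length(msg) == 0 && nrow(x) > 0 && ncol(x) > 0) {
    sums <- rowsum(ifelse(is.na(x), 0, x), rd$gene_id)
    nmiss <- rowsum((!is.na(x)) + 0, rd$gene_id)
    full <- nmiss == as.vector(tab[rownames(nmiss)])
    if (any(abs(sums[full] - 1) > 1e-9))
      msg <- c(msg, "per-gene ratios must sum to 1 for complete samples")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RatioPhenotypeTable
#'
#' @param ratios matrix of ratios, rows = isoforms, columns = samples.
#' @param gene_id character vector, gene of each row.
#' @param isoform_id character vector, isoform of each row.
#' @return A [RatioPhenotypeTable-class].
#' @export
RatioPhenotypeTable <- function(ratios, gene_id, isoform_id) {
  rownames(ratios) <- isoform_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = ratios),
    rowData = DataFrame(gene_id = gene_id, isoform_id = isoform_id))
  new("RatioPhenotypeTable", se)
}

#' SLDSCFit: a stratified LD score regression fit
#'
#' Holds per-annotation heritability coefficients (tau), the regression
#' intercept, the total SNP heritability, and a per-annotation table of
#' heritability share, SNP share, enrichment score (share of h2 divided
#' by share of SNPs), block-jackknife standard errors, and the one-sided
#' p-value for enrichment > 1.
#'
#' @slot tau named numeric, per-annotation per-SNP heritability
#'   coefficients.
#' @slot tauSE named numeric, jackknife standard errors of `tau`.
#' @slot intercept numeric, free regression intercept.
#' @slot h2Total numeric, estimated total SNP heritability.
#' @slot table data.frame with columns `annotation`, `h2`, `prop_h2`,
#'   `prop_snps`, `enrichment`, `jackknife_se`, `p_one_sided`.
#' @slot nBlocks integer, number of jackknife blocks.
#' @slot meta list of fitting metadata (weights scheme, window, sample
#'   size).
#' @export
setClass("SLDSCFit",
  representation(tau = "numeric", tauSE = "numeric", intercept = "numeric",
                 h2Total = "numeric", table = "data.frame",
                 nBlocks = "integer", meta = "list"))

setValidity("SLDSCFit", function(object) {
  tab <- object@table
  msg <- character()
  if (nrow(tab)) {
    ok <- is.finite(tab$prop_snps) & is.finite(tab$prop_h2)
    bad <- abs(tab$enrichment[ok] - tab$prop_h2[ok] / tab$prop_snps[ok]) > 1e-9
    if (any(bad, na.rm = TRUE))
      msg <- c(msg, "enrichment must equal prop_h2 / prop_snps")
    if (any(tab$prop_snps <= 0 | tab$prop_snps > 1))
      msg <- c(msg, "prop_snps must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})
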