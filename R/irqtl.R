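#' Cross-filter isoform-ratio QTL against gene-level eQTL
#'
#' The final irQTL definition: an isoform-ratio locus is retained when
#' its lead variant is genome-wide significant for the isoform ratio
#' (`p_irqtl < alpha`) and shows no gene-level eQTL effect at that same
#' variant (`p_eqtl > eqtl_p`, strictly). The gene-level p-value is
#' looked up at the irQTL lead variant in the gene-level scan of the
#' same gene.
#'
#' @param irqtl_loci loci data.frame from [mapCisLoci()] on isoform
#'   ratios (with `gene_id`, `lead_variant`, `lead_p`).
#' @param eqtl_records data.frame of gene-level association records
#'   with columns `gene_id`, `variant_id`, `p` (e.g. [fastOlsScan()]
#'   output per gene, row-bound with the gene id attached).
#' @param alpha irQTL significance threshold (default 5e-8).
#' @param eqtl_p eQTL exclusion threshold (default 0.05).
#' @return data.frame of irQTL calls: the input loci plus `p_eqtl` and
#'   logical `retained`.
#' @export
irqtlVsEqtlFilter <- function(irqtl_loci, eqtl_records, alpha = 5e-8,
                              eqtl_p = 0.05) {
  key <- paste(eqtl_records$gene_id, eqtl_records$variant_id)
  hit <- match(paste(irqtl_loci$gene_id, irqtl_loci$lead_variant), key)
  if (anyNA(hit)) {
    miss <- irqtl_loci$lead_variant[is.na(hit)]
    stop("lead variant(s) absent from the gene-level scan: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  out <- irqtl_loci
  out$p_eqtl <- eqtl_records$p[hit]
  out$retained <- !is.na(out$lead_p) & out$lead_p < alpha &
    !is.na(out$p_eqtl) & out$p_eqtl > eqtl_p
  out
}

#' Count overlap of QTL calls with a reference table
#'
#' Set semantics: the number of distinct call identifiers (lead
#' variants in `"variant"` mode, genes in `"gene"` mode) that appear in
#' the reference identifier set. No double counting.
#'
#' @param calls irQTL call data.frame (with `lead_variant`, `gene_id`).
#' @param reference character vector of reference identifiers.
#' @param mode `"variant"` or `"gene"`.
#' @return integer overlap count.
#' @export
overlapWithReference <- function(calls, reference,
                                 mode = c("variant", "gene")) {
  mode <- match.arg(mode)
  ids <- switch(mode, variant = calls$lead_variant, gene = calls$gene_id)
  length(intersect(unique(ids), unique(reference)))
}

#' Odds ratio of QTL membership in a functional annotation
#'
#' 2x2 table: `a` QTL variants inside the annotation, `b` QTL variants
#' outside, `c` other variants inside, `d` other variants outside.
#' `OR = a d / (b c)` with a 95% Wald CI on the log scale,
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`; when any cell is
#' zero the Haldane-Anscombe +0.5 correction is applied to all cells.
#' The CI lower bound is the conservative headline figure.
#'
#' @param qtl_variants character vector of QTL variant ids.
#' @param all_variants character vector of the full variant universe.
#' @param annotation character vector of annotated variant ids.
#' @return list with `or`, `ci_low`, `ci_high` and the table `cells`.
#' @export
annotationOddsRatio <- function(qtl_variants, all_variants, annotation) {
  qtl <- unique(qtl_variants)
  other <- setdiff(unique(all_variants), qtl)
  ann <- unique(annotation)
  a <- sum(qtl %in% ann); b <- length(qtl) - a
  cc <- sum(other %in% ann); d <- length(other) - cc
  if (a + b == 0 || cc + d == 0)
    stop("empty margin in the 2x2 annotation table")
  cells <- c(a = a, b = b, c = cc, d = d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  halfw <- 1.96 * sqrt(sum(1 / cells))
  list(or = unname(or),
       ci_low = unname(exp(log(or) - halfw)),
       ci_high = unname(exp(log(or) + halfw)),
       cells = c(a = a, b = b, c = cc, d = d))
}
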