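#' @include AllClasses.R
NULL

#' Accessors for GenotypeMatrix
#'
#' `dosages` returns the samples x variants dosage matrix, `variantInfo`
#' the per-variant metadata, `mafs` the per-variant minor allele
#' frequencies, `sampleIDs`/`variantIDs` the identifiers.
#'
#' @param x a [GenotypeMatrix-class].
#' @return `dosages`: numeric matrix; `variantInfo`: DataFrame; `mafs`:
#'   named numeric; `sampleIDs`, `variantIDs`: character.
#' @name GenotypeMatrix-accessors
NULL

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) x@variants)

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("mafs", "GenotypeMatrix", function(x) {
  stats::setNames(x@variants$maf, colnames(x@dosages))
})

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("sampleIDs", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("variantIDs", function(x) standardGeneric("variantIDs"))

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("variantIDs", "GenotypeMatrix", function(x) colnames(x@dosages))

#' @describeIn GenotypeMatrix-accessors number of samples and variants.
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosages))

#' Subset a GenotypeMatrix by samples (i) and/or variants (j)
#'
#' MAF is recomputed for the retained samples.
#'
#' @param x a [GenotypeMatrix-class].
#' @param i sample index or names.
#' @param j variant index or names.
#' @param ... ignored.
#' @param drop ignored, always FALSE.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosages
  v <- x@variants
  if (!missing(i)) d <- d[i, , drop = FALSE]
  if (!missing(j)) {
    d <- d[, j, drop = FALSE]
    v <- v[j, , drop = FALSE]
  }
  v$maf <- .maf_from_dosages(d)
  new("GenotypeMatrix", dosages = d, variants = v)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants\n",
              nrow(object@dosages), ncol(object@dosages)))
  v <- object@variants
  if (nrow(v)) {
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(v$chrom), collapse = ", ")))
    cat(sprintf("  MAF range: [%.4g, %.4g]\n",
                min(v$maf, na.rm = TRUE), max(v$maf, na.rm = TRUE)))
    miss <- mean(is.na(object@dosages))
    cat(sprintf("  missing dosages: %.2f%%\n", 100 * miss))
  }
})

#' Expression unit of an ExpressionTable
#' @param x an [ExpressionTable-class].
#' @return `"counts"` or `"tpm"`.
#' @export
setGeneric("expressionUnit", function(x) standardGeneric("expressionUnit"))

#' @rdname expressionUnit
#' @export
setMethod("expressionUnit", "ExpressionTable", function(x) x@unit)

setMethod("show", "ExpressionTable", function(object) {
  cat(sprintf("ExpressionTable (%s): %d isoforms x %d samples\n",
              object@unit, nrow(object), ncol(object)))
})

setMethod("show", "RatioPhenotypeTable", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf(
    "RatioPhenotypeTable: %d isoforms of %d multi-isoform genes x %d samples\n",
    nrow(object), length(unique(rd$gene_id)), ncol(object)))
})

#' Per-annotation result table of an SLDSCFit
#' @param x an [SLDSCFit-class].
#' @return data.frame of per-annotation h2 partition, enrichment,
#'   jackknife SE and one-sided p.
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname enrichmentTable
#' @export
setMethod("enrichmentTable", "SLDSCFit", function(x) x@table)

#' Coefficients of an SLDSCFit (per-annotation tau and intercept)
#' @param object an [SLDSCFit-class].
#' @param ... ignored.
#' @export
setMethod("coef", "SLDSCFit", function(object, ...) {
  c(intercept = object@intercept, object@tau)
})

setMethod("show", "SLDSCFit", function(object) {
  cat(sprintf("SLDSCFit: %d annotations, %d jackknife blocks\n",
              nrow(object@table), object@nBlocks))
  cat(sprintf("  h2 total: %.4g   intercept: %.4g\n",
              object@h2Total, object@intercept))
  print(utils::head(object@table, 5), row.names = FALSE)
  if (nrow(object@table) > 5) cat("  ...\n")
})
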