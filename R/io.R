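#' Read biallelic genotypes from a VCF file
#'
#' Parses a VCF 4.x file with hard genotype calls (GT) into a
#' [GenotypeMatrix-class]. Dosage is the count of ALT alleles in the GT
#' field; the effect allele is the VCF ALT. MAF is computed over
#' non-missing calls. Records are ordered by (chrom, pos, variant id),
#' so the result is deterministic given the file.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return A [GenotypeMatrix-class].
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "irQTL")
#' g <- readGenotypesVcf(vcf)
#' mafs(g)
#' @export
readGenotypesVcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    bad <- fix[which(multi)[1], ]
    stop(sprintf("multi-allelic record at %s:%s (ALT=%s); only biallelic records are supported",
                 bad$CHROM, bad$POS, bad$ALT))
  }
  fmt <- v@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) "GT" %in% f, logical(1))))
    stop("VCF records lack a GT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("|", "/", gt, fixed = TRUE)
  count_alt <- function(s) {
    if (is.na(s) || s %in% c(".", "./.")) return(NA_real_)
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (any(parts == ".")) return(NA_real_)
    sum(parts == "1")
  }
  dos <- matrix(vapply(alleles, count_alt, numeric(1)),
                nrow = nrow(gt), dimnames = dimnames(gt))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS, "_", fix$REF, "_", fix$ALT),
                fix$ID)
  pos <- as.integer(fix$POS)
  ord <- order(fix$CHROM, pos, ids)
  dos <- t(dos[ord, , drop = FALSE])
  colnames(dos) <- ids[ord]
  GenotypeMatrix(dos, data.frame(
    chrom = fix$CHROM[ord], pos = pos[ord],
    ref = fix$REF[ord], alt = fix$ALT[ord],
    stringsAsFactors = FALSE))
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' Emits a sites+GT VCF 4.2 file that [readGenotypesVcf()] reads back
#' bit-identically (unphased diploid GT, missing calls as `./.`).
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(g, path) {
  v <- variantInfo(g)
  d <- dosages(g)
  gt_of <- c("0/0", "0/1", "1/1")
  body <- apply(d, 2, function(col) {
    out <- rep("./.", length(col))
    ok <- !is.na(col)
    out[ok] <- gt_of[col[ok] + 1]
    out
  })
  # body: samples x variants -> rows are variants in the file
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleIDs(g)), collapse = "\t"))
  recs <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(v$chrom[j], v$pos[j], colnames(d)[j], v$ref[j], v$alt[j],
            ".", "PASS", ".", "GT", body[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, recs), path)
  invisible(path)
}

#' Read gene models from GFF3 or a BED-like TSV
#'
#' Builds one record per gene with its transcript (isoform) set. GFF3
#' input must contain `gene` features and `transcript`/`mRNA` features
#' whose `Parent` names a gene; TSV input has columns
#' `gene_id, chrom, start, end, strand, transcript_id` (header
#' required). Coordinates are 1-based inclusive. The TSS is the gene
#' start on the `+` strand and the gene end on the `-` strand.
#'
#' @param path path to a `.gff`/`.gff3` file or a TSV.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `n_isoforms` and a list-column `isoforms`.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    genes <- df[df$type == "gene", , drop = FALSE]
    tx <- df[df$type %in% c("transcript", "mRNA"), , drop = FALSE]
    parent <- vapply(tx$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
    tab <- data.frame(gene_id = parent,
                      chrom = as.character(tx$seqnames),
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_,
                      transcript_id = tx$ID,
                      stringsAsFactors = FALSE)
    gdf <- data.frame(gene_id = genes$ID,
                      chrom = as.character(genes$seqnames),
                      start = genes$start, end = genes$end,
                      strand = as.character(genes$strand),
                      stringsAsFactors = FALSE)
    .assemble_gene_models(gdf, tab)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    needed <- c("gene_id", "chrom", "start", "end", "strand",
                "transcript_id")
    if (!all(needed %in% colnames(tab)))
      stop("gene model TSV must have columns: ",
           paste(setdiff(needed, colnames(tab)), collapse = ", "))
    gdf <- unique(tab[, c("gene_id", "chrom", "start", "end", "strand")])
    .assemble_gene_models(gdf, tab)
  }
}

.assemble_gene_models <- function(gdf, tx) {
  tx$gene_id[!is.na(tx$gene_id) & tx$gene_id == ""] <- NA_character_
  gdf <- gdf[!is.na(gdf$gene_id) & gdf$gene_id != "", , drop = FALSE]
  if (anyDuplicated(gdf$gene_id))
    stop("conflicting duplicate gene_id: ",
         paste(unique(gdf$gene_id[duplicated(gdf$gene_id)]), collapse = ", "))
  orphan <- setdiff(tx$gene_id, gdf$gene_id)
  orphan <- orphan[!is.na(orphan)]
  if (length(orphan) || anyNA(tx$gene_id))
    stop("transcript(s) with unknown parent gene: ",
         paste(utils::head(stats::na.omit(c(orphan,
           tx$transcript_id[is.na(tx$gene_id)])), 5), collapse = ", "))
  iso <- split(tx$transcript_id, tx$gene_id)[gdf$gene_id]
  for (g in gdf$gene_id)
    if (anyDuplicated(iso[[g]]))
      stop("duplicate isoform ids within gene ", g)
  if (!all(gdf$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(gdf$start > gdf$end)) stop("gene start must be <= end")
  out <- data.frame(gene_id = gdf$gene_id, chrom = gdf$chrom,
                    start = as.integer(gdf$start), end = as.integer(gdf$end),
                    strand = gdf$strand,
                    tss = ifelse(gdf$strand == "+",
                                 as.integer(gdf$start), as.integer(gdf$end)),
                    n_isoforms = lengths(iso),
                    stringsAsFactors = FALSE)
  out$isoforms <- I(unname(iso))
  out
}

#' Map isoforms to genes from a gene-model table
#' @param models output of [readGeneModels()] (or the simulator).
#' @return data.frame with columns `isoform_id`, `gene_id`.
#' @export
tx2gene <- function(models) {
  data.frame(isoform_id = unlist(models$isoforms, use.names = FALSE),
             gene_id = rep(models$gene_id, lengths(models$isoforms)),
             stringsAsFactors = FALSE)
}

.sumstats_aliases <- list(
  variant_id = c("variant_id", "snp", "rsid", "variant", "id"),
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("pos", "bp", "position"),
  effect_allele = c("effect_allele", "a1", "alt", "ea"),
  other_allele = c("other_allele", "a2", "ref", "oa", "nea"),
  beta = c("beta", "b", "effect"),
  se = c("se", "stderr"),
  p = c("p", "pval", "p_value", "pvalue"),
  n = c("n", "nsample", "samplesize"),
  z = c("z", "zscore"))

#' Read GWAS summary statistics from a TSV
#'
#' Accepts the common SNP/CHR/POS/A1/A2/BETA/SE/P/N header dialect
#' (case-insensitive, with usual aliases). Mandatory content: a variant
#' id, both alleles, `beta` or `z`, `se` or `n`, and `p`. Rows whose
#' numeric fields fail to parse are dropped with a message; the dropped
#' count is attached as attribute `n_dropped`. When absent, `z` is
#' filled from `beta/se`.
#'
#' @param path TSV path.
#' @return data.frame of class `sumstats` with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `p`,
#'   `n`, `z`.
#' @export
readSumstats <- function(path) {
  if (!file.exists(path)) stop("sumstats file not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, colClasses = "character")
  lc <- tolower(colnames(raw))
  pick <- function(key) {
    hit <- which(lc %in% .sumstats_aliases[[key]])
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  cols <- lapply(stats::setNames(names(.sumstats_aliases),
                                 names(.sumstats_aliases)), pick)
  missing_req <- c(
    if (is.null(cols$variant_id)) "variant id (SNP)",
    if (is.null(cols$effect_allele) || is.null(cols$other_allele))
      "allele columns (A1/A2)",
    if (is.null(cols$beta) && is.null(cols$z)) "beta or z",
    if (is.null(cols$se) && is.null(cols$n)) "se or n",
    if (is.null(cols$p)) "p")
  if (length(missing_req))
    stop("sumstats file missing mandatory columns: ",
         paste(missing_req, collapse = "; "))
  num <- function(x) if (is.null(x)) rep(NA_real_, nrow(raw))
                     else suppressWarnings(as.numeric(x))
  out <- data.frame(
    variant_id = cols$variant_id,
    chrom = if (is.null(cols$chrom)) NA_character_ else cols$chrom,
    pos = if (is.null(cols$pos)) NA_integer_
          else suppressWarnings(as.integer(cols$pos)),
    effect_allele = toupper(cols$effect_allele),
    other_allele = toupper(cols$other_allele),
    beta = num(cols$beta), se = num(cols$se), p = num(cols$p),
    n = num(cols$n), z = num(cols$z),
    stringsAsFactors = FALSE)
  bad <- is.na(out$p) |
    (is.na(out$beta) & is.na(out$z)) |
    (is.na(out$se) & is.na(out$n)) |
    out$p <= 0 | out$p > 1 |
    (!is.na(out$se) & out$se <= 0)
  n_dropped <- sum(bad)
  if (n_dropped > 0)
    message(sprintf("readSumstats: dropped %d row(s) with unparseable or invalid numerics", n_dropped))
  out <- out[!bad, , drop = FALSE]
  fill <- is.na(out$z) & !is.na(out$beta) & !is.na(out$se)
  out$z[fill] <- out$beta[fill] / out$se[fill]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Write GWAS summary statistics as TSV
#' @param ss sumstats data.frame (as returned by [readSumstats()] or the
#'   simulator).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$variant_id, CHR = ss$chrom, POS = ss$pos,
                    A1 = ss$effect_allele, A2 = ss$other_allele,
                    BETA = ss$beta, SE = ss$se, P = ss$p, N = ss$n,
                    Z = ss$z)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read an isoform expression TSV (first column isoform id)
#' @param path TSV path; columns after the first are samples.
#' @param unit `"counts"` or `"tpm"`.
#' @return An [ExpressionTable-class].
#' @export
readExpressionTsv <- function(path, unit = c("counts", "tpm")) {
  unit <- match.arg(unit)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  ExpressionTable(m, unit = unit)
}

#' Write an ExpressionTable as TSV
#' @param et an [ExpressionTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTsv <- function(et, path) {
  m <- SummarizedExperiment::assay(et)
  out <- data.frame(isoform_id = rownames(m), m, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a covariate TSV (sample, age, sex, optional PCs)
#' @param path TSV path with at least columns `sample`, `age`, `sex`.
#' @return data.frame with rownames = sample ids.
#' @export
readCovariates <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (!all(c("sample", "age", "sex") %in% colnames(tab)))
    stop("covariate TSV must have columns sample, age, sex")
  rownames(tab) <- tab$sample
  tab
}

#' Write covariates as TSV
#' @param cov data.frame with a `sample` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCovariates <- function(cov, path) {
  data.table::fwrite(cov, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
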