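# Shared fixture builders; all randomness under explicit seeds.

# genotype matrix with given dosage columns (list of numeric vectors)
toy_genotypes <- function(cols, pos = NULL, chrom = "1") {
  d <- do.call(cbind, cols)
  storage.mode(d) <- "double"
  if (is.null(colnames(d)))
    colnames(d) <- sprintf("v%03d", seq_along(cols))
  rownames(d) <- sprintf("s%03d", seq_len(nrow(d)))
  if (is.null(pos)) pos <- 1000L * seq_along(cols)
  al <- rbind(c("A", "G"), c("T", "C"), c("C", "A"), c("G", "T"))
  k <- (seq_along(cols) - 1L) %% 4L + 1L
  GenotypeMatrix(d, data.frame(chrom = chrom, pos = pos,
                               ref = al[k, 1], alt = al[k, 2],
                               stringsAsFactors = FALSE))
}

random_genotypes <- function(n, m, seed = 1, maf = c(0.1, 0.5)) {
  set.seed(seed)
  f <- runif(m, maf[1], maf[2])
  toy_genotypes(lapply(f, function(fj) rbinom(n, 2, fj)))
}

# minimal gene-model table in the readGeneModels() output format
toy_models <- function(gene_id, chrom, start, end, strand, isoforms) {
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand,
             tss = ifelse(strand == "+", start, end),
             n_isoforms = lengths(isoforms),
             isoforms = I(isoforms), stringsAsFactors = FALSE)
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
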