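#' Pipeline configuration
#'
#' One structured configuration drives the whole workflow: either a
#' [simulationConfig()] (synthetic study, the bundled default) or a
#' list of input paths (`vcf`, `counts`, `tpm`, `covariates`,
#' `gene_models`, plus a named list `sumstats` of trait files), the
#' analysis thresholds, stage toggles, one root seed and an output
#' directory.
#'
#' @param simulation a [simulationConfig()], or `NULL` when `inputs`
#'   are given.
#' @param inputs named list of file paths (ignored when `simulation`
#'   is non-NULL).
#' @param stages character subset of
#'   `c("scan", "filter", "enrich", "mr")`.
#' @param seed root seed; defaults to the simulation's seed.
#' @param outdir output directory, or `NULL` to skip writing.
#' @param maf MAF filter threshold (in \[0, 0.5)).
#' @param alpha genome-wide significance threshold (in (0, 1)).
#' @param eqtl_p gene-level eQTL exclusion threshold (in (0, 1)).
#' @param clump_r2 LD-clumping r-squared threshold (in (0, 1)).
#' @param cis_half_width cis window half-width in bp (> 0).
#' @param n_pcs number of genomic PCs used as covariates.
#' @param fdr FDR level for enrichment and MR reporting.
#' @param ld_window_bp LD-score window in bp (1 cM at 1 cM/Mb).
#' @param n_jackknife jackknife blocks for S-LDSC.
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(simulation = NULL, inputs = NULL,
                           stages = c("scan", "filter", "enrich", "mr"),
                           seed = NULL, outdir = NULL, maf = 0.05,
                           alpha = 5e-8, eqtl_p = 0.05,
                           clump_r2 = 0.001, cis_half_width = 1e6,
                           n_pcs = 3, fdr = 0.05, ld_window_bp = 1e6,
                           n_jackknife = 200) {
  if (is.null(simulation) && is.null(inputs))
    stop("either a simulation config or input paths must be given")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(eqtl_p > 0 && eqtl_p < 1)) stop("eqtl_p must lie in (0, 1)")
  if (!(maf >= 0 && maf < 0.5)) stop("maf must lie in [0, 0.5)")
  if (!(clump_r2 > 0 && clump_r2 < 1)) stop("clump_r2 must lie in (0, 1)")
  if (cis_half_width <= 0) stop("cis_half_width must be > 0")
  stages <- match.arg(stages, c("scan", "filter", "enrich", "mr"),
                      several.ok = TRUE)
  if (is.null(seed))
    seed <- if (!is.null(simulation)) simulation$seed else 1L
  structure(list(simulation = simulation, inputs = inputs,
                 stages = stages, seed = as.integer(seed),
                 outdir = outdir,
                 thresholds = list(maf = maf, alpha = alpha,
                                   eqtl_p = eqtl_p,
                                   clump_r2 = clump_r2,
                                   cis_half_width = cis_half_width,
                                   n_pcs = n_pcs, fdr = fdr,
                                   ld_window_bp = ld_window_bp,
                                   n_jackknife = n_jackknife)),
            class = "pipeline_config")
}

.load_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    sc <- config$simulation
    g <- simulateGenotypes(sc)
    sim <- simulateIsoformExpression(g, sc)
    ss <- list()
    if (length(sc$traits)) {
      for (k in seq_along(sc$traits)) {
        tr <- sc$traits[[k]]
        ss[[tr$trait_id]] <- simulateTraitSumstats(
          g, sim$truth, tr, sc, seed = sc$seed + 1000L + k)
      }
    }
    list(genotypes = g, counts = sim$counts, tpm = sim$tpm,
         covariates = sim$covariates, models = sim$gene_models,
         truth = sim$truth, sumstats = ss,
         trait_configs = sc$traits)
  } else {
    paths <- config$inputs
    needed <- c("vcf", "counts", "covariates", "gene_models")
    missing_p <- needed[!vapply(needed, function(k)
      !is.null(paths[[k]]) && file.exists(paths[[k]]), logical(1))]
    if (length(missing_p))
      stop("missing input file(s) for enabled stages: ",
           paste(missing_p, collapse = ", "))
    ss <- list()
    if (!is.null(paths$sumstats))
      ss <- lapply(paths$sumstats, readSumstats)
    counts <- readExpressionTsv(paths$counts, "counts")
    tpm <- if (!is.null(paths$tpm)) readExpressionTsv(paths$tpm, "tpm")
           else NULL
    list(genotypes = readGenotypesVcf(paths$vcf), counts = counts,
         tpm = tpm, covariates = readCovariates(paths$covariates),
         models = readGeneModels(paths$gene_models), truth = NULL,
         sumstats = ss, trait_configs = NULL)
  }
}

#' Run the irQTL pipeline end to end
#'
#' Stages, in workflow order: sample QC and MAF filtering; kinship,
#' genomic PCs, covariate residualization and inverse normal transform;
#' the isoform-ratio cis scan with locus/lead calling and the matched
#' gene-level eQTL scan; the eQTL cross-filter defining the final irQTL
#' set; S-LDSC heritability enrichment of the irQTL gene annotation for
#' each configured trait; and IVW/Egger Mendelian randomization of each
#' significant isoform on each trait. Identical config and seed give
#' identical outputs; a per-stage count funnel is recorded in the
#' manifest.
#'
#' @param config a [pipelineConfig()].
#' @return list with `irqtl` (final calls), `diagnostics`,
#'   `enrichment`, `mr`, `loci`, `truth` (when simulated) and
#'   `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  inp <- .load_inputs(config)
  funnel <- list(n_samples_in = ncol(inp$counts),
                 n_variants_in = ncol(dosages(inp$genotypes)))
  keep_samples <- sampleQc(inp$counts, inp$models)
  g <- inp$genotypes[keep_samples, ]
  g <- variantMafFilter(g, th$maf)
  funnel$n_samples_qc <- length(keep_samples)
  funnel$n_variants_maf <- ncol(dosages(g))
  K <- computeGrm(g)
  pcs <- genomicPcs(K, th$n_pcs)
  covar <- inp$covariates[match(keep_samples, inp$covariates$sample), ]
  X <- cbind(age = covar$age, sex = covar$sex, pcs)
  tpm <- inp$tpm
  # per-sample TPM columns each sum to 1e6, so column subsetting is safe
  tpm_sub <- ExpressionTable(
    SummarizedExperiment::assay(tpm)[, keep_samples, drop = FALSE],
    unit = "tpm",
    isoform_info = SummarizedExperiment::rowData(tpm))
  ratios <- computeIsoformRatios(tpm_sub, inp$models)
  rd <- SummarizedExperiment::rowData(ratios)
  funnel$n_multi_isoform_genes <- length(unique(rd$gene_id))
  funnel$n_ratio_phenotypes <- nrow(ratios)
  phenos <- preparePhenotypes(ratios, X)
  # gene-level phenotype for the eQTL cross-filter: log(gene TPM + 1)
  gene_tpm <- rowsum(ifelse(is.na(SummarizedExperiment::assay(tpm_sub)), 0,
                            SummarizedExperiment::assay(tpm_sub)),
                     tx2gene(inp$models)$gene_id[
                       match(rownames(tpm_sub),
                             tx2gene(inp$models)$isoform_id)])
  gene_phenos <- preparePhenotypes(log(gene_tpm + 1), X)
  res <- list(truth = inp$truth)
  if (!"scan" %in% config$stages) {
    res$manifest <- .pipeline_manifest(config, funnel)
    return(res)
  }
  scan <- mapCisLoci(phenos, g, inp$models,
                     pheno2gene = rd$gene_id[match(rownames(phenos),
                                                   rd$isoform_id)],
                     half_width = th$cis_half_width)
  sig <- significantLociAndFdr(scan$loci, scan$p, th$alpha)
  res$loci <- scan$loci
  res$diagnostics <- sig$diagnostics
  funnel$n_loci <- nrow(scan$loci)
  funnel$n_significant_loci <- nrow(sig$loci)
  if ("filter" %in% config$stages) {
    eqtl_records <- do.call(rbind, lapply(
      unique(scan$loci$gene_id), function(gid) {
        leads <- unique(scan$loci$lead_variant[scan$loci$gene_id == gid])
        rec <- fastOlsScan(gene_phenos[gid, ],
                           g[, match(leads, variantIDs(g))])
        data.frame(gene_id = gid, variant_id = rec$variant_id,
                   p = rec$p, stringsAsFactors = FALSE)
      }))
    calls <- irqtlVsEqtlFilter(scan$loci, eqtl_records, th$alpha,
                               th$eqtl_p)
    res$irqtl <- calls
    funnel$n_irqtl_final <- sum(calls$retained)
  }
  if ("enrich" %in% config$stages && length(inp$sumstats)) {
    retained_genes <- unique(res$irqtl$gene_id[res$irqtl$retained])
    v <- variantInfo(g)
    in_genes <- rep(FALSE, nrow(v))
    for (gid in retained_genes) {
      gm <- inp$models[inp$models$gene_id == gid, ]
      in_genes <- in_genes | (v$chrom == gm$chrom & v$pos >= gm$start &
                                v$pos <= gm$end)
    }
    ann <- cbind(base = 1, irQTL_genes = as.numeric(in_genes))
    enr <- NULL
    if (any(in_genes) && !all(in_genes)) {
      ld <- computeLdScores(g, ann, th$ld_window_bp)
      ref <- data.frame(variant_id = rownames(v),
                        effect_allele = v$alt, other_allele = v$ref,
                        stringsAsFactors = FALSE)
      enr <- do.call(rbind, lapply(names(inp$sumstats), function(nm) {
        ssh <- mungeHarmonize(inp$sumstats[[nm]], ref)
        fit <- sldscFit(ssh, ld, ann,
                        n_blocks = min(th$n_jackknife,
                                       floor(nrow(ann) / 2)))
        tab <- enrichmentTable(fit)
        row <- tab[tab$annotation == "irQTL_genes", ]
        data.frame(tissue = "synthetic", trait = nm,
                   enrichment = row$enrichment,
                   se = row$jackknife_se, stringsAsFactors = FALSE)
      }))
      enr <- enrichmentTestAndFdr(enr)
    }
    res$enrichment <- enr
  }
  if ("mr" %in% config$stages && length(inp$sumstats) &&
      !is.null(res$irqtl)) {
    v <- variantInfo(g)
    mr_rows <- list()
    retained <- res$irqtl[res$irqtl$retained, , drop = FALSE]
    for (ph in unique(retained$phenotype_id)) {
      row <- retained[retained$phenotype_id == ph, ][1, ]
      idx <- which(v$chrom == row$chrom & v$pos >= row$window_start &
                     v$pos <= row$window_end)
      rec <- fastOlsScan(phenos[ph, ], g[, idx])
      sig_rec <- rec[!is.na(rec$p) & rec$p < th$alpha, , drop = FALSE]
      if (nrow(sig_rec) == 0) next
      inst0 <- ldClump(sig_rec, g, th$clump_r2)
      vi <- match(inst0$variant_id, rownames(v))
      exposure <- data.frame(variant_id = inst0$variant_id,
                             effect_allele = v$alt[vi],
                             other_allele = v$ref[vi],
                             beta = inst0$beta, se = inst0$se,
                             p = inst0$p, maf = inst0$maf,
                             stringsAsFactors = FALSE)
      for (nm in names(inp$sumstats)) {
        inst <- harmonizeInstruments(exposure, inp$sumstats[[nm]])
        ivw <- mrIvw(inst)
        ivw$exposure <- ph; ivw$outcome <- nm
        mr_rows[[paste(ph, nm, "ivw")]] <- ivw
        if (nrow(inst) >= 3) {
          eg <- mrEgger(inst)
          eg$exposure <- ph; eg$outcome <- nm
          mr_rows[[paste(ph, nm, "egger")]] <-
            eg[, c("method", "estimate", "se", "p", "n_instruments",
                   "exposure", "outcome")]
        }
      }
    }
    if (length(mr_rows)) {
      mr_tab <- do.call(rbind, mr_rows)
      rownames(mr_tab) <- NULL
      ivw_only <- mr_tab[mr_tab$method == "IVW", , drop = FALSE]
      ivw_only <- mrFdr(ivw_only, th$fdr)
      res$mr <- ivw_only
      res$mr_all <- mr_tab
      funnel$n_mr_pairs <- nrow(ivw_only)
      funnel$n_mr_significant <- sum(ivw_only$significant)
    }
  }
  res$manifest <- .pipeline_manifest(config, funnel)
  if (!is.null(config$outdir)) .write_pipeline(res, config)
  res
}

.pipeline_manifest <- function(config, funnel) {
  list(package_version = as.character(utils::packageVersion("irQTL")),
       seed = config$seed, thresholds = config$thresholds,
       stages = config$stages, counts = funnel,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

.write_pipeline <- function(res, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x))
      data.table::fwrite(x, file.path(config$outdir, name), sep = "\t",
                         quote = FALSE, na = "NA")
  }
  wr(res$loci, "loci.tsv")
  wr(res$irqtl, "irqtl_calls.tsv")
  wr(res$enrichment, "enrichment.tsv")
  wr(res$mr, "mr_results.tsv")
  if (!is.null(res$diagnostics))
    writeLines(yaml::as.yaml(res$diagnostics),
               file.path(config$outdir, "diagnostics.yaml"))
  manifest <- res$manifest
  manifest$timestamp <- NULL  # byte-identical reruns
  writeLines(yaml::as.yaml(manifest),
             file.path(config$outdir, "manifest.yaml"))
  invisible(NULL)
}
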