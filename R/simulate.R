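#' Per-gene configuration for the isoform-expression simulator
#'
#' Each gene has `n_isoforms` isoforms whose usage proportions follow a
#' softmax (multinomial-logit) model: for sample i,
#' `pi_k = softmax_k(a_k + b_k * x_i + xi_ki)` with `x_i` the dosage at
#' the gene's causal variant and `xi ~ N(0, sigma_pi^2)`. Total gene
#' expression is log-normal with covariate effects and, by default, no
#' genotype term — opposite-sign `b` therefore shifts isoform ratios
#' while total expression stays genetically flat (the cancellation
#' mechanism). A nonzero `eqtl_beta` adds a genotype effect on the log
#' total, giving positive-control eQTL genes.
#'
#' @param gene_id gene identifier.
#' @param n_isoforms number of isoforms K (>= 1).
#' @param causal_variant index (or id) of the causal variant in the
#'   genotype matrix, or `NA` for a null gene.
#' @param b per-isoform logit effects of the causal dosage (length K;
#'   default `c(+0.8, -0.8)` for K = 2, balanced around zero otherwise).
#' @param a baseline logits (length K, default 0).
#' @param sigma_pi SD of per-isoform logit noise (default 0.5).
#' @param mu mean log total expression (default `log(100)`).
#' @param sigma_g SD of log total expression noise (default 0.5).
#' @param eqtl_beta genotype effect on log total expression (default 0).
#' @return list of class `gene_config`.
#' @export
geneConfig <- function(gene_id, n_isoforms = 2, causal_variant = NA,
                       b = NULL, a = NULL, sigma_pi = 0.5,
                       mu = log(100), sigma_g = 0.5, eqtl_beta = 0) {
  K <- as.integer(n_isoforms)
  if (K < 1) stop("n_isoforms must be >= 1")
  if (is.null(b)) {
    b <- if (K == 1) 0 else 0.8 * rep_len(c(1, -1), K) *
      rep(1, K) / ifelse(K > 2, (K - 1) / 2, 1)
    if (K > 2) b <- 0.8 * scale(seq_len(K), scale = FALSE)[, 1] /
      max(abs(scale(seq_len(K), scale = FALSE)[, 1]))
  }
  if (is.null(a)) a <- rep(0, K)
  if (K == 1 && any(b != 0))
    stop("a single-isoform gene cannot carry isoform-ratio effects (b != 0)")
  if (length(b) != K || length(a) != K)
    stop("a and b must have length n_isoforms")
  if (sigma_pi < 0 || sigma_g < 0) stop("sigma values must be >= 0")
  structure(list(gene_id = gene_id, n_isoforms = K,
                 causal_variant = causal_variant, b = b, a = a,
                 sigma_pi = sigma_pi, mu = mu, sigma_g = sigma_g,
                 eqtl_beta = eqtl_beta),
            class = "gene_config")
}

#' Per-trait configuration for the GWAS summary-statistics simulator
#'
#' @param trait_id trait identifier.
#' @param causal data.frame with columns `gene_id`, `isoform` (index of
#'   the isoform within the gene) and `gamma` (causal effect of the
#'   genetic isoform-ratio predictor on the trait), or `NULL`.
#' @param h2_bg polygenic background heritability in \[0, 1).
#' @param annotation logical vector over variants (or indices) marking
#'   the annotation whose per-SNP heritability is enriched; `NULL` for
#'   none.
#' @param enrichment target heritability enrichment score of the
#'   annotation: the proportion of h2 in the annotation divided by the
#'   proportion of SNPs (the S-LDSC estimand). Internally converted to a
#'   per-SNP variance fold `E(1-p)/(1-E p)` for annotation fraction `p`.
#' @param n_gwas GWAS cohort size (>= 10).
#' @return list of class `trait_config`.
#' @export
traitConfig <- function(trait_id, causal = NULL, h2_bg = 0.3,
                        annotation = NULL, enrichment = 1,
                        n_gwas = 10000) {
  if (n_gwas < 10) stop("n_gwas must be >= 10")
  if (h2_bg < 0 || h2_bg >= 1) stop("h2_bg must be in [0, 1)")
  if (enrichment <= 0) stop("enrichment must be > 0")
  structure(list(trait_id = trait_id, causal = causal, h2_bg = h2_bg,
                 annotation = annotation, enrichment = enrichment,
                 n_gwas = as.integer(n_gwas)),
            class = "trait_config")
}

#' Simulation configuration
#'
#' Defines the synthetic study: an LD-structured genotype panel on one
#' synthetic chromosome, multi-isoform genes with genetically regulated
#' isoform proportions, covariates (age uniform on 21-70 years, sex
#' Bernoulli(1/2), an ancestry axis), and outcome traits. Haplotypes
#' follow a first-order copying process: the allele at a variant copies
#' the previous variant's allele with probability `exp(-d / ld_decay_bp)`
#' for inter-variant distance `d`, otherwise it is drawn fresh at the
#' variant's base frequency.
#'
#' @param seed integer root seed; all stages derive their streams from it.
#' @param n_samples expression-panel size (default 500).
#' @param n_variants number of variants (default 1000).
#' @param maf_range base allele-frequency range, subset of (0, 0.5].
#' @param ld_decay_bp LD decay scale in bp (default 25000).
#' @param spacing_bp inter-variant spacing in bp (default 2000); ignored
#'   when `positions` is given.
#' @param positions optional explicit 1-based positions (non-decreasing).
#' @param chrom chromosome name (default `"1"`).
#' @param genes list of [geneConfig()] entries; default 10 two-isoform
#'   genes with opposite-sign effects `c(+0.8, -0.8)` at evenly spaced
#'   causal variants.
#' @param covariate_effects named list `age`, `sex`, `ancestry` of
#'   effects on log total expression.
#' @param traits list of [traitConfig()] entries (may be empty).
#' @return list of class `simulation_config`.
#' @export
simulationConfig <- function(seed = 1L, n_samples = 500L,
                             n_variants = 1000L,
                             maf_range = c(0.05, 0.5),
                             ld_decay_bp = 25000, spacing_bp = 2000,
                             positions = NULL, chrom = "1",
                             genes = NULL,
                             covariate_effects = list(age = 0.005,
                                                      sex = 0.1,
                                                      ancestry = 0.2),
                             traits = list()) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be a subset of (0, 0.5]")
  if (is.null(positions)) {
    # exponential gaps: clustered sites give heterogeneous LD scores,
    # which keeps the LDSC intercept and base LD score identifiable
    set.seed(seed)
    gaps <- pmax(1, round(stats::rexp(n_variants, 1 / spacing_bp)))
    positions <- cumsum(gaps)
  } else {
    if (length(positions) != n_variants)
      stop("positions must have length n_variants")
    if (is.unsorted(positions)) stop("positions must be non-decreasing")
  }
  if (is.null(genes)) {
    idx <- unique(round(seq(n_variants / 20, n_variants,
                            length.out = 10)))
    genes <- lapply(seq_along(idx), function(i)
      geneConfig(sprintf("gene%02d", i), causal_variant = idx[i]))
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, ld_decay_bp = ld_decay_bp,
                 positions = as.integer(positions), chrom = chrom,
                 genes = genes, covariate_effects = covariate_effects,
                 traits = traits),
            class = "simulation_config")
}

# haplotype-copying genotypes: 2n haplotypes, Markov copy along the chromosome
.simulate_dosages <- function(n, freqs, positions, ld_decay_bp) {
  m <- length(freqs)
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  H[, 1] <- stats::rbinom(2L * n, 1L, freqs[1])
  if (m > 1) {
    d <- diff(positions)
    rho <- exp(-d / ld_decay_bp)
    for (j in 2:m) {
      copy <- stats::runif(2L * n) < rho[j - 1]
      fresh <- stats::rbinom(2L * n, 1L, freqs[j])
      H[, j] <- ifelse(copy, H[, j - 1], fresh)
    }
  }
  out <- H[seq(1, 2L * n, by = 2), , drop = FALSE] +
    H[seq(2, 2L * n, by = 2), , drop = FALSE]
  storage.mode(out) <- "double"   # dosages are stored as doubles throughout
  out
}

.variant_alleles <- function(m) {
  # non-strand-ambiguous ref/alt pairs, cycled deterministically
  pairs <- rbind(c("A", "G"), c("T", "C"), c("C", "A"), c("G", "T"))
  pairs[(seq_len(m) - 1L) %% 4L + 1L, , drop = FALSE]
}

#' Simulate an LD-structured genotype panel
#'
#' Draws `n_samples` diploid genotypes at `n_variants` positions on one
#' synthetic chromosome under the haplotype-copying LD model of
#' [simulationConfig()]. Base allele frequencies are uniform on
#' `maf_range`; because copying mixes neighbouring frequencies, the
#' empirical MAF of a variant matches its base frequency exactly only in
#' the weak-LD limit. The base frequency is stored in the variant
#' metadata (`base_freq`) so that independent cohorts (e.g. a GWAS
#' cohort for trait simulation) can be drawn from the same population.
#'
#' @param config a [simulationConfig()].
#' @param seed optional override of `config$seed`.
#' @return A [GenotypeMatrix-class] with extra variant columns
#'   `base_freq`.
#' @export
simulateGenotypes <- function(config, seed = config$seed) {
  set.seed(seed)
  m <- config$n_variants
  n <- config$n_samples
  freqs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dos <- .simulate_dosages(n, freqs, config$positions, config$ld_decay_bp)
  ids <- sprintf("v%06d", seq_len(m))
  dimnames(dos) <- list(sprintf("s%04d", seq_len(n)), ids)
  al <- .variant_alleles(m)
  GenotypeMatrix(dos, data.frame(
    chrom = config$chrom, pos = config$positions,
    ref = al[, 1], alt = al[, 2], base_freq = freqs,
    stringsAsFactors = FALSE))
}

.softmax_rows <- function(eta) {
  e <- exp(eta - apply(eta, 1, max))
  e / rowSums(e)
}

#' Simulate isoform expression, covariates and the truth table
#'
#' For each configured gene, isoform proportions follow the softmax
#' model of [geneConfig()] and total gene expression is log-normal with
#' age, sex and ancestry effects but (by default) no genotype term, so
#' isoform TPMs of a gene always sum to the gene's total within each
#' sample while the genetic signal lives only in the proportions.
#' Isoform TPMs across all genes are rescaled per sample to sum to 1e6.
#'
#' @param genotypes a [GenotypeMatrix-class] from [simulateGenotypes()].
#' @param config the same [simulationConfig()].
#' @param seed optional override (default `config$seed + 1`).
#' @return list with elements `tpm` ([ExpressionTable-class], unit
#'   `"tpm"`), `counts` (unit `"counts"`, unnormalized rounded
#'   expression), `covariates` (data.frame sample/age/sex/ancestry),
#'   `gene_models` (as [readGeneModels()] returns) and `truth` (list
#'   with per-gene causal variant and per-isoform logit effects).
#' @export
simulateIsoformExpression <- function(genotypes, config,
                                      seed = config$seed + 1L) {
  set.seed(seed)
  n <- nrow(dosages(genotypes))
  v <- variantInfo(genotypes)
  for (gc in config$genes) {
    cv <- gc$causal_variant
    if (!is.na(cv) && (cv < 1 || cv > ncol(dosages(genotypes))))
      stop("causal variant of gene ", gc$gene_id,
           " not present in the genotype matrix")
  }
  age <- round(stats::runif(n, 21, 70))
  sex <- stats::rbinom(n, 1, 0.5)
  Z <- scale(dosages(genotypes))
  Z[is.na(Z)] <- 0
  ancestry <- as.vector(scale(rowMeans(Z)))
  ce <- config$covariate_effects
  cov_lin <- ce$age * (age - mean(age)) + ce$sex * sex +
    ce$ancestry * ancestry
  iso_rows <- list(); gene_rows <- list(); truth_rows <- list()
  expr <- list()
  for (gc in config$genes) {
    K <- gc$n_isoforms
    x <- if (is.na(gc$causal_variant)) rep(0, n)
         else dosages(genotypes)[, gc$causal_variant]
    x_imp <- ifelse(is.na(x), mean(x, na.rm = TRUE), x)
    eta <- matrix(gc$a, n, K, byrow = TRUE) +
      outer(x_imp, gc$b) +
      matrix(stats::rnorm(n * K, sd = gc$sigma_pi), n, K)
    pi_ki <- if (K == 1) matrix(1, n, 1) else .softmax_rows(eta)
    log_tot <- gc$mu + cov_lin + gc$eqtl_beta * x_imp +
      stats::rnorm(n, sd = gc$sigma_g)
    tot <- exp(log_tot)
    iso <- t(pi_ki * tot)           # K x n
    iso_ids <- paste0(gc$gene_id, ".", seq_len(K))
    rownames(iso) <- iso_ids
    expr[[gc$gene_id]] <- iso
    cv_id <- if (is.na(gc$causal_variant)) NA_character_
             else colnames(dosages(genotypes))[gc$causal_variant]
    cv_pos <- if (is.na(gc$causal_variant)) NA_integer_
              else v$pos[gc$causal_variant]
    gene_rows[[gc$gene_id]] <- data.frame(
      gene_id = gc$gene_id, chrom = config$chrom,
      start = if (is.na(cv_pos)) 1L else max(1L, cv_pos - 5000L),
      end = if (is.na(cv_pos)) 10000L else cv_pos + 5000L,
      strand = "+", stringsAsFactors = FALSE)
    truth_rows[[gc$gene_id]] <- data.frame(
      gene_id = gc$gene_id, isoform_id = iso_ids,
      causal_variant = cv_id, b = gc$b,
      eqtl_beta = gc$eqtl_beta, stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, expr)
  colnames(mat) <- sampleIDs(genotypes)
  tpm <- sweep(mat, 2, colSums(mat), "/") * 1e6
  gdf <- do.call(rbind, gene_rows)
  gdf$tss <- gdf$start
  gdf$n_isoforms <- vapply(config$genes, `[[`, integer(1), "n_isoforms")
  gdf$isoforms <- I(lapply(config$genes, function(gc)
    paste0(gc$gene_id, ".", seq_len(gc$n_isoforms))))
  rownames(gdf) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  t2g <- data.frame(isoform_id = rownames(mat),
                    gene_id = rep(gdf$gene_id, gdf$n_isoforms))
  list(
    tpm = ExpressionTable(tpm, unit = "tpm", isoform_info = t2g),
    counts = ExpressionTable(round(mat), unit = "counts",
                             isoform_info = t2g),
    covariates = data.frame(sample = sampleIDs(genotypes), age = age,
                            sex = sex, ancestry = ancestry,
                            stringsAsFactors = FALSE),
    gene_models = gdf,
    truth = truth)
}

#' Simulate GWAS summary statistics for an outcome trait
#'
#' Draws an independent GWAS cohort of `trait$n_gwas` samples from the
#' same population as `genotypes` (same base frequencies, positions and
#' LD model — the two-sample MR setting), builds the trait as
#' `y = sum_c gamma_c * (b_k * x_causal) + sum_j beta_j * ztilde_j + e`
#' where the polygenic `beta_j` have per-SNP variance proportional to
#' the annotation fold implied by the configured enrichment score, and
#' returns per-variant marginal OLS summary statistics. Large cohorts
#' are processed in sample blocks via sufficient statistics, so memory
#' stays flat in `n_gwas`.
#'
#' @param genotypes the [GenotypeMatrix-class] panel (supplies variant
#'   metadata and base frequencies).
#' @param truth truth table from [simulateIsoformExpression()] (only
#'   needed when the trait has causal isoforms; may be `NULL`).
#' @param trait a [traitConfig()].
#' @param config the [simulationConfig()].
#' @param seed optional override (default derives from `config$seed`).
#' @return sumstats data.frame (columns as [readSumstats()]), with the
#'   realized per-SNP effects in `attr(,"beta_true")`.
#' @export
simulateTraitSumstats <- function(genotypes, truth, trait, config,
                                  seed = config$seed + 1000L) {
  if (trait$n_gwas < 10) stop("n_gwas must be >= 10")
  set.seed(seed)
  v <- variantInfo(genotypes)
  m <- nrow(v)
  freqs <- v$base_freq
  if (is.null(freqs)) freqs <- pmax(v$maf, 1e-3)
  # per-SNP background effects on the standardized-genotype scale
  w <- rep(1, m)
  if (!is.null(trait$annotation)) {
    ann <- rep(FALSE, m)
    ann[trait$annotation] <- TRUE
    p_ann <- mean(ann)
    E <- trait$enrichment
    if (E * p_ann >= 1)
      stop("enrichment target too large for annotation fraction")
    fold <- E * (1 - p_ann) / (1 - E * p_ann)
    w[ann] <- fold
  }
  beta_std <- if (trait$h2_bg > 0)
    stats::rnorm(m, sd = sqrt(trait$h2_bg * w / sum(w))) else rep(0, m)
  sd_x <- sqrt(2 * freqs * (1 - freqs))
  beta_dose <- beta_std / sd_x
  # causal isoform-ratio effects: gamma * b_k at the gene's causal variant
  causal_idx <- integer(0); causal_eff <- numeric(0)
  if (!is.null(trait$causal) && nrow(trait$causal) > 0) {
    if (is.null(truth)) stop("trait has causal isoforms but truth is NULL")
    for (r in seq_len(nrow(trait$causal))) {
      gi <- trait$causal$gene_id[r]
      iso <- trait$causal$isoform[r]
      rows <- truth[truth$gene_id == gi, , drop = FALSE]
      if (nrow(rows) == 0) stop("causal gene not in truth table: ", gi)
      cv <- rows$causal_variant[1]
      if (is.na(cv)) stop("causal gene has no causal variant: ", gi)
      j <- match(cv, rownames(v))
      causal_idx <- c(causal_idx, j)
      causal_eff <- c(causal_eff,
                      trait$causal$gamma[r] * rows$b[iso])
    }
  }
  n <- trait$n_gwas
  sigma_e <- sqrt(max(1e-8, 1 - trait$h2_bg))
  Sx <- Sxx <- Sxy <- numeric(m)
  Sy <- Syy <- 0
  block <- max(1L, min(n, as.integer(2e7 / m)))
  done <- 0L
  while (done < n) {
    nb <- min(block, n - done)
    X <- .simulate_dosages(nb, freqs, config$positions, config$ld_decay_bp)
    g_bg <- as.vector(sweep(X, 2, 2 * freqs) %*% beta_std_scaled(beta_std, sd_x))
    g_causal <- if (length(causal_idx))
      as.vector(X[, causal_idx, drop = FALSE] %*% causal_eff) else 0
    y <- g_bg + g_causal + stats::rnorm(nb, sd = sigma_e)
    Sx <- Sx + colSums(X)
    Sxx <- Sxx + colSums(X^2)
    Sxy <- Sxy + as.vector(crossprod(X, y))
    Sy <- Sy + sum(y)
    Syy <- Syy + sum(y^2)
    done <- done + nb
  }
  Sxx_c <- Sxx - Sx^2 / n
  Sxy_c <- Sxy - Sx * Sy / n
  Syy_c <- Syy - Sy^2 / n
  ok <- Sxx_c > 0
  beta <- ifelse(ok, Sxy_c / Sxx_c, NA_real_)
  rss <- pmax(Syy_c - beta^2 * Sxx_c, 0)
  se <- ifelse(ok, sqrt(rss / ((n - 2) * Sxx_c)), NA_real_)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(
    variant_id = rownames(v), chrom = v$chrom, pos = v$pos,
    effect_allele = v$alt, other_allele = v$ref,
    beta = beta, se = se, p = p, n = n, z = tstat,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  attr(out, "beta_true") <- beta_dose
  attr(out, "trait_id") <- trait$trait_id
  out
}

# dosage-scale background effects from standardized-scale draws
beta_std_scaled <- function(beta_std, sd_x) beta_std / sd_x

#' Draw an independent genotype cohort from the simulated population
#'
#' Generates a fresh cohort (e.g. a GWAS cohort for many traits) at the
#' same variants, base frequencies and LD model as an existing
#' simulated panel. Useful when several traits share one outcome
#' cohort: draw the cohort once and build trait phenotypes on it.
#'
#' @param genotypes a [GenotypeMatrix-class] from [simulateGenotypes()]
#'   (its `base_freq` variant column defines the population).
#' @param config the [simulationConfig()] (positions, LD decay).
#' @param n cohort size.
#' @param seed integer seed.
#' @return A [GenotypeMatrix-class] of `n` new samples.
#' @export
simulateGwasCohort <- function(genotypes, config, n, seed) {
  set.seed(seed)
  v <- variantInfo(genotypes)
  freqs <- v$base_freq
  if (is.null(freqs)) stop("genotypes lack base_freq metadata")
  dos <- .simulate_dosages(n, freqs, config$positions,
                           config$ld_decay_bp)
  dimnames(dos) <- list(sprintf("g%05d", seq_len(n)),
                        rownames(v))
  GenotypeMatrix(dos, data.frame(chrom = v$chrom, pos = v$pos,
                                 ref = v$ref, alt = v$alt,
                                 base_freq = freqs,
                                 stringsAsFactors = FALSE))
}

#' Simulate a two-sample Mendelian-randomization study
#'
#' Generates `n_instruments` independent biallelic variants, an exposure
#' built from their additive effects (`b_j`, equal magnitude with
#' alternating sign by default), and an outcome
#' `y = gamma * (sum_j b_j x_j) + sum_j alpha_j x_j + e` in an
#' independent cohort, where `alpha_j` is directional pleiotropy
#' (default 0). Marginal OLS summary statistics from both cohorts are
#' returned as a harmonized instrument table, the input expected by
#' [mrIvw()] and [mrEgger()].
#'
#' @param n_instruments number of independent instruments.
#' @param gamma causal effect of the exposure on the outcome.
#' @param n_exp exposure-cohort size (default 20000).
#' @param n_out outcome-cohort size (default 20000).
#' @param b_abs absolute per-instrument exposure effect (default 0.2).
#' @param pleiotropy common directional pleiotropic effect alpha
#'   (default 0).
#' @param seed integer seed.
#' @return data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `b_exp`, `se_exp`, `b_out`, `se_out`, `p_exp`;
#'   `attr(,"gamma")` carries the simulated truth.
#' @export
simulateMrStudy <- function(n_instruments = 10, gamma = 0.3,
                            n_exp = 20000, n_out = 20000, b_abs = 0.2,
                            pleiotropy = 0, seed = 1L) {
  set.seed(seed)
  m <- n_instruments
  f <- stats::runif(m, 0.1, 0.5)
  b <- b_abs * rep_len(c(1, -1), m)
  alpha <- rep(pleiotropy, m)
  marginal <- function(n, coefs, extra_var) {
    X <- matrix(stats::rbinom(n * m, 2, rep(f, each = n)), n, m)
    g <- as.vector(X %*% coefs)
    y <- g + stats::rnorm(n, sd = sqrt(max(1e-8, extra_var)))
    xc <- sweep(X, 2, colMeans(X))
    Sxx <- colSums(xc^2)
    bhat <- as.vector(crossprod(xc, y - mean(y))) / Sxx
    rss <- sum((y - mean(y))^2) - bhat^2 * Sxx
    se <- sqrt(pmax(rss, 0) / ((n - 2) * Sxx))
    list(b = bhat, se = se)
  }
  var_g <- sum(b^2 * 2 * f * (1 - f))
  exp_st <- marginal(n_exp, b, 1 - min(var_g, 0.9))
  out_coefs <- gamma * b + alpha
  var_go <- sum(out_coefs^2 * 2 * f * (1 - f))
  out_st <- marginal(n_out, out_coefs, 1 - min(var_go, 0.9))
  al <- .variant_alleles(m)
  res <- data.frame(
    variant_id = sprintf("iv%03d", seq_len(m)),
    effect_allele = al[, 2], other_allele = al[, 1],
    b_exp = exp_st$b, se_exp = exp_st$se,
    b_out = out_st$b, se_out = out_st$se,
    p_exp = 2 * stats::pnorm(-abs(exp_st$b / exp_st$se)),
    stringsAsFactors = FALSE)
  attr(res, "gamma") <- gamma
  attr(res, "b_true") <- b
  res
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits the VCF, expression TSVs (counts and TPM), covariate TSV,
#' gene-model TSV, truth-table TSV and one sumstats TSV per trait, all
#' readable by the `read*` functions of this package.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param sim result of [simulateIsoformExpression()].
#' @param dir output directory (created if needed).
#' @param sumstats optional named list of sumstats data.frames.
#' @return named character vector of written paths, invisibly.
#' @export
writeSimulation <- function(genotypes, sim, dir, sumstats = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    counts = file.path(dir, "isoform_counts.tsv"),
    tpm = file.path(dir, "isoform_tpm.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    gene_models = file.path(dir, "gene_models.tsv"),
    truth = file.path(dir, "truth.tsv"))
  writeGenotypesVcf(genotypes, paths["vcf"])
  writeExpressionTsv(sim$counts, paths["counts"])
  writeExpressionTsv(sim$tpm, paths["tpm"])
  writeCovariates(sim$covariates, paths["covariates"])
  gm <- sim$gene_models
  tx <- tx2gene(gm)
  tab <- merge(tx, gm[, c("gene_id", "chrom", "start", "end", "strand")],
               by = "gene_id", sort = FALSE)
  data.table::fwrite(
    tab[, c("gene_id", "chrom", "start", "end", "strand", "isoform_id")],
    paths["gene_models"], sep = "\t", quote = FALSE,
    col.names = TRUE)
  # TSV reader expects the transcript column named transcript_id
  hdr <- readLines(paths["gene_models"])
  hdr[1] <- sub("isoform_id", "transcript_id", hdr[1])
  writeLines(hdr, paths["gene_models"])
  data.table::fwrite(sim$truth, paths["truth"], sep = "\t", quote = FALSE)
  if (!is.null(sumstats)) {
    for (nm in names(sumstats)) {
      p <- file.path(dir, paste0("sumstats_", nm, ".tsv"))
      writeSumstats(sumstats[[nm]], p)
      paths[paste0("sumstats_", nm)] <- p
    }
  }
  invisible(paths)
}
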