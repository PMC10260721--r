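test_that("genotype simulation is deterministic and hits the target MAF without LD", {
  sc <- simulationConfig(seed = 11, n_samples = 10000, n_variants = 5,
                         maf_range = c(0.3, 0.3), ld_decay_bp = 1,
                         spacing_bp = 1e6, genes = list())
  g1 <- simulateGenotypes(sc)
  g2 <- simulateGenotypes(sc)
  expect_identical(dosages(g1), dosages(g2))
  expect_true(all(abs(mafs(g1) - 0.3) < 0.01))
})

test_that("zero-distance variants are near-perfect LD under the copying model", {
  sc <- simulationConfig(seed = 5, n_samples = 2000, n_variants = 2,
                         positions = c(500L, 500L), ld_decay_bp = 10000,
                         genes = list())
  g <- simulateGenotypes(sc)
  d <- dosages(g)
  expect_gt(cor(d[, 1], d[, 2]), 0.95)
})

test_that("isoform proportions are a softmax: per-gene TPMs sum to the gene total", {
  sc <- simulationConfig(seed = 2, n_samples = 100, n_variants = 50,
                         genes = list(geneConfig("gA", 3, causal_variant = 10,
                                                 b = c(0.5, 0, -0.5))))
  g <- simulateGenotypes(sc)
  sim <- simulateIsoformExpression(g, sc)
  tpm <- SummarizedExperiment::assay(sim$tpm)
  # all isoforms belong to one gene here, so columns sum to 1e6 exactly
  expect_equal(unname(colSums(tpm)), rep(1e6, 100), tolerance = 1e-9)
  r <- computeIsoformRatios(sim$tpm, sim$gene_models)
  sums <- colSums(SummarizedExperiment::assay(r))
  expect_equal(unname(sums), rep(1, 100), tolerance = 1e-12)
})

test_that("null genes show no dosage association; cancellation genes hide from the gene level", {
  # ancestry effect off: with few variants the ancestry proxy is itself
  # correlated with single dosages, which would leak genotype into totals
  sc <- simulationConfig(seed = 9, n_samples = 500, n_variants = 60,
    covariate_effects = list(age = 0.005, sex = 0.1, ancestry = 0),
    genes = list(geneConfig("gNull", 2, causal_variant = 30, b = c(0, 0)),
                 geneConfig("gCanc", 2, causal_variant = 45,
                            b = c(0.8, -0.8))))
  g <- simulateGenotypes(sc)
  sim <- simulateIsoformExpression(g, sc)
  r <- SummarizedExperiment::assay(computeIsoformRatios(sim$tpm,
                                                        sim$gene_models))
  x_null <- dosages(g)[, 30]
  t_null <- summary(lm(r["gNull.1", ] ~ x_null))$coefficients[2, 3]
  expect_lt(abs(t_null), 4)
  x <- dosages(g)[, 45]
  tot <- colSums(SummarizedExperiment::assay(sim$counts)[
    c("gCanc.1", "gCanc.2"), ])
  expect_lt(abs(cor(tot, x)), 3 / sqrt(500))
  slope <- coef(lm(r["gCanc.1", ] ~ x))[2]
  expect_gt(slope, 0)
})

test_that("null GWAS sumstats are calibrated: mean chi-square within 1 +/- 0.05", {
  # effectively independent variants: the check concerns the marginal
  # calibration of the statistics, and LD only shrinks the effective
  # number of independent chi-squares behind the mean
  sc <- simulationConfig(seed = 21, n_samples = 50, n_variants = 5000,
                         ld_decay_bp = 10, spacing_bp = 5000,
                         genes = list(),
                         traits = list(traitConfig("null", h2_bg = 0,
                                                   n_gwas = 1000)))
  g <- simulateGenotypes(sc)
  ss <- simulateTraitSumstats(g, NULL, sc$traits[[1]], sc)
  expect_equal(mean(ss$z^2), 1, tolerance = 0.05)
})

test_that("single-causal trait obeys the Wald-ratio identity at the causal variant", {
  sc <- simulationConfig(seed = 31, n_samples = 200, n_variants = 80,
    genes = list(geneConfig("gA", 2, causal_variant = 40,
                            b = c(0.8, -0.8))),
    traits = list(traitConfig("t1",
      causal = data.frame(gene_id = "gA", isoform = 1, gamma = 0.3),
      h2_bg = 0, n_gwas = 50000)))
  g <- simulateGenotypes(sc)
  sim <- simulateIsoformExpression(g, sc)
  ss <- simulateTraitSumstats(g, sim$truth, sc$traits[[1]], sc)
  # marginal outcome effect at the causal variant = gamma * b_1
  j <- which(ss$variant_id == "v000040")
  expect_lt(abs(ss$beta[j] - 0.3 * 0.8), 2 * ss$se[j])
})

test_that("annotation enrichment raises mean chi-square inside the annotation", {
  m <- 2000
  ann_idx <- 1:200
  sc <- simulationConfig(seed = 41, n_samples = 50, n_variants = m,
    genes = list(),
    traits = list(traitConfig("enr", h2_bg = 0.5, annotation = ann_idx,
                              enrichment = 5, n_gwas = 20000)))
  g <- simulateGenotypes(sc)
  ss <- simulateTraitSumstats(g, NULL, sc$traits[[1]], sc)
  inside <- mean(ss$z[ann_idx]^2)
  outside <- mean(ss$z[-ann_idx]^2)
  expect_gt(inside, outside)
})

test_that("simulation writers emit files the readers reproduce", {
  sc <- simulationConfig(seed = 8, n_samples = 40, n_variants = 30,
    genes = list(geneConfig("gA", 2, causal_variant = 15)),
    traits = list(traitConfig("t1", h2_bg = 0.1, n_gwas = 500)))
  g <- simulateGenotypes(sc)
  sim <- simulateIsoformExpression(g, sc)
  ss <- simulateTraitSumstats(g, sim$truth, sc$traits[[1]], sc)
  dir <- tempfile()
  paths <- writeSimulation(g, sim, dir, sumstats = list(t1 = ss))
  g2 <- readGenotypesVcf(paths[["vcf"]])
  expect_identical(dosages(g2), dosages(g))
  m2 <- readGeneModels(paths[["gene_models"]])
  expect_equal(m2$gene_id, sim$gene_models$gene_id)
  expect_equal(sort(m2$isoforms[[1]]), sort(sim$gene_models$isoforms[[1]]))
  ss2 <- readSumstats(paths[["sumstats_t1"]])
  expect_equal(ss2$beta, ss$beta, tolerance = 1e-12)
})
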