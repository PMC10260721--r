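test_that("harmonization flips swapped alleles, drops ambiguous and excluded variants", {
  ref <- data.frame(variant_id = c("r1", "r2", "r3", "r4"),
                    effect_allele = c("G", "C", "T", "G"),
                    other_allele = c("A", "T", "A", "C"))
  ss <- data.frame(variant_id = sprintf("r%d", 1:14),
                   chrom = "1", pos = c(1:4 * 100L, 5:14 * 100L),
                   effect_allele = c("A", "C", "T", "G", rep("G", 10)),
                   other_allele = c("G", "T", "A", "C", rep("A", 10)),
                   beta = c(-0.1, 0.2, 0.3, 0.4, rnorm(10)),
                   se = 0.1, p = 0.5, n = 1000)
  ss$z <- ss$beta / ss$se
  ref_all <- rbind(ref, data.frame(variant_id = sprintf("r%d", 5:14),
                                   effect_allele = "G",
                                   other_allele = "A"))
  h <- mungeHarmonize(ss, ref_all)
  expect_equal(h$beta[h$variant_id == "r1"], 0.1)   # swapped -> flipped
  expect_equal(h$beta[h$variant_id == "r2"], 0.2)   # same orientation
  expect_false("r3" %in% h$variant_id)              # A/T ambiguous
  expect_false("r4" %in% h$variant_id)              # G/C ambiguous
  expect_equal(h$chi2, h$z^2)
  # exclusion region removes r1
  h2 <- mungeHarmonize(ss, ref_all,
                       exclusion_regions = data.frame(chrom = "1",
                                                      start = 50,
                                                      end = 150))
  expect_false("r1" %in% h2$variant_id)
  expect_error(mungeHarmonize(ss[1:4, ], ref), "fewer than 10")
})

test_that("LD scores: self-pair and perfect-LD conventions", {
  x <- rep(c(0, 1, 2, 1), 10)
  y <- rbinom(40, 2, 0.3)
  g <- toy_genotypes(list(v1 = x, v2 = x, v3 = y),
                     pos = c(100L, 200L, 100000000L))
  ann <- cbind(base = rep(1, 3))
  # isolated variant: only the self pair contributes
  ell <- computeLdScores(g, ann, window_bp = 1000, adjusted = TRUE)
  expect_equal(ell$base[3], 1, tolerance = 1e-12)
  # two perfectly correlated variants, unadjusted: l = 2 each
  ell2 <- computeLdScores(g, ann, window_bp = 1000, adjusted = FALSE)
  expect_equal(ell2$base[1], 2, tolerance = 1e-12)
  expect_equal(ell2$base[2], 2, tolerance = 1e-12)
  expect_error(computeLdScores(g, ann, window_bp = 0), "window")
})

test_that("LD scores equal the brute-force pairwise oracle on a 30 x 200 fixture", {
  set.seed(55)
  g <- random_genotypes(30, 200, seed = 55)
  m <- 200; n <- 30
  ann <- cbind(base = rep(1, m),
               sub = as.numeric(seq_len(m) <= 60))
  win <- 5000
  for (adjusted in c(TRUE, FALSE)) {
    ell <- computeLdScores(g, ann, window_bp = win, adjusted = adjusted)
    d <- dosages(g); v <- variantInfo(g)
    oracle <- matrix(0, m, 2)
    for (j in 1:m) for (k in 1:m) {
      if (abs(v$pos[j] - v$pos[k]) > win) next
      r2 <- if (j == k) 1 else cor(d[, j], d[, k])^2
      if (adjusted && j != k) r2 <- r2 - (1 - r2) / (n - 2)
      oracle[j, ] <- oracle[j, ] + ann[k, ] * r2
    }
    expect_equal(ell$base, oracle[, 1], tolerance = 1e-10)
    expect_equal(ell$sub, oracle[, 2], tolerance = 1e-10)
  }
})

test_that("S-LDSC recovers tau exactly from noiseless statistics", {
  set.seed(66)
  m <- 400; N <- 10000
  ell <- data.frame(variant_id = sprintf("v%04d", 1:m),
                    base = runif(m, 1, 30),
                    sub = runif(m, 0, 10))
  ann <- cbind(base = rep(1, m), sub = rbinom(m, 1, 0.2))
  tau <- c(base = 2e-5, sub = 5e-5)
  chi2 <- 1 + N * (tau["base"] * ell$base + tau["sub"] * ell$sub)
  ss <- data.frame(variant_id = ell$variant_id, chi2 = chi2, n = N)
  fit <- sldscFit(ss, ell, ann, n_blocks = 50)
  expect_equal(unname(coef(fit)[-1]), unname(tau), tolerance = 1e-8)
  expect_equal(fit@intercept, 1, tolerance = 1e-6)
  # enrichment = prop_h2 / prop_snps by construction
  tab <- enrichmentTable(fit)
  expect_equal(tab$enrichment, tab$prop_h2 / tab$prop_snps,
               tolerance = 1e-12)
  # the all-SNP base annotation has enrichment exactly 1
  expect_equal(tab$enrichment[tab$annotation == "base"], 1,
               tolerance = 1e-12)
  # collinear annotations are rejected by name
  ell_bad <- ell; ell_bad$dup <- ell_bad$sub
  ann_bad <- cbind(ann, dup = ann[, "sub"])
  expect_error(sldscFit(ss, ell_bad, ann_bad, n_blocks = 50),
               "collinear")
})

test_that("one-sided enrichment test and per-tissue BH FDR behave as closed forms", {
  tab <- data.frame(tissue = "cortex", trait = c("t1", "t2", "t3"),
                    enrichment = c(1, 1 + 1.6449 * 0.5, 3),
                    se = c(0.5, 0.5, 0))
  out <- enrichmentTestAndFdr(tab)
  expect_equal(out$p_one_sided[1], 0.5, tolerance = 1e-12)
  expect_equal(out$p_one_sided[2], 0.05, tolerance = 1e-4)
  expect_true(is.na(out$p_one_sided[3]))   # zero SE flagged
  # BH on the 4-p fixture: all adjusted to 0.04
  tab2 <- data.frame(tissue = "t", trait = paste0("x", 1:4),
                     enrichment = 2, se = 1,
                     p_one_sided = c(0.01, 0.02, 0.03, 0.04))
  bh <- p.adjust(tab2$p_one_sided, method = "BH")
  expect_equal(bh, rep(0.04, 4))
  tab3 <- data.frame(tissue = "t", trait = paste0("x", 1:4),
                     enrichment = 1 + qnorm(1 - c(0.01, 0.02, 0.03, 0.04)),
                     se = 1)
  out3 <- enrichmentTestAndFdr(tab3)
  expect_equal(out3$fdr, rep(0.04, 4), tolerance = 1e-10)
})

test_that("relative enrichment with delta-method SE", {
  r <- relativeEnrichmentDelta(4, 1, 2, 0)
  expect_equal(r$ratio, 2)
  expect_equal(r$se, 0.5)
  expect_equal(relativeEnrichmentDelta(3, 0.2, 3, 0.1)$ratio, 1)
  # SE grows monotonically in each input SE
  expect_gt(relativeEnrichmentDelta(4, 2, 2, 0)$se, r$se)
  expect_gt(relativeEnrichmentDelta(4, 1, 2, 0.5)$se, r$se)
  expect_error(relativeEnrichmentDelta(4, 1, 0, 0.1), "> 0")
})

test_that("S-LDSC jackknife errors cover tau under heteroskedastic noise", {
  set.seed(72)
  m <- 2000; N <- 20000
  ell <- data.frame(variant_id = sprintf("v%04d", 1:m),
                    base = runif(m, 2, 40),
                    sub = runif(m, 0, 8))
  ann <- cbind(base = rep(1, m), sub = rbinom(m, 1, 0.15))
  tau <- c(base = 1.5e-5, sub = 6e-5)
  mu <- 1 + N * (tau["base"] * ell$base + tau["sub"] * ell$sub)
  chi2 <- mu * rchisq(m, df = 1)        # marginal chi2(1) scaling
  ss <- data.frame(variant_id = ell$variant_id, chi2 = chi2, n = N)
  fit <- sldscFit(ss, ell, ann, n_blocks = 40)
  est <- coef(fit)[-1]
  se <- fit@tauSE
  expect_lt(abs(est["base"] - tau["base"]), 3 * se["base"])
  expect_lt(abs(est["sub"] - tau["sub"]), 3 * se["sub"])
  # a clearly positive annotation coefficient is detected one-sided
  tab <- enrichmentTable(fit)
  expect_lt(tab$p_one_sided[tab$annotation == "sub"], 0.05)
  expect_gt(tab$enrichment[tab$annotation == "sub"], 1)
})
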