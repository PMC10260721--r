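test_that("instrument harmonization aligns alleles, drops mismatches, is involutive", {
  exposure <- data.frame(variant_id = c("v1", "v2", "v3"),
                         effect_allele = c("G", "G", "G"),
                         other_allele = c("T", "T", "T"),
                         beta = c(0.2, 0.3, 0.4), se = 0.05,
                         maf = c(0.3, 0.3, 0.3))
  outcome <- data.frame(variant_id = c("v1", "v2", "v3"),
                        effect_allele = c("T", "G", "G"),
                        other_allele = c("G", "T", "C"),
                        beta = c(-0.1, 0.15, 9), se = 0.02, p = 0.5,
                        n = 1e5)
  h <- harmonizeInstruments(exposure, outcome)
  expect_equal(h$variant_id, c("v1", "v2"))   # v3 allele pair mismatch
  expect_equal(h$b_exp, c(0.2, 0.3))
  expect_equal(h$b_out, c(0.1, 0.15))         # v1 swapped -> flipped
  # involution: flipping the outcome orientation twice changes nothing
  out2 <- outcome[1:2, ]
  tmp <- out2$effect_allele
  out2$effect_allele <- out2$other_allele
  out2$other_allele <- tmp
  out2$beta <- -out2$beta
  h2 <- harmonizeInstruments(exposure, out2)
  expect_equal(h2$b_out, h$b_out)
  # strand-ambiguous high-MAF instruments are dropped
  expA <- data.frame(variant_id = "v9", effect_allele = "A",
                     other_allele = "T", beta = 0.2, se = 0.05,
                     maf = 0.45)
  outA <- data.frame(variant_id = "v9", effect_allele = "A",
                     other_allele = "T", beta = 0.1, se = 0.02)
  expect_error(harmonizeInstruments(expA, outA), "instrument")
  expect_error(harmonizeInstruments(exposure,
                                    transform(outcome, variant_id = "zz")),
               "shared")
})

test_that("greedy LD clumping keeps the smallest-p variant of each correlated block", {
  base <- expand.grid(a = 0:2, c = 0:2)      # balanced: cor(a, c) = 0
  a <- rep(base$a, 40); cc <- rep(base$c, 40)
  b <- a; b[1:30] <- 2 - b[1:30]             # correlated with a, r2 large
  g <- toy_genotypes(list(A = a, B = b, C = cc))
  rec <- data.frame(variant_id = c("A", "B", "C"),
                    p = c(1e-10, 1e-9, 1e-8))
  kept <- ldClump(rec, g, r2_max = 0.001)
  expect_setequal(kept$variant_id, c("A", "C"))
  # all pairwise independent: everything kept
  g2 <- toy_genotypes(list(A = a, C = cc))
  expect_equal(nrow(ldClump(rec[c(1, 3), ], g2, 0.001)), 2)
  # unknown variants dropped with warning
  expect_warning(ldClump(rec, g2, 0.001), "absent")
})

test_that("greedy clumping equals the exhaustive best-maximal-independent-set oracle", {
  oracle_clump <- function(rec, r2, thr) {
    m <- nrow(rec)
    best <- NULL
    for (mask in 1:(2^m - 1)) {
      S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      ok <- all(r2[S, S][upper.tri(diag(length(S)))] < thr)
      if (!ok) next
      maximal <- all(vapply(setdiff(seq_len(m), S), function(j)
        any(r2[j, S] >= thr), logical(1)))
      if (!maximal) next
      key <- sort(rec$p[S])
      if (is.null(best)) { best <- S; next }
      bk <- sort(rec$p[best])
      L <- max(length(key), length(bk))
      key_p <- c(key, rep(Inf, L - length(key)))
      bk_p <- c(bk, rep(Inf, L - length(bk)))
      cmpi <- which(key_p != bk_p)
      if (length(cmpi) && key_p[cmpi[1]] < bk_p[cmpi[1]]) best <- S
    }
    sort(rec$variant_id[best])
  }
  set.seed(99)
  for (rep in 1:5) {
    g <- random_genotypes(400, 8, seed = 100 + rep)
    rec <- data.frame(variant_id = variantIDs(g),
                      p = runif(8, 1e-12, 1e-4))
    d <- dosages(g)
    r2 <- cor(d)^2
    thr <- 0.01
    kept <- ldClump(rec, g, thr)
    expect_identical(sort(kept$variant_id), oracle_clump(rec, r2, thr))
  }
})

test_that("IVW reduces to the Wald ratio and matches the weighted-regression oracle", {
  one <- data.frame(variant_id = "v1", effect_allele = "G",
                    other_allele = "A", b_exp = 0.2, se_exp = 0.02,
                    b_out = 0.1, se_out = 0.01)
  expect_equal(mrIvw(one)$estimate, 0.5, tolerance = 1e-12)
  set.seed(10)
  inst <- data.frame(variant_id = sprintf("v%d", 1:8),
                     effect_allele = "G", other_allele = "A",
                     b_exp = runif(8, 0.1, 0.4), se_exp = 0.02,
                     b_out = rnorm(8, 0.05, 0.02),
                     se_out = runif(8, 0.01, 0.05))
  res <- mrIvw(inst)
  fit <- lm(b_out ~ 0 + b_exp, data = inst, weights = 1 / inst$se_out^2)
  sm <- summary(fit)
  expect_equal(res$estimate, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(res$se, unname(sm$coefficients[1, 2] / sm$sigma),
               tolerance = 1e-10)
  # exact proportionality
  inst2 <- inst; inst2$b_out <- 0.5 * inst2$b_exp
  expect_equal(mrIvw(inst2)$estimate, 0.5, tolerance = 1e-12)
  expect_error(mrIvw(transform(inst, se_out = 0)), "> 0")
})

test_that("Egger requires 3 instruments and recovers an exact line", {
  inst <- data.frame(variant_id = sprintf("v%d", 1:4),
                     effect_allele = "G", other_allele = "A",
                     b_exp = c(0.1, 0.2, 0.3, 0.4), se_exp = 0.02,
                     b_out = 0.1 + 0.5 * c(0.1, 0.2, 0.3, 0.4),
                     se_out = 0.02)
  res <- mrEgger(inst)
  expect_equal(res$estimate, 0.5, tolerance = 1e-10)
  expect_equal(res$egger_intercept, 0.1, tolerance = 1e-10)
  expect_error(mrEgger(inst[1:2, ]), "three")
})

test_that("BH FDR across MR pairs follows the step-up rule", {
  res <- data.frame(p = c(0.01, 0.02, 0.03, 0.04))
  out <- mrFdr(res)
  expect_equal(out$fdr, rep(0.04, 4))
  expect_equal(mrFdr(data.frame(p = 0.3))$fdr, 0.3)
  out2 <- mrFdr(data.frame(p = sort(runif(20))))
  expect_true(all(diff(rank(out2$fdr, ties.method = "first")) >= 0 |
                    diff(out2$fdr) >= 0))
})

test_that("reverse-direction IVW is null-calibrated under forward-only simulation", {
  # five exactly orthogonal instruments (3^5 factorial design)
  des <- as.matrix(expand.grid(rep(list(0:2), 5)))
  g <- toy_genotypes(lapply(1:5, function(j) des[, j]))
  trait_ss <- data.frame(variant_id = variantIDs(g),
                         chrom = "1", pos = variantInfo(g)$pos,
                         effect_allele = variantInfo(g)$alt,
                         other_allele = variantInfo(g)$ref,
                         beta = c(0.3, -0.25, 0.2, 0.35, -0.3),
                         se = 0.01, p = 1e-12, n = 1e5)
  set.seed(123)
  pvals <- replicate(150, {
    y <- rnorm(nrow(des))
    rec <- fastOlsScan(y, g)
    reverseMrCheck(trait_ss, rec, g, alpha = 5e-8, r2_max = 0.001)$p
  })
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.05)
  # no instruments reaching significance -> flagged
  weak <- transform(trait_ss, p = 0.5)
  out <- reverseMrCheck(weak, fastOlsScan(rnorm(nrow(des)), g), g)
  expect_equal(out$note, "no instruments")
  expect_equal(out$n_instruments, 0L)
})

test_that("reverse IVW recovers a true reverse-causal effect", {
  set.seed(7)
  n <- 4000
  f <- runif(5, 0.2, 0.5)
  X <- sapply(f, function(fj) rbinom(n, 2, fj))
  g <- toy_genotypes(lapply(1:5, function(j) X[, j]))
  b_trait <- c(0.3, -0.25, 0.2, 0.35, -0.3)
  trait <- as.vector(X %*% b_trait) + rnorm(n, sd = 0.5)
  ratio <- 0.4 * trait + rnorm(n)        # trait causes the ratio
  trait_rec <- fastOlsScan(trait, g)
  trait_ss <- data.frame(variant_id = trait_rec$variant_id, chrom = "1",
                         pos = variantInfo(g)$pos,
                         effect_allele = variantInfo(g)$alt,
                         other_allele = variantInfo(g)$ref,
                         beta = trait_rec$beta, se = trait_rec$se,
                         p = trait_rec$p, n = n)
  out <- reverseMrCheck(trait_ss, fastOlsScan(ratio, g), g,
                        r2_max = 0.05)
  expect_gt(out$n_instruments, 2)
  expect_lt(abs(out$estimate - 0.4), 2 * out$se)
})
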