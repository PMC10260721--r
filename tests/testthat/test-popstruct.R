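test_that("MAF filter is strictly greater-than and drops monomorphic variants", {
  at_threshold <- c(rep(1, 50), rep(0, 450))      # maf = 50/1000 = 0.05
  just_above <- c(rep(1, 51), rep(0, 449))        # maf = 0.051
  mono <- rep(0, 500)
  g <- toy_genotypes(list(at = at_threshold, above = just_above,
                          mono = mono))
  kept <- variantIDs(variantMafFilter(g, 0.05))
  expect_identical(kept, "above")
  # threshold 0: all polymorphic retained, monomorphic still removed
  kept0 <- variantIDs(variantMafFilter(g, 0))
  expect_setequal(kept0, c("at", "above"))
})

test_that("GRM matches the brute-force double-loop oracle and handles duplicates", {
  set.seed(7)
  g <- random_genotypes(20, 50, seed = 7)
  d <- dosages(g); d[2, 5] <- NA
  g <- GenotypeMatrix(d, variantInfo(g)[, c("chrom", "pos", "ref", "alt")])
  K <- computeGrm(g)
  # oracle: explicit double loop over mean-imputed standardized dosages
  dd <- dosages(g)
  for (j in seq_len(ncol(dd))) {
    nas <- is.na(dd[, j]); dd[nas, j] <- mean(dd[, j], na.rm = TRUE)
  }
  Z <- apply(dd, 2, function(x) (x - mean(x)) / sd(x))
  M <- ncol(Z)
  Ko <- matrix(0, 20, 20)
  for (i in 1:20) for (k in 1:20)
    Ko[i, k] <- sum(Z[i, ] * Z[k, ]) / M
  expect_equal(unname(K), Ko, tolerance = 1e-10)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_equal(mean(diag(K)), 1, tolerance = 0.1)
  # duplicated sample: off-diagonal equals the diagonals
  d2 <- dosages(g); d2[2, ] <- d2[1, ]
  K2 <- computeGrm(GenotypeMatrix(
    d2, variantInfo(g)[, c("chrom", "pos", "ref", "alt")]))
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-9)
  expect_equal(K2[1, 2], K2[2, 2], tolerance = 1e-9)
})

test_that("genomic PCs are orthonormal, ordered, and separate structured subpopulations", {
  set.seed(12)
  n <- 120
  pop <- rep(0:1, each = n / 2)
  cols <- lapply(1:150, function(j) {
    f <- runif(1, 0.1, 0.5)
    f2 <- plogis(qlogis(f) + ifelse(runif(1) < 0.5, 1.2, -1.2))
    rbinom(n, 2, ifelse(pop == 1, f2, f))
  })
  g <- toy_genotypes(cols)
  K <- computeGrm(g)
  V <- genomicPcs(K, 3)
  expect_equal(crossprod(V), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  e <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(diff(e[1:3]) <= 1e-12))
  expect_gt(abs(cor(V[, 1], pop)), 0.9)
  expect_error(genomicPcs(K, nrow(K)), "n_pcs")
})

test_that("covariate residualization matches the normal-equations oracle", {
  y <- c(2.1, 3.5, 1.2, 4.4, 2.2, 5.0)
  cv <- data.frame(age = c(30, 40, 25, 60, 35, 55),
                   sex = c(0, 1, 0, 1, 1, 0))
  r <- residualizeCovariates(y, cv)
  X <- cbind(1, as.matrix(cv))
  beta <- solve(t(X) %*% X, t(X) %*% y)   # hand normal equations
  expect_equal(r, as.vector(y - X %*% beta), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(X, r))), 1e-9)  # orthogonal to design
  # orthogonal phenotype comes back mean-centered
  y2 <- residuals(lm(rnorm(6) ~ X - 1))
  expect_equal(residualizeCovariates(y2, cv), unname(y2),
               tolerance = 1e-9)
  expect_error(residualizeCovariates(y, cbind(cv, age2 = cv$age)),
               "rank")
})

test_that("inverse normal transform uses Blom offsets, preserves order, averages ties", {
  z <- inverseNormalTransform(c(10, 20, 30))
  expect_equal(z, c(-0.8694, 0, 0.8694), tolerance = 1e-3)
  set.seed(5)
  x <- rnorm(50)
  z2 <- inverseNormalTransform(x)
  expect_identical(order(z2), order(x))
  # tied middle values of n = 4 share one transformed value
  zt <- inverseNormalTransform(c(1, 2, 2, 3))
  expect_equal(zt[2], zt[3])
  # missing propagates; degenerate input errors
  zm <- inverseNormalTransform(c(1, NA, 2, 3))
  expect_true(is.na(zm[2]))
  expect_error(inverseNormalTransform(c(1, 1, 1)), "identical")
})

test_that("residualize-then-INT pipeline yields mean 0, variance ~ 1", {
  set.seed(6)
  n <- 400
  cv <- data.frame(age = runif(n, 21, 70), sex = rbinom(n, 1, 0.5))
  y <- 0.01 * cv$age + 0.3 * cv$sex + rexp(n)   # skewed phenotype
  z <- inverseNormalTransform(residualizeCovariates(y, cv))
  expect_equal(mean(z), 0, tolerance = 0.02)
  expect_equal(var(z), 1, tolerance = 0.05)
})
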