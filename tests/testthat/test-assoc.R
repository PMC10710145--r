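test_that("genotype PCs separate simulated subpopulations", {
  g <- simulate_genotypes(300, 400, maf_range = c(0.1, 0.4),
                          subpop_fraction = 0.5, maf_divergence = 0.2,
                          seed = 17)
  pcs <- genotype_pca(g, k = 5)
  grp <- attr(g, "subpop")
  expect_gt(abs(cor(pcs[, 1], grp)), 0.9)
  ## scores orthogonal (SVD property)
  gram <- crossprod(pcs)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
})

test_that("genotype PCA rejects degenerate input and ignores variant order", {
  g0 <- genotype_matrix(matrix(1, 10, 4))
  expect_error(genotype_pca(g0, 2), "zero variance")
  g <- simulate_genotypes(80, 60, seed = 4)
  p1 <- genotype_pca(g, k = 3)
  perm <- rev(seq_len(60))
  g2 <- genotype_matrix(g$counts[, perm],
                        variant_ids = g$variant_ids[perm])
  p2 <- genotype_pca(g2, k = 3)
  expect_equal(abs(p1), abs(p2), tolerance = 1e-8)
})

test_that("residualize removes the covariate projection exactly", {
  x1 <- matrix(rnorm(30), 30, 1)
  expect_equal(residualize(c(1, 2, 3)), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(residualize(x1[, 1], x1), rep(0, 30), tolerance = 1e-10)
  set.seed(8)
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- rnorm(200)
  r <- residualize(y, x)
  ## brute-force normal equations oracle
  d <- cbind(1, x)
  beta <- solve(t(d) %*% d, t(d) %*% y)
  expect_equal(r, y - drop(d %*% beta), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(d, r))), 1e-8)
})

test_that("residualize names the offending collinear column", {
  x <- cbind(a = rnorm(20), b = 1:20)
  x <- cbind(x, c = x[, "a"] * 2)
  expect_error(residualize(rnorm(20), covariate_set(x)), "c")
})

test_that("score test reproduces the defining formulas", {
  st <- score_test(c(1, -1, 0), c(1, 0, -1))
  expect_equal(st$U, 1)
  expect_equal(st$V, 4 / 3)
  expect_equal(st$T, 0.75)
  ## orthogonal residuals
  st0 <- score_test(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(st0$T, 0)
  expect_equal(st0$p, 1)
  ## degenerate genotype column flagged
  stz <- score_test(c(1, -1, 0), c(0, 0, 0))
  expect_true(stz$degenerate)
  expect_equal(stz$p, 1)
})

test_that("score statistic equals N times squared correlation", {
  set.seed(5)
  x <- matrix(rnorm(60), 60, 1)
  for (i in 1:100) {
    y_res <- residualize(rnorm(60), x)
    g_res <- residualize(rbinom(60, 2, 0.3), x)
    st <- score_test(y_res, g_res)
    expect_equal(st$T, 60 * cor(y_res, g_res)^2, tolerance = 1e-10)
  }
})

test_that("gwas scan finds a planted causal variant", {
  g <- simulate_genotypes(400, 300, maf_range = c(0.2, 0.4), seed = 23)
  cov <- matrix(rnorm(400 * 2), 400, 2)
  y <- simulate_phenotype(g, causal_index = 42, causal_effects = 1.2,
                          covariates = cov, covariate_effects = c(1, -1),
                          noise_sd = 1, seed = 3)
  tab <- run_gwas(g, y, covariate_set(cov))
  expect_equal(nrow(tab), 300)
  expect_equal(tab$variant_id[which.min(tab$p)], "snp42")
})

test_that("gwas is invariant to a consistent subject permutation", {
  g <- simulate_genotypes(120, 50, seed = 2)
  cov <- matrix(rnorm(120), 120, 1)
  y <- simulate_phenotype(g, causal_index = 5, causal_effects = 0.8,
                          covariates = cov, covariate_effects = 1, seed = 6)
  tab1 <- run_gwas(g, y, covariate_set(cov))
  perm <- sample(120)
  g2 <- genotype_matrix(g$counts[perm, ], subject_ids = g$subject_ids[perm],
                        variant_ids = g$variant_ids,
                        chromosome = g$chromosome, position = g$position)
  tab2 <- run_gwas(g2, y[perm], covariate_set(cov[perm, , drop = FALSE]))
  expect_equal(tab1$p, tab2$p, tolerance = 1e-10)
})

test_that("top-k selection orders by p with positional tie-break", {
  tab <- data.frame(
    variant_id = c("a", "b", "c", "d"),
    chrom = c("2", "1", "1", "3"),
    pos = c(100L, 200L, 500L, 50L),
    U = 0, V = 1, T = 0,
    ## b and c tie on p; b sits earlier on chromosome 1
    p = c(0.01, 0.001, 0.001, 0.5),
    degenerate = FALSE
  )
  counts <- matrix(rbinom(4 * 10, 2, 0.4), 10, 4,
                   dimnames = list(NULL, c("a", "b", "c", "d")))
  g <- genotype_matrix(counts, variant_ids = c("a", "b", "c", "d"),
                       chromosome = c("2", "1", "1", "3"),
                       position = c(100L, 200L, 500L, 50L))
  sel <- select_top_k(tab, g, k = 4)
  ## ties at p=0.001: chrom 1 pos 200 ("b") precedes chrom 1 pos 500 ("c")
  expect_equal(sel$variant_ids, c("b", "c", "a", "d"))
  expect_equal(dim(sel$features), c(10L, 4L))
  expect_error(select_top_k(tab, g, k = 5), "exceeds")
})

test_that("selected p-values dominate the excluded ones", {
  g <- simulate_genotypes(150, 500, seed = 14)
  cov <- matrix(rnorm(150), 150, 1)
  y <- simulate_phenotype(g, covariates = cov, covariate_effects = 1,
                          noise_sd = 1, seed = 5)
  tab <- run_gwas(g, y, covariate_set(cov))
  sel <- select_top_k(tab, g, k = 100)
  inside <- tab$p[match(sel$variant_ids, tab$variant_id)]
  outside <- tab$p[!(tab$variant_id %in% sel$variant_ids)]
  expect_lte(max(inside), min(outside))
  expect_equal(ncol(sel$features), 100)
  expect_false(anyNA(sel$features))
})
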