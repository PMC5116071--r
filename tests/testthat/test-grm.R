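test_that("compute_grm matches the standardized cross-product by hand", {
  # 4 samples x 3 variants, frequencies computed from the sample
  X <- rbind(c(0, 1, 2), c(1, 1, 0), c(2, 0, 1), c(1, 2, 1))
  g <- genotype_matrix(X)
  p <- colMeans(X) / 2
  Z <- sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  K_hand <- tcrossprod(Z) / 3
  K <- compute_grm(g)
  expect_equal(K$K, K_hand, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(K$K, t(K$K))
})

test_that("duplicate samples have K_12 equal to the diagonal entries", {
  X <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 1))
  K <- compute_grm(genotype_matrix(X))$K
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
})

test_that("GRM of a simulated unrelated panel has unit diagonal and 1/S off-diagonal variance", {
  g <- simulate_genotypes(200, 5000, seed = 7)
  K <- compute_grm(g)$K
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(diag(K)) - 1), 0.02)
  # sample-frequency centring makes rows sum to ~0, so the off-diagonal
  # mean sits at -tr[K]/(N (N-1)) ~ -1/(N-1), vanishing with N
  expect_lt(abs(mean(off) + 1 / 199), 1e-3)
  expect_lt(abs(var(off) - 1 / 5000) / (1 / 5000), 0.15)
})

test_that("compute_grm is invariant to variant ordering and rejects monomorphic input", {
  g <- simulate_genotypes(50, 200, seed = 3)
  perm <- sample(200)
  g2 <- genotype_matrix(g$dosages[, perm], g$sample_ids,
                        g$variants[perm, ])
  expect_equal(compute_grm(g)$K, compute_grm(g2)$K, tolerance = 1e-12)
  gm <- genotype_matrix(cbind(rep(0, 10), rbinom(10, 2, 0.5)))
  expect_error(compute_grm(gm), "monomorphic")
})

test_that("grm_principal_components matches a dense eigendecomposition", {
  set.seed(11)
  A <- crossprod(matrix(rnorm(25), 5))
  K <- genetic_similarity(A / mean(diag(A)))
  pcs <- grm_principal_components(K, 3)
  e <- eigen(K$K, symmetric = TRUE)
  for (j in 1:3) {
    expect_equal(abs(sum(pcs[, j] * e$vectors[, j])), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(pcs[, j]^2)), 1, tolerance = 1e-12)
  }
  expect_equal(attr(pcs, "eigenvalues"), e$values[1:3])
  # rank-1 matrix: first PC proportional to the generating vector
  v <- c(3, 1, -2, 0.5) / sqrt(sum(c(3, 1, -2, 0.5)^2))
  K1 <- genetic_similarity(tcrossprod(v) + diag(1e-10, 4))
  p1 <- grm_principal_components(K1, 1)
  expect_equal(abs(sum(p1 * v)), 1, tolerance = 1e-6)
  expect_error(grm_principal_components(K, 5), "n_pc")
})

test_that("GCTA binary GRM round-trips and validates sizes", {
  g <- simulate_genotypes(7, 50, maf_range = c(0.3, 0.5), seed = 5)
  K <- compute_grm(g)
  prefix <- file.path(withr::local_tempdir(), "test")
  write_grm(K, prefix, n_snps = 50)
  K2 <- read_grm(prefix)
  expect_equal(K2$K, K$K, tolerance = 1e-6)
  expect_equal(K2$sample_ids, K$sample_ids)
  # corrupt: drop the last sample from the id file
  writeLines(readLines(paste0(prefix, ".grm.id"))[-7],
             paste0(prefix, ".grm.id"))
  expect_error(read_grm(prefix), "expected")
})

test_that("GCTA lower-triangle ordering is (1,1),(2,1),(2,2),...", {
  K <- genetic_similarity(matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3))
  prefix <- file.path(withr::local_tempdir(), "tri")
  write_grm(K, prefix)
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  v <- readBin(con, "numeric", 6, size = 4)
  close(con)
  expect_equal(v, c(1, .1, 1, .2, .3, 1), tolerance = 1e-6)
})

test_that("plain-text GRM round-trips", {
  K <- compute_grm(simulate_genotypes(5, 40, maf_range = c(0.35, 0.5),
                                      seed = 9))
  path <- file.path(withr::local_tempdir(), "k.txt")
  write_grm_text(K, path)
  K2 <- read_grm_text(path)
  expect_equal(K2$K, K$K, tolerance = 1e-12)
})

test_that("PLINK bed/bim/fam round-trips including missing genotypes", {
  g <- simulate_genotypes(13, 37, missing_rate = 0.05, seed = 21)
  prefix <- file.path(withr::local_tempdir(), "pl")
  write_plink(g, prefix)
  g2 <- read_plink(prefix)
  expect_equal(g2$dosages, g$dosages, ignore_attr = TRUE)
  expect_equal(g2$sample_ids, g$sample_ids)
  expect_equal(g2$variants$id, g$variants$id)
  # magic byte check
  con <- file(paste0(prefix, ".bed"), "rb")
  expect_equal(readBin(con, "raw", 3), as.raw(c(0x6c, 0x1b, 0x01)))
  close(con)
})
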