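test_that("pedigree structure encodes twin-design kinship and shared environment", {
  ped <- simulate_twin_pedigree(n_mz = 2, n_dz = 2, n_sib = 3,
                                n_singleton = 1)
  tab <- ped$table
  K <- ped$K_ped$K
  L <- ped$Lambda
  expect_equal(diag(K), rep(1, nrow(tab)), ignore_attr = TRUE)
  mz <- which(tab$relation == "MZ")
  dz <- which(tab$relation == "DZ")
  sib <- which(tab$relation == "sib")
  expect_equal(K[mz[1], mz[2]], 1)
  expect_equal(K[dz[1], dz[2]], 0.5)
  # sibs relate to their family's twins by 0.5
  fam_of_sib <- tab$family[sib[1]]
  twin_in_fam <- which(tab$family == fam_of_sib & tab$relation != "sib")[1]
  expect_equal(K[sib[1], twin_in_fam], 0.5)
  # Lambda is 1 within families (including sibs), 0 across
  expect_true(all(L[tab$family[1] == tab$family,
                    tab$family[1] == tab$family] == 1))
  expect_equal(sum(L[tab$family == tab$family[1],
                     tab$family != tab$family[1]]), 0)
  expect_true(all(L %in% c(0, 1)))
})

test_that("REML recovers ACE variance components in a simulated twin study", {
  ped <- simulate_twin_pedigree(100, 100, 0, 0)
  set.seed(71)
  est <- matrix(0, 30, 3)
  for (r in 1:30) {
    Y <- simulate_traits(ped$K_ped, matrix(0.5), matrix(0.3),
                         Sigma_C = matrix(0.2), Lambda = ped$Lambda)
    f <- fit_ace_component(Y$Y[, 1], ped$K_ped, ped$Lambda)
    expect_true(f$converged)
    est[r, ] <- f$sigma2
  }
  expect_equal(colMeans(est), c(0.5, 0.2, 0.3), tolerance = 0.2)
})

test_that("perfect MZ concordance drives the unique environment to zero", {
  n_pairs <- 30
  ped <- simulate_twin_pedigree(n_pairs, 0, 0, 0)
  set.seed(73)
  fam_val <- rnorm(n_pairs)
  y <- fam_val[match(ped$table$family, unique(ped$table$family))]
  f <- fit_ace_component(y, ped$K_ped, ped$Lambda)
  expect_lt(f$sigma2["E"] / sum(f$sigma2), 1e-4)
  expect_gt(f$h2 + f$c2, 0.999)
})

test_that("unrelated-sample ACE input is flagged as unidentifiable", {
  set.seed(74)
  y <- rnorm(40)
  f <- fit_ace_component(y, diag(40), matrix(0, 40, 40))
  expect_false(f$identifiable)
  expect_false(f$converged)
})

test_that("non-PSD inputs are rejected", {
  K <- diag(4); K[1, 2] <- K[2, 1] <- 2
  expect_error(fit_ace_component(rnorm(4), K, NULL), "semidefinite")
})

test_that("combine_components takes a variance-weighted average", {
  f1 <- structure(list(h2 = 0.2, total_variance = 1, converged = TRUE),
                  class = "ace_fit")
  f2 <- structure(list(h2 = 0.6, total_variance = 3, converged = TRUE),
                  class = "ace_fit")
  expect_equal(as.numeric(combine_components(list(f1, f2))), 0.5)
  # identical components: convexity
  expect_equal(as.numeric(combine_components(list(f1, f1))), 0.2)
  # single component passes through
  expect_equal(as.numeric(combine_components(list(f2))), 0.6)
  # explicit weights override the fitted ones
  expect_equal(as.numeric(combine_components(list(f1, f2), c(1, 1))), 0.4)
  f3 <- structure(list(h2 = 0.9, total_variance = 1, converged = FALSE),
                  class = "ace_fit")
  expect_equal(as.numeric(combine_components(list(f1, f3))), 0.2)
  expect_error(combine_components(list(f3)), "converged")
})

test_that("bootstrap of identical clone families has zero spread", {
  ped <- simulate_twin_pedigree(10, 0, 0, 0)
  y <- rep(c(1.3, -0.7), 10)  # every family identical
  bs <- block_bootstrap_se(matrix(y), ped, n_boots = 30, seed = 5)
  expect_equal(as.numeric(bs), 0, tolerance = 1e-10)
  ped1 <- simulate_twin_pedigree(1, 0, 0, 0)
  expect_error(block_bootstrap_se(matrix(c(1, 2)), ped1, n_boots = 10,
                                  seed = 1), "2 families")
})

test_that("two-family bootstrap matches the exhaustive enumeration oracle", {
  # families A and B: resamples are {AA, AB, BA, BB} with equal probability
  ped <- pedigree_structure(data.frame(
    sample = c("a1", "a2", "b1", "b2"),
    family = c("A", "A", "B", "B"),
    relation = c("MZ", "MZ", "DZ", "DZ")))
  set.seed(81)
  Y <- simulate_traits(ped$K_ped, matrix(0.6), matrix(0.4),
                       Sigma_C = matrix(0.2), Lambda = ped$Lambda)$Y
  fit_on <- function(fam1, fam2) {
    # duplicated families are independent blocks, not extra relatives
    K <- as.matrix(Matrix::bdiag(ped$K_ped$K[fam1, fam1],
                                 ped$K_ped$K[fam2, fam2]))
    L <- as.matrix(Matrix::bdiag(ped$Lambda[fam1, fam1],
                                 ped$Lambda[fam2, fam2]))
    fit_ace_component(Y[c(fam1, fam2), 1], K, L)$h2
  }
  A <- c(1, 2); B <- c(3, 4)
  h_AA <- fit_on(A, A)
  h_AB <- fit_on(A, B)
  h_BB <- fit_on(B, B)
  vals <- c(h_AA, h_AB, h_AB, h_BB)
  sd_exact <- sqrt(mean((vals - mean(vals))^2))
  bs <- block_bootstrap_se(Y, ped, n_boots = 400, seed = 82)
  # 400 draws from a 4-point distribution: sd of sd ~ 4%
  expect_equal(as.numeric(bs), sd_exact, tolerance = 0.15)
})

test_that("fit_ace combines per-component fits with a bootstrap s.e.", {
  ped <- simulate_twin_pedigree(40, 40, 0, 0)
  Y <- simulate_traits(ped$K_ped, diag(0.5, 2), diag(0.3, 2),
                       Sigma_C = diag(0.2, 2), Lambda = ped$Lambda,
                       seed = 91)
  fit <- fit_ace(Y, ped, n_boots = 40, seed = 92)
  expect_length(fit$fits, 2)
  expect_true(fit$h2 >= 0 && fit$h2 <= 1)
  expect_true(is.finite(fit$se) && fit$se > 0)
  manual <- combine_components(fit$fits)
  expect_equal(fit$h2, as.numeric(manual))
})
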