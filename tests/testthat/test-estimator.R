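test_that("M=1 moment matching equals the brute-force Haseman-Elston OLS", {
  dat <- sim_dataset(n = 80, s = 400, m = 1, seed = 2)
  P <- project_out_covariates(dat$Y, dat$K)
  D <- fit_moment_matching(P)
  o <- he_ols_oracle(P$Y[, 1], P$K)
  expect_equal(D$h2_raw, o$h2, tolerance = 1e-8)
  expect_equal(D$Sigma_A[1, 1], o$sigma_a, tolerance = 1e-8)
  expect_equal(D$Sigma_E[1, 1], o$sigma_e, tolerance = 1e-8)
})

test_that("multivariate decomposition matches elementwise regression on a hand-enumerable fixture", {
  # N=6 block-structured similarity, 2 traits, fully written out
  K <- genetic_similarity(rbind(
    c(1.0, 0.5, 0.0, 0.0, 0.0, 0.0),
    c(0.5, 1.0, 0.0, 0.0, 0.0, 0.0),
    c(0.0, 0.0, 1.0, 0.3, 0.0, 0.0),
    c(0.0, 0.0, 0.3, 1.0, 0.0, 0.0),
    c(0.0, 0.0, 0.0, 0.0, 1.0, 0.1),
    c(0.0, 0.0, 0.0, 0.0, 0.1, 1.0)))
  Y <- trait_matrix(cbind(c(1.2, 0.8, -0.5, -0.1, 0.4, -1.8),
                          c(0.3, -0.6, 1.1, 0.9, -1.2, -0.5)),
                    sample_ids = K$sample_ids)
  P <- project_out_covariates(Y, K)
  D <- fit_moment_matching(P)
  o <- he_ols_oracle_multi(P$Y, P$K)
  expect_equal(D$Sigma_A, o$Sigma_A, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(D$Sigma_E, o$Sigma_E, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(D$h2_raw, o$h2, tolerance = 1e-8)
  # trace bookkeeping
  expect_equal(D$t_P, D$t_A + D$t_E)
  expect_equal(D$v_K, sum(P$K^2) - sum(diag(P$K))^2 / nrow(P$K),
               tolerance = 1e-10)
})

test_that("heritability is invariant to orthogonal rotation of the traits", {
  dat <- sim_dataset(n = 120, s = 600, m = 4, seed = 5)
  P <- project_out_covariates(dat$Y, dat$K)
  h0 <- fit_moment_matching(P)$h2_raw
  set.seed(99)
  for (r in 1:5) {
    T_ <- random_orthogonal(4)
    Pr <- P
    Pr$Y <- P$Y %*% T_
    expect_equal(fit_moment_matching(Pr)$h2_raw, h0, tolerance = 1e-10)
  }
})

test_that("multivariate estimate is the variance-weighted average of per-component estimates", {
  dat <- sim_dataset(n = 100, s = 500, m = 3, seed = 8,
                     Sigma_A = diag(c(0.7, 0.3, 0.1)),
                     Sigma_E = diag(c(0.5, 0.9, 0.4)))
  P <- project_out_covariates(dat$Y, dat$K)
  D <- fit_moment_matching(P)
  per <- vapply(1:3, function(m) {
    Pm <- P
    Pm$Y <- P$Y[, m, drop = FALSE]
    Dm <- fit_moment_matching(Pm)
    c(Dm$h2_raw, Dm$t_P)
  }, numeric(2))
  gamma <- per[2, ] / sum(per[2, ])
  expect_equal(sum(gamma * per[1, ]), D$h2_raw, tolerance = 1e-10)
})

test_that("estimator is unbiased over replicates with known covariances", {
  g <- simulate_genotypes(150, 800, seed = 31)
  K <- compute_grm(g)
  SA <- matrix(c(0.5, 0.2, 0.2, 0.3), 2)
  SE <- matrix(c(0.5, -0.1, -0.1, 0.7), 2)
  true_h2 <- sum(diag(SA)) / sum(diag(SA + SE))
  set.seed(32)
  acc_A <- matrix(0, 2, 2)
  h2s <- numeric(400)
  for (r in 1:400) {
    Y <- simulate_traits(K, SA, SE)
    D <- fit_moment_matching(project_out_covariates(Y, K))
    acc_A <- acc_A + D$Sigma_A
    h2s[r] <- D$h2_raw
  }
  expect_equal(as.vector(acc_A / 400), as.vector(SA), tolerance = 0.12)
  expect_lt(abs(mean(h2s) - true_h2), 0.02)
})

test_that("estimator is undefined without genetic-relatedness contrast", {
  K <- genetic_similarity(diag(10))
  Y <- trait_matrix(matrix(rnorm(20), 10), sample_ids = K$sample_ids)
  P <- project_out_covariates(Y, K)
  expect_error(fit_moment_matching(P), "undefined")
})

test_that("reported h2 is clamped while the raw value is retained", {
  set.seed(40)
  dat <- sim_dataset(n = 60, s = 300, m = 1, h2 = 0, seed = 41)
  reps <- lapply(1:40, function(r) {
    Y <- simulate_traits(dat$K, matrix(0), matrix(1))
    fit_moment_matching(project_out_covariates(Y, dat$K))
  })
  raw <- vapply(reps, function(d) d$h2_raw, numeric(1))
  cl <- vapply(reps, function(d) d$h2, numeric(1))
  expect_true(any(raw < 0))
  expect_true(all(cl >= 0 & cl <= 1))
  expect_equal(cl[raw >= 0 & raw <= 1], raw[raw >= 0 & raw <= 1])
})

test_that("analytic variance halves per doubling of independent traits and equals the scalar case under perfect correlation", {
  dat <- sim_dataset(n = 90, s = 500, m = 1, seed = 13)
  P <- project_out_covariates(dat$Y, dat$K)
  D1 <- fit_moment_matching(P)
  # perfectly correlated: replicate the same trait 5 times
  P5c <- P
  P5c$Y <- P$Y[, rep(1, 5)]
  D5c <- fit_moment_matching(P5c)
  expect_equal(D5c$se, D1$se, tolerance = 1e-12)
  expect_equal(D5c$h2_raw, D1$h2_raw, tolerance = 1e-12)
  # the eigenvalue form: for Sigma_P = c I_M the ratio is exactly 1/M
  Dm <- D1
  Dm$Sigma_A <- diag(0.4, 5); Dm$Sigma_E <- diag(0.6, 5)
  Dm$t_A <- 2; Dm$t_E <- 3; Dm$t_P <- 5
  expect_equal(sampling_variance(P, Dm)^2, D1$se^2 *
                 (sum(diag(D1$Sigma_A + D1$Sigma_E))^2 /
                    sum((D1$Sigma_A + D1$Sigma_E)^2)) / 5,
               tolerance = 1e-12)
})

test_that("Monte-Carlo spread of estimates matches the analytic standard error", {
  g <- simulate_genotypes(300, 2000, seed = 61)
  K <- compute_grm(g)
  set.seed(62)
  h2s <- ses <- numeric(300)
  for (r in 1:300) {
    Y <- simulate_traits(K, diag(0.4 / 3, 3), diag(0.6 / 3, 3))
    D <- fit_moment_matching(project_out_covariates(Y, K))
    h2s[r] <- D$h2_raw
    ses[r] <- D$se
  }
  expect_lt(abs(sd(h2s) - mean(ses)) / mean(ses), 0.25)
})

test_that("Lin's concordance correlation coefficient follows its definition", {
  x <- c(1, 2, 3, 4)
  expect_equal(trait_reliability(x, x), 1)
  xc <- x - mean(x)
  expect_equal(trait_reliability(xc, -xc), -1)
  y <- c(1.1, 2.1, 2.9, 4.2)
  vx <- mean((x - mean(x))^2); vy <- mean((y - mean(y))^2)
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  expect_equal(trait_reliability(x, y),
               2 * cxy / (vx + vy + (mean(x) - mean(y))^2),
               tolerance = 1e-12)
  # matrix input averages per-component concordances
  X1 <- cbind(x, x); X2 <- cbind(y, x)
  expect_equal(as.numeric(trait_reliability(X1, X2)),
               mean(c(trait_reliability(x, y), 1)))
  expect_error(trait_reliability(rep(1, 4), rep(1, 4)), "variance")
})
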