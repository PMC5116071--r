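# Independent test oracles, deliberately written with different machinery
# than the package implementation.

# scalar Haseman-Elston estimate by explicit two-regressor OLS on the
# vectorized cross-product matrix {y_i y_j} against {K_ij, delta_ij}
he_ols_oracle <- function(y, K) {
  z <- as.vector(tcrossprod(y))
  k <- as.vector(K)
  d <- as.vector(diag(nrow(K)))
  co <- stats::coef(stats::lm(z ~ 0 + k + d))
  list(sigma_a = unname(co[1]), sigma_e = unname(co[2]),
       h2 = unname(co[1] / (co[1] + co[2])))
}

# multivariate elementwise-regression oracle: per trait pair (r, s),
# regress y_r y_s' entries on (K, I)
he_ols_oracle_multi <- function(Y, K) {
  m <- ncol(Y)
  SA <- SE <- matrix(0, m, m)
  k <- as.vector(K)
  d <- as.vector(diag(nrow(K)))
  for (r in seq_len(m)) for (s in seq_len(m)) {
    z <- as.vector(tcrossprod(Y[, r], Y[, s]))
    co <- stats::coef(stats::lm(z ~ 0 + k + d))
    SA[r, s] <- co[1]; SE[r, s] <- co[2]
  }
  list(Sigma_A = (SA + t(SA)) / 2, Sigma_E = (SE + t(SE)) / 2,
       h2 = sum(diag(SA)) / (sum(diag(SA)) + sum(diag(SE))))
}

# exact HWE probabilities by direct log-factorial enumeration
hwe_enum_oracle <- function(n_aa, n_ab, n_bb, midp = TRUE) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  rare <- min(na, nb)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  pobs <- p[match(n_ab, hs)]
  out <- sum(p[p <= pobs * (1 + 1e-12)])
  if (midp) out <- out - 0.5 * pobs
  max(out, 0)
}

# random orthogonal matrix via QR with sign fix
random_orthogonal <- function(m) {
  qd <- qr(matrix(rnorm(m * m), m))
  Q <- qr.Q(qd)
  Q %*% diag(sign(diag(qr.R(qd))), m)
}

# small simulated unrelated-sample dataset shared across tests
sim_dataset <- function(n = 150, s = 1000, m = 3, h2 = 0.5, seed = 1,
                        Sigma_A = NULL, Sigma_E = NULL) {
  g <- simulate_genotypes(n, s, seed = seed)
  p <- colMeans(g$dosages) / 2
  poly <- p > 0 & p < 1   # small panels can fix an allele by chance
  g <- genotype_matrix(g$dosages[, poly, drop = FALSE], g$sample_ids,
                       g$variants[poly, , drop = FALSE])
  K <- compute_grm(g)
  if (is.null(Sigma_A)) Sigma_A <- diag(h2, m)
  if (is.null(Sigma_E)) Sigma_E <- diag(1 - h2, m)
  Y <- simulate_traits(K, Sigma_A, Sigma_E, seed = seed + 1000L)
  list(g = g, K = K, Y = Y)
}
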