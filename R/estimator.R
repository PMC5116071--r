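#' Project covariates out of traits and genetic similarity
#'
#' Removes fixed-effect covariates from the multivariate variance-component
#' model by rotating the data onto the (N - q)-dimensional null space of
#' the covariates: with `U` any N x (N - q) orthonormal basis satisfying
#' `U'X = 0` and `UU' = P0 = I - X(X'X)^{-1}X'`, the projected data are
#' `Y~ = U'Y` and `K~ = U'KU`. The transformed model has the same
#' variance-component structure, and every downstream estimate is invariant
#' to the particular basis chosen (the estimator depends on U only through
#' `UU'`).
#'
#' @param Y a [trait_matrix()].
#' @param K a [genetic_similarity()].
#' @param X optional [covariate_matrix()]; `NULL` means no projection.
#' @return Object of class `projected_data` with elements `Y` ((N-q) x M),
#'   `K` ((N-q) x (N-q)), `dof` = N - q, `ids` and `trait_names`.
#' @export
project_out_covariates <- function(Y, K, X = NULL) {
  al <- align_samples(Y, K, X)
  n <- nrow(al$Y)
  if (is.null(al$X)) {
    out <- list(Y = al$Y, K = al$K, dof = n, n_samples = n,
                ids = al$ids, trait_names = colnames(al$Y))
    class(out) <- "projected_data"
    return(out)
  }
  q <- ncol(al$X)
  qx <- qr(al$X)
  if (qx$rank < q) stop("covariate matrix is rank deficient")
  U <- qr.Q(qx, complete = TRUE)[, seq.int(q + 1L, n), drop = FALSE]
  Yt <- crossprod(U, al$Y)
  Kt <- crossprod(U, al$K %*% U)
  Kt <- (Kt + t(Kt)) / 2
  out <- list(Y = Yt, K = Kt, dof = n - q, n_samples = n,
              ids = al$ids, trait_names = colnames(al$Y))
  class(out) <- "projected_data"
  out
}

#' @export
print.projected_data <- function(x, ...) {
  cat("projected_data:", x$dof, "effective rows x", ncol(x$Y), "traits",
      "(from", x$n_samples, "samples)\n")
  invisible(x)
}

# trace statistics of a similarity matrix: k_bar = tr[K]/n, kappa =
# tr[K^2]/n, v_K = tr[K^2] - tr[K]^2/n
.k_stats <- function(K) {
  n <- nrow(K)
  k_bar <- sum(diag(K)) / n
  kappa <- sum(K * K) / n
  list(n = n, k_bar = k_bar, kappa = kappa, v_K = n * (kappa - k_bar^2))
}

#' Moment-matching estimator of the genetic and environmental covariance
#'
#' Multivariate Haseman-Elston regression: the empirical cross-product of
#' each trait pair is regressed on the genetic similarity matrix `K` and
#' the identity. The ordinary-least-squares solution has the closed form
#' \deqn{\hat\Sigma_A = Y'(K - \bar k I)Y / v_K, \qquad
#'       \hat\Sigma_E = Y'(\kappa I - \bar k K)Y / v_K,}
#' with \eqn{\bar k = tr[K]/N}, \eqn{\kappa = tr[K^2]/N} and
#' \eqn{v_K = tr[K^2] - tr^2[K]/N}. Heritability is the trace ratio
#' \eqn{\hat h^2 = tr[\hat\Sigma_A] / tr[\hat\Sigma_A + \hat\Sigma_E]},
#' clamped to `[0, 1]` for reporting; the unclamped value is retained for
#' inference. For a single trait this is the classical Haseman-Elston
#' regression estimator.
#'
#' @param P a [project_out_covariates()] result (use `X = NULL` for no
#'   covariates).
#' @return Object of class `covariance_decomposition` with `Sigma_A`,
#'   `Sigma_E`, traces `t_A`, `t_E`, `t_P`, `h2` (clamped), `h2_raw`,
#'   `se`, and the K statistics `k_bar`, `kappa`, `v_K`.
#' @export
fit_moment_matching <- function(P) {
  stopifnot(inherits(P, "projected_data"))
  Y <- P$Y
  K <- P$K
  ks <- .k_stats(K)
  if (ks$v_K / ks$n < 1e-8 * ks$kappa)
    stop("estimator undefined: no genetic-relatedness contrast in K ",
         "(v_K too close to zero)")
  KY <- K %*% Y
  YtY <- crossprod(Y)
  YtKY <- crossprod(Y, KY)
  YtKY <- (YtKY + t(YtKY)) / 2
  Sigma_A <- (YtKY - ks$k_bar * YtY) / ks$v_K
  Sigma_E <- (ks$kappa * YtY - ks$k_bar * YtKY) / ks$v_K
  t_A <- sum(diag(Sigma_A))
  t_E <- sum(diag(Sigma_E))
  t_P <- t_A + t_E
  if (t_P <= 0) stop("total phenotypic variance estimate is not positive")
  h2_raw <- t_A / t_P
  out <- structure(
    list(Sigma_A = Sigma_A, Sigma_E = Sigma_E,
         t_A = t_A, t_E = t_E, t_P = t_P,
         h2 = min(max(h2_raw, 0), 1), h2_raw = h2_raw,
         k_bar = ks$k_bar, kappa = ks$kappa, v_K = ks$v_K,
         n = ks$n, m = ncol(Y), trait_names = P$trait_names),
    class = "covariance_decomposition")
  out$se <- sampling_variance(P, out)
  out
}

#' @export
print.covariance_decomposition <- function(x, ...) {
  cat("Moment-matching covariance decomposition (", x$m, " trait",
      if (x$m > 1) "s", ", ", x$n, " rows)\n", sep = "")
  cat(sprintf("  h2 = %.4f (s.e. %.4f)\n", x$h2, x$se))
  cat(sprintf("  tr[Sigma_A] = %.4g, tr[Sigma_E] = %.4g\n", x$t_A, x$t_E))
  invisible(x)
}

#' Approximate standard error of the trace-ratio heritability estimate
#'
#' Delta-method variance of \eqn{f(t) = t_A / (t_A + t_E)} with the
#' covariance of the trace estimates simplified under two standard
#' approximations for unrelated-sample GRMs: the off-diagonal elements of
#' `K` are small (`K` close to the identity) and the phenotypic covariance
#' is replaced by its empirical estimate. The result is
#' \deqn{var[\hat h^2] \approx \frac{2}{v_K}\,
#'   \frac{tr[\hat\Sigma_P^2]}{tr^2[\hat\Sigma_P]},}
#' which, given `K`, depends only on the sample size and the phenotypic
#' covariance structure. In terms of the eigenvalues \eqn{\lambda_m} of
#' \eqn{\hat\Sigma_P}, the ratio is \eqn{\sum_m \lambda_m^2 /
#' (\sum_m \lambda_m)^2 \le 1}, so a multidimensional trait never has a
#' larger variance than a scalar trait (equality iff the components are
#' perfectly correlated), and M independent equal-variance components
#' reduce the variance by a factor M.
#'
#' @param P a [project_out_covariates()] result.
#' @param D a fitted [fit_moment_matching()] decomposition.
#' @return The standard error (square root of the approximate variance).
#' @export
sampling_variance <- function(P, D) {
  stopifnot(inherits(D, "covariance_decomposition"))
  if (D$t_P <= 0) stop("degenerate decomposition: t_P must be positive")
  Sigma_P <- D$Sigma_A + D$Sigma_E
  ratio <- sum(Sigma_P * Sigma_P) / sum(diag(Sigma_P))^2
  sqrt(2 * ratio / D$v_K)
}

#' Estimate the heritability of a (multidimensional) trait
#'
#' Convenience wrapper chaining [project_out_covariates()],
#' [fit_moment_matching()], the Wald test and (optionally) the
#' permutation test.
#'
#' @param Y a [trait_matrix()].
#' @param K a [genetic_similarity()].
#' @param X optional [covariate_matrix()].
#' @param n_perm number of permutations (0 = skip permutation inference).
#' @param seed RNG seed for the permutation test (required if `n_perm > 0`).
#' @return Object of class `heritability_fit`: the decomposition plus
#'   `p_wald`, and `p_perm`/`n_perm` when permutations were run.
#' @export
estimate_heritability <- function(Y, K, X = NULL, n_perm = 0L, seed = NULL) {
  P <- project_out_covariates(Y, K, X)
  D <- fit_moment_matching(P)
  wt <- wald_test(D$h2_raw, D$se)
  out <- list(decomposition = D, h2 = D$h2, se = D$se,
              statistic = wt$statistic, p_wald = wt$p_wald,
              p_perm = NA_real_, n_perm = 0L)
  if (n_perm > 0L) {
    pt <- permutation_test(P, n_perm = n_perm, seed = seed)
    out$p_perm <- pt$p_perm
    out$n_perm <- pt$n_perm
  }
  class(out) <- "heritability_fit"
  out
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf("h2 = %.4f (s.e. %.4f), Wald p = %.4g", x$h2, x$se, x$p_wald))
  if (x$n_perm > 0L)
    cat(sprintf(", permutation p = %.4g (%d perms)", x$p_perm, x$n_perm))
  cat("\n")
  invisible(x)
}
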