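#' Wald test for heritability against the boundary null
#'
#' Under the null h2 = 0 the parameter lies on the boundary of its space,
#' so the Wald statistic `W = (h2 / se)^2` is distributed as a half-half
#' mixture of a point mass at zero and a chi-square with one degree of
#' freedom. The p-value is `0.5 * P(chi2_1 >= W)` for `W > 0` and 0.5 at
#' `W = 0` (or for negative unclamped estimates).
#'
#' @param h2 point estimate (the unclamped value may be negative).
#' @param se positive standard error.
#' @return List of class `test_result` with `statistic` and `p_wald`.
#' @export
wald_test <- function(h2, se) {
  if (!is.finite(se) || se <= 0) stop("se must be a positive number")
  W <- if (h2 > 0) (h2 / se)^2 else 0
  p <- if (W > 0) 0.5 * pchisq(W, df = 1, lower.tail = FALSE) else 0.5
  structure(list(statistic = W, p_wald = p), class = "test_result")
}

#' Permutation test for heritability
#'
#' Shuffles the rows and columns of the (projected) genetic similarity
#' matrix jointly, keeping the traits fixed, and recomputes the estimate
#' for each permutation. The p-value uses the add-one convention
#' `p = (1 + #\{h2_r >= h2\}) / (n_perm + 1)`, so it is never zero and is
#' super-uniform under the null. Comparisons use the unclamped estimate, so
#' ties at the boundary do not distort the null distribution.
#'
#' @param P a [project_out_covariates()] result.
#' @param n_perm number of permutations (>= 1; 10,000 for publication-grade
#'   p-values).
#' @param seed integer RNG seed; required for reproducibility.
#' @return List of class `test_result` with `p_perm`, `n_perm`, the
#'   observed unclamped estimate `h2_obs` and the permuted values `h2_perm`.
#' @export
permutation_test <- function(P, n_perm = 10000L, seed = NULL) {
  stopifnot(inherits(P, "projected_data"))
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  Y <- P$Y
  K <- P$K
  n <- nrow(Y)
  ks <- .k_stats(K)
  # h2 as a function of tr[Y' K Y]; tr[Y'Y] and the K statistics are
  # permutation invariant
  tYY <- sum(Y * Y)
  h2_of <- function(tYKY) {
    t_A <- (tYKY - ks$k_bar * tYY) / ks$v_K
    t_E <- (ks$kappa * tYY - ks$k_bar * tYKY) / ks$v_K
    t_A / (t_A + t_E)
  }
  h2_obs <- h2_of(sum(Y * (K %*% Y)))
  h2_perm <- vapply(seq_len(n_perm), function(r) {
    pr <- sample.int(n)
    Yp <- Y[pr, , drop = FALSE]
    h2_of(sum(Yp * (K %*% Yp)))
  }, numeric(1))
  p <- (1 + sum(h2_perm >= h2_obs)) / (n_perm + 1)
  structure(list(p_perm = p, n_perm = as.integer(n_perm),
                 h2_obs = h2_obs, h2_perm = h2_perm),
            class = "test_result")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR control across a family of heritability tests.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q target FDR level (default 0.05).
#' @return data.frame with `p`, `q_value` (BH-adjusted) and `significant`.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L)
    return(data.frame(p = numeric(0), q_value = numeric(0),
                      significant = logical(0)))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  qv <- p.adjust(p_values, method = "BH")
  data.frame(p = p_values, q_value = qv, significant = qv <= q)
}
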