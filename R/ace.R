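#' Build a pedigree structure for twin/sibling designs
#'
#' Converts a pedigree table into the expected additive genetic covariance
#' matrix `K = 2 * Phi` and the household-sharing matrix `Lambda`. Kinship
#' follows the standard twin-design coefficients: `phi = 1/2` for MZ twin
#' pairs and `phi = 1/4` for DZ twins and full siblings, so MZ pairs get
#' `K = 1` and all other within-family pairs `K = 0.5`. Members of a family
#' (twins and their non-twin siblings) are assumed to share the same
#' environment: `Lambda = 1` within a family, 0 elsewhere.
#'
#' @param ped data.frame with columns `sample`, `family` and `relation`
#'   (values `"MZ"`, `"DZ"`, `"sib"` or `"singleton"`; the two `"MZ"` (or
#'   `"DZ"`) members of a family are treated as the twin pair). An optional
#'   `household` column overrides the family-based `Lambda`.
#' @return Object of class `pedigree_structure` with `K_ped` (a
#'   [genetic_similarity()], source `"pedigree"`), `Lambda`, `families` and
#'   the input table.
#' @export
pedigree_structure <- function(ped) {
  ped <- as.data.frame(ped)
  need <- c("sample", "family", "relation")
  if (!all(need %in% names(ped)))
    stop("pedigree table needs columns: ", paste(need, collapse = ", "))
  ped$sample <- as.character(ped$sample)
  ped$family <- as.character(ped$family)
  if (anyDuplicated(ped$sample)) stop("duplicate sample IDs in pedigree")
  rel <- as.character(ped$relation)
  if (!all(rel %in% c("MZ", "DZ", "sib", "singleton")))
    stop("relation must be one of MZ, DZ, sib, singleton")
  n <- nrow(ped)
  K <- diag(n)
  Lam <- diag(n)
  for (fam in split(seq_len(n), ped$family)) {
    if (length(fam) < 2L) next
    for (a in seq_along(fam)) {
      for (b in seq_len(a - 1L)) {
        i <- fam[a]; j <- fam[b]
        k <- if (rel[i] == "MZ" && rel[j] == "MZ") 1 else 0.5
        K[i, j] <- K[j, i] <- k
      }
    }
    Lam[fam, fam] <- 1
  }
  if (!is.null(ped$household)) {
    hh <- as.character(ped$household)
    Lam <- outer(hh, hh, "==") * 1
    diag(Lam) <- 1
  }
  dimnames(Lam) <- list(ped$sample, ped$sample)
  structure(list(K_ped = genetic_similarity(K, ped$sample, "pedigree"),
                 Lambda = Lam, families = ped$family, table = ped),
            class = "pedigree_structure")
}

#' @export
print.pedigree_structure <- function(x, ...) {
  cat("pedigree_structure:", nrow(x$table), "samples in",
      length(unique(x$families)), "families\n")
  invisible(x)
}

# Decompose the covariance structure into independent blocks (connected
# components of the combined nonzero pattern of K and Lambda, i.e.
# families) and group blocks with identical (K, Lambda) sub-matrices, so
# each REML likelihood evaluation only factorizes one small matrix per
# distinct family type.
.reml_blocks <- function(K, L) {
  n <- nrow(K)
  pat <- abs(K) + abs(L)
  diag(pat) <- 1
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(pat[v, ] > 1e-12 & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  blocks <- split(seq_len(n), comp)
  key <- vapply(blocks, function(ix)
    paste(length(ix), paste(signif(K[ix, ix], 12), collapse = ","),
          paste(signif(L[ix, ix], 12), collapse = ",")), character(1))
  groups <- lapply(split(blocks, key), function(bl) {
    ix <- bl[[1]]
    list(Kb = K[ix, ix, drop = FALSE], Lb = L[ix, ix, drop = FALSE],
         size = length(ix),
         members = matrix(unlist(bl), nrow = length(ix)))
  })
  unname(groups)
}

# Restricted log-likelihood of y ~ N(X beta, V), V = sA*K + sC*L + sE*I,
# evaluated blockwise on the precomputed group structure.
.reml_ll_blocks <- function(s2, y, X, groups) {
  n <- length(y)
  q <- ncol(X)
  Vi_y <- numeric(n)
  Vi_X <- matrix(0, n, q)
  logdetV <- 0
  for (g in groups) {
    s <- g$size
    Vb <- s2[1] * g$Kb + s2[2] * g$Lb + diag(s2[3], s)
    R <- tryCatch(chol(Vb), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    nf <- ncol(g$members)
    logdetV <- logdetV + nf * 2 * sum(log(diag(R)))
    ix <- as.vector(g$members)
    # stack the family segments of y and X as columns sharing one solve
    rhs <- cbind(matrix(y[ix], nrow = s),
                 matrix(X[ix, , drop = FALSE], nrow = s))
    W <- backsolve(R, forwardsolve(t(R), rhs))
    Vi_y[ix] <- as.vector(W[, seq_len(nf), drop = FALSE])
    Vi_X[ix, ] <- matrix(W[, -seq_len(nf), drop = FALSE], ncol = q)
  }
  XtViX <- crossprod(X, Vi_X)
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(-Inf)
  logdetX <- 2 * sum(log(diag(Rx)))
  beta <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, Vi_y)))
  yPy <- sum(y * Vi_y) - sum(crossprod(Vi_X, y) * beta)
  -0.5 * (logdetV + logdetX + yPy)
}

.reml_ll <- function(s2, y, K, L, X, groups = NULL) {
  if (is.null(groups)) groups <- .reml_blocks(K, L)
  .reml_ll_blocks(s2, y, X, groups)
}

#' Fit a univariate ACE variance-component model by REML
#'
#' Restricted maximum likelihood estimation of
#' `cov[y] = sigma2_A * K_ped + sigma2_C * Lambda + sigma2_E * I` with
#' fixed effects profiled out. The likelihood is maximised on the
#' log-variance scale (which enforces nonnegativity); components driven to
#' the boundary are reported as zero.
#'
#' @param y numeric response vector (complete, length N).
#' @param K_ped N x N expected genetic covariance (matrix or
#'   [genetic_similarity()]).
#' @param Lambda N x N household-sharing matrix.
#' @param X fixed-effect design ([covariate_matrix()] or plain matrix);
#'   defaults to an intercept.
#' @return List of class `ace_fit` with `sigma2` (named A/C/E), `h2`,
#'   `c2`, `loglik`, `converged` and `identifiable`.
#' @export
fit_ace_component <- function(y, K_ped, Lambda = NULL, X = NULL) {
  if (inherits(K_ped, "genetic_similarity")) K_ped <- K_ped$K
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stop("y must be complete")
  if (is.null(Lambda)) Lambda <- matrix(0, n, n)
  if (inherits(X, "covariate_matrix")) X <- X$X
  if (is.null(X)) X <- matrix(1, n, 1)
  if (nrow(K_ped) != n || nrow(Lambda) != n || nrow(X) != n)
    stop("dimension mismatch between y, K_ped, Lambda and X")
  groups <- .reml_blocks(K_ped, Lambda)
  eK <- min(vapply(groups, function(g)
    min(eigen(g$Kb, symmetric = TRUE, only.values = TRUE)$values), numeric(1)))
  eL <- min(vapply(groups, function(g)
    min(eigen(g$Lb, symmetric = TRUE, only.values = TRUE)$values), numeric(1)))
  if (eK < -1e-8 * n || eL < -1e-8 * n)
    stop("K_ped and Lambda must be positive semidefinite")
  use_C <- any(Lambda[upper.tri(Lambda)] != 0)
  # identifiability: A needs relatedness contrast beyond the identity
  offK <- K_ped; diag(offK) <- 0
  identifiable <- max(abs(offK)) > 1e-8
  .fit_ace_core(y, X, groups, use_C, identifiable)
}

# optimize the blockwise restricted likelihood on the log-variance scale
.fit_ace_core <- function(y, X, groups, use_C, identifiable = TRUE) {
  vy <- var(y)
  if (vy <= 0) stop("response has zero variance")
  floor_s2 <- 1e-8 * vy
  nll <- function(theta) {
    s2 <- c(exp(theta[1]), if (use_C) exp(theta[2]) else 0,
            exp(theta[length(theta)]))
    -.reml_ll_blocks(s2, y, X, groups)
  }
  k0 <- log(vy / (2 + use_C))
  init <- if (use_C) c(k0, k0, k0) else c(k0, k0)
  opt <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  theta <- opt$par
  s2 <- c(A = exp(theta[1]),
          C = if (use_C) exp(theta[2]) else 0,
          E = exp(theta[length(theta)]))
  s2[s2 < floor_s2] <- 0
  tot <- sum(s2)
  structure(list(sigma2 = s2, h2 = unname(s2["A"] / tot),
                 c2 = unname(s2["C"] / tot), total_variance = tot,
                 loglik = -opt$value,
                 converged = opt$convergence == 0L && identifiable,
                 identifiable = identifiable, n = length(y)),
            class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("ACE fit (n = %d): A = %.4g, C = %.4g, E = %.4g; h2 = %.3f\n",
              x$n, x$sigma2["A"], x$sigma2["C"], x$sigma2["E"], x$h2))
  if (!x$converged) cat("  (flagged: not converged or not identifiable)\n")
  invisible(x)
}

#' Variance-weighted combination of per-component heritabilities
#'
#' For a multidimensional trait fitted component by component, the overall
#' heritability is the weighted average of component heritabilities with
#' weights proportional to the components' phenotypic variances — the same
#' decomposition that makes the trace-ratio definition a weighted average
#' of its parts.
#'
#' @param fits list of [fit_ace_component()] results (non-converged fits
#'   are dropped).
#' @param Sigma_P_diag optional per-component phenotypic variances; by
#'   default the fitted total variances are used.
#' @return Combined h2 in `[0, 1]`, with the weights in attribute
#'   `"weights"` and the number of fits used in `"n_used"`.
#' @export
combine_components <- function(fits, Sigma_P_diag = NULL) {
  if (inherits(fits, "ace_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no converged component fits to combine")
  fits <- fits[ok]
  if (is.null(Sigma_P_diag))
    Sigma_P_diag <- vapply(fits, function(f) f$total_variance, numeric(1))
  else
    Sigma_P_diag <- Sigma_P_diag[ok]
  if (any(Sigma_P_diag <= 0)) stop("phenotypic variances must be positive")
  w <- Sigma_P_diag / sum(Sigma_P_diag)
  h2 <- sum(w * vapply(fits, function(f) f$h2, numeric(1)))
  structure(min(max(h2, 0), 1), weights = w, n_used = length(fits))
}

#' Fit an ACE model to a multidimensional trait in a familial sample
#'
#' Fits [fit_ace_component()] to every column of `Y`, combines the
#' component heritabilities by [combine_components()], and (optionally)
#' attaches a family-block bootstrap standard error.
#'
#' @param Y a [trait_matrix()] (or plain matrix) aligned with the pedigree.
#' @param pedigree a [pedigree_structure()].
#' @param X optional [covariate_matrix()].
#' @param n_boots bootstrap replicates (0 = no bootstrap; 1,000 for
#'   publication-grade standard errors).
#' @param seed RNG seed for the bootstrap.
#' @return List of class `ace_multifit` with `h2`, `se` (NA if no
#'   bootstrap), per-component `fits`, and bootstrap diagnostics.
#' @export
fit_ace <- function(Y, pedigree, X = NULL, n_boots = 0L, seed = NULL) {
  stopifnot(inherits(pedigree, "pedigree_structure"))
  if (inherits(Y, "trait_matrix")) {
    ids <- pedigree$table$sample
    if (!all(ids %in% Y$sample_ids))
      stop("pedigree samples missing from trait matrix")
    Ym <- Y$Y[ids, , drop = FALSE]
  } else Ym <- as.matrix(Y)
  Xm <- if (inherits(X, "covariate_matrix")) X$X else X
  K <- pedigree$K_ped$K
  Lam <- pedigree$Lambda
  fits <- lapply(seq_len(ncol(Ym)), function(m)
    fit_ace_component(Ym[, m], K, Lam, Xm))
  h2 <- combine_components(fits)
  out <- list(h2 = as.numeric(h2), fits = fits, se = NA_real_,
              n_boots = 0L, n_dropped = 0L,
              weights = attr(h2, "weights"))
  if (n_boots > 0L) {
    bs <- block_bootstrap_se(Ym, pedigree, X = Xm, n_boots = n_boots,
                             seed = seed)
    out$se <- as.numeric(bs)
    out$n_boots <- attr(bs, "n_used")
    out$n_dropped <- attr(bs, "n_dropped")
    out$h2_boot <- attr(bs, "h2_boot")
  }
  class(out) <- "ace_multifit"
  out
}

#' @export
print.ace_multifit <- function(x, ...) {
  cat(sprintf("Familial ACE heritability: h2 = %.4f", x$h2))
  if (x$n_boots > 0L)
    cat(sprintf(" +/- %.4f (%d bootstrap replicates)", x$se, x$n_boots))
  cat("\n")
  invisible(x)
}

#' Family-block bootstrap standard error
#'
#' Families are resampled with replacement (all members of a family move
#' together) to the original family count; the per-component ACE fits and
#' the variance-weighted combination are recomputed on every bootstrap
#' sample, and the standard deviation of the replicate estimates is
#' returned. Replicates in which no component converges are dropped and
#' counted.
#'
#' @param Y matrix of traits (rows in pedigree order).
#' @param pedigree a [pedigree_structure()] with at least 2 families.
#' @param X optional fixed-effect design matrix.
#' @param n_boots number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @return Bootstrap standard error, with attributes `h2_boot`, `n_used`
#'   and `n_dropped`.
#' @export
block_bootstrap_se <- function(Y, pedigree, X = NULL, n_boots = 1000L,
                               seed = NULL) {
  stopifnot(inherits(pedigree, "pedigree_structure"))
  Ym <- if (inherits(Y, "trait_matrix")) Y$Y[pedigree$table$sample, , drop = FALSE]
        else as.matrix(Y)
  if (n_boots < 2L) stop("n_boots must be at least 2")
  fam_ids <- unique(pedigree$families)
  if (length(fam_ids) < 2L)
    stop("block bootstrap requires at least 2 families")
  if (!is.null(seed)) set.seed(seed)
  fam_rows <- split(seq_along(pedigree$families), pedigree$families)[fam_ids]
  K <- pedigree$K_ped$K
  Lam <- pedigree$Lambda
  Xm <- if (inherits(X, "covariate_matrix")) X$X else X
  if (is.null(Xm)) Xm <- matrix(1, nrow(Ym), 1)
  use_C <- any(Lam[upper.tri(Lam)] != 0)
  # resampled families keep their own (K, Lambda) blocks, so the unique
  # block types can be computed once and only the membership changes
  fam_size <- lengths(fam_rows)
  fam_key <- vapply(fam_rows, function(r)
    paste(length(r), paste(signif(K[r, r, drop = FALSE], 12), collapse = ","),
          paste(signif(Lam[r, r, drop = FALSE], 12), collapse = ",")),
    character(1))
  types <- lapply(fam_rows[!duplicated(fam_key)], function(r)
    list(Kb = K[r, r, drop = FALSE], Lb = Lam[r, r, drop = FALSE],
         size = length(r)))
  type_of <- match(fam_key, fam_key[!duplicated(fam_key)])
  h2_boot <- rep(NA_real_, n_boots)
  for (b in seq_len(n_boots)) {
    pick <- sample.int(length(fam_ids), replace = TRUE)
    rows <- unlist(fam_rows[pick], use.names = FALSE)
    offsets <- cumsum(c(0L, fam_size[pick]))
    groups <- lapply(which(tabulate(type_of[pick],
                                    length(types)) > 0L), function(t_) {
      sel <- which(type_of[pick] == t_)
      members <- vapply(sel, function(s)
        offsets[s] + seq_len(fam_size[pick[s]]),
        integer(types[[t_]]$size))
      c(types[[t_]], list(members = matrix(members,
                                           nrow = types[[t_]]$size)))
    })
    Yb <- Ym[rows, , drop = FALSE]
    Xb <- Xm[rows, , drop = FALSE]
    h2_boot[b] <- tryCatch({
      fits <- lapply(seq_len(ncol(Yb)), function(m)
        .fit_ace_core(Yb[, m], Xb, groups, use_C))
      as.numeric(combine_components(fits))
    }, error = function(e) NA_real_)
  }
  used <- h2_boot[is.finite(h2_boot)]
  if (length(used) < 2L) stop("too few converged bootstrap replicates")
  se <- sd(used)
  structure(se, h2_boot = used, n_used = length(used),
            n_dropped = n_boots - length(used))
}
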