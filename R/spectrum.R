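# Linear finite-element discretisation of the Laplace-Beltrami operator on
# a triangle mesh: cotangent stiffness matrix and consistent (linear
# element) mass matrix.
.fem_matrices <- function(mesh, lumped = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p3 - p2  # edge opposite vertex 1
  e2 <- p1 - p3
  e3 <- p2 - p1
  cr <- cbind(e3[, 2] * (-e2[, 3]) - e3[, 3] * (-e2[, 2]),
              e3[, 3] * (-e2[, 1]) - e3[, 1] * (-e2[, 3]),
              e3[, 1] * (-e2[, 2]) - e3[, 2] * (-e2[, 1]))
  area2 <- sqrt(rowSums(cr^2))        # twice the triangle area
  bad <- which(area2 <= .Machine$double.eps * rowSums(e3^2))
  if (length(bad))
    stop("degenerate (zero-area) faces: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...")
  # cotangent at vertex k = dot of adjacent edges / (2 * area)
  cot1 <- rowSums((-e2) * e3) / area2
  cot2 <- rowSums((-e3) * e1) / area2
  cot3 <- rowSums((-e1) * e2) / area2
  # stiffness: off-diagonal -cot/2 on the edge opposite the angle
  ii <- c(f[, 2], f[, 3], f[, 3], f[, 1], f[, 1], f[, 2])
  jj <- c(f[, 3], f[, 2], f[, 1], f[, 3], f[, 2], f[, 1])
  ww <- -0.5 * c(cot1, cot1, cot2, cot2, cot3, cot3)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nv, nv))
  A <- A - Matrix::Diagonal(x = Matrix::colSums(A))
  area <- area2 / 2
  if (lumped) {
    dm <- numeric(nv)
    for (k in 1:3) {
      t_ <- tapply(area / 3, f[, k], sum)
      dm[as.integer(names(t_))] <- dm[as.integer(names(t_))] + t_
    }
    B <- Matrix::Diagonal(x = dm)
  } else {
    mi <- c(f[, 1], f[, 2], f[, 3], ii)
    mj <- c(f[, 1], f[, 2], f[, 3], jj)
    mx <- c(rep(area / 6, 3), rep(area / 12, 6))
    B <- Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(nv, nv))
  }
  list(A = Matrix::forceSymmetric(A), B = Matrix::forceSymmetric(B))
}

# Smallest k eigenpairs of the generalized problem A f = lambda B f with A
# symmetric PSD and B symmetric PD. Dense Cholesky reduction for small
# problems; shift-invert block subspace iteration (sparse Cholesky of
# A + sigma B) for large ones.
.geigen_smallest <- function(A, B, k, tol = 1e-10, max_iter = 400L) {
  n <- nrow(A)
  if (k >= n) stop("requested more modes than vertices")
  if (n <= 700L) {
    R <- chol(as.matrix(B))
    Ri <- backsolve(R, diag(n))
    C <- crossprod(Ri, as.matrix(A) %*% Ri)
    C <- (C + t(C)) / 2
    e <- eigen(C, symmetric = TRUE)
    ord <- seq.int(n, n - k + 1L)
    vals <- e$values[ord]
    vecs <- Ri %*% e$vectors[, ord, drop = FALSE]
    return(list(values = vals, vectors = vecs))
  }
  p <- min(n - 1L, k + max(10L, ceiling(k / 2)))
  sigma <- max(1e-10, 0.5 * (sum(Matrix::diag(A)) / sum(Matrix::diag(B))) *
                 (k / n))
  Ch <- Matrix::Cholesky(A + sigma * B, LDL = FALSE, perm = TRUE)
  # deterministic start independent of the caller's RNG stream
  rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(1L)
  V <- matrix(rnorm(n * p), n, p)
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  vals_old <- rep(Inf, k)
  for (it in seq_len(max_iter)) {
    W <- as.matrix(Matrix::solve(Ch, B %*% V))
    BW <- as.matrix(B %*% W)
    Mw <- crossprod(W, BW)
    Mw <- (Mw + t(Mw)) / 2
    Rw <- tryCatch(chol(Mw), error = function(e) NULL)
    if (is.null(Rw)) {  # rank collapse: re-seed the deficient directions
      V <- W + 1e-8 * matrix(rnorm(n * p), n, p)
      next
    }
    W <- W %*% backsolve(Rw, diag(p))
    H <- crossprod(W, as.matrix(A %*% W))
    H <- (H + t(H)) / 2
    eh <- eigen(H, symmetric = TRUE)
    ord <- seq.int(p, 1L)
    V <- W %*% eh$vectors[, ord, drop = FALSE]
    vals <- eh$values[ord][seq_len(k)]
    if (max(abs(vals - vals_old) / pmax(abs(vals), sigma)) < tol) {
      return(list(values = vals, vectors = V[, seq_len(k), drop = FALSE]))
    }
    vals_old <- vals
  }
  warning("generalized eigensolver reached max_iter without full convergence")
  list(values = vals_old, vectors = V[, seq_len(k), drop = FALSE])
}

#' Truncated Laplace-Beltrami spectrum of a surface mesh
#'
#' Solves the Laplacian eigenvalue problem (Helmholtz equation) on the 2D
#' surface by linear finite elements: cotangent stiffness matrix `A` and
#' consistent linear-element mass matrix `B` (a lumped diagonal mass is
#' available behind a flag), then the smallest `n_modes` solutions of
#' `A f = lambda B f`. Eigenvalues are returned in ascending order; for a
#' closed surface the first eigenvalue is zero (constant eigenfunction).
#' The spectrum is isometry invariant and scales as `1/s^2` when the mesh
#' is scaled by `s`.
#'
#' @param mesh a [triangle_mesh()] with no degenerate faces.
#' @param n_modes number of eigenvalues (< number of vertices).
#' @param lumped use the lumped (diagonal) mass matrix instead of the
#'   consistent one.
#' @return Object of class `lb_spectrum` with `eigenvalues`, `n_modes`,
#'   and `enclosed_volume` (NA for open meshes).
#' @export
compute_spectrum <- function(mesh, n_modes = 51L, lumped = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  mats <- .fem_matrices(mesh, lumped = lumped)
  eg <- .geigen_smallest(mats$A, mats$B, k = n_modes)
  vals <- eg$values
  vals[vals < 0 & vals > -1e-8 * max(abs(vals))] <- 0
  if (any(vals < 0)) stop("negative eigenvalues: mesh is likely degenerate")
  if (is.unsorted(vals)) vals <- sort(vals)
  vol <- if (mesh$closed) mesh_volume(mesh) else NA_real_
  structure(list(eigenvalues = vals, n_modes = as.integer(n_modes),
                 enclosed_volume = vol),
            class = "lb_spectrum")
}

#' @export
print.lb_spectrum <- function(x, ...) {
  cat("lb_spectrum:", x$n_modes, "modes; first eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "),
      "...\n")
  invisible(x)
}
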