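# Synthetic-data generators: genotypes, Kronecker-structured traits, twin
# pedigrees and analytic test meshes. These give every module a
# download-free test surface with known ground truth.

#' Simulate unlinked SNP genotypes
#'
#' Independent biallelic sites with allele frequencies drawn uniformly
#' from `maf_range`; dosages are binomial(2, p) counts, i.e.
#' Hardy-Weinberg genotypes in an unstructured population.
#'
#' @param n_samples,n_snps panel dimensions.
#' @param maf_range length-2 range of minor allele frequencies in (0, 0.5].
#' @param missing_rate fraction of genotypes set missing at random.
#' @param seed RNG seed (set for reproducibility).
#' @return A [genotype_matrix()]; allele frequencies in attribute `"maf"`.
#' @export
simulate_genotypes <- function(n_samples, n_snps,
                               maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = NULL) {
  if (any(maf_range <= 0) || any(maf_range > 0.5))
    stop("maf_range must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  p <- runif(n_snps, maf_range[1], maf_range[2])
  X <- matrix(rbinom(n_samples * n_snps, 2L, rep(p, each = n_samples)),
              n_samples, n_snps)
  if (missing_rate > 0)
    X[runif(length(X)) < missing_rate] <- NA_integer_
  g <- genotype_matrix(X, paste0("S", seq_len(n_samples)))
  attr(g, "maf") <- p
  g
}

# symmetric PSD square root via eigendecomposition; tiny negative
# eigenvalues from finite samples are clipped to zero
.psd_factor <- function(S, label = "matrix") {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop(label, " must be symmetric")
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- e$values
  if (min(v) < -1e-6 * max(abs(v), 1))
    stop(label, " is not positive semidefinite")
  v[v < 0] <- 0
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Simulate multidimensional traits under the variance-component model
#'
#' Draws `Y = G + C + E` with `vec(G) ~ N(0, Sigma_A (x) K)`,
#' `vec(C) ~ N(0, Sigma_C (x) Lambda)` and `vec(E) ~ N(0, Sigma_E (x) I)`,
#' using the matrix-normal factorization `G = L_K Z L_A'` so the NM x NM
#' Kronecker covariance is never assembled. The generative trace-ratio
#' heritability `tr[Sigma_A] / tr[Sigma_A + Sigma_C + Sigma_E]` is recorded
#' in attribute `"true_h2"` (exact when the diagonal of K is 1).
#'
#' @param K a [genetic_similarity()] or N x N PSD matrix.
#' @param Sigma_A,Sigma_E M x M genetic and unique-environment covariance
#'   matrices (scalars accepted for M = 1).
#' @param Sigma_C,Lambda optional shared-environment covariance and
#'   household matrix (both or neither).
#' @param seed RNG seed.
#' @return A [trait_matrix()].
#' @export
simulate_traits <- function(K, Sigma_A, Sigma_E, Sigma_C = NULL,
                            Lambda = NULL, seed = NULL) {
  ids <- if (inherits(K, "genetic_similarity")) K$sample_ids else rownames(K)
  Km <- if (inherits(K, "genetic_similarity")) K$K else as.matrix(K)
  n <- nrow(Km)
  Sigma_A <- as.matrix(Sigma_A)
  Sigma_E <- as.matrix(Sigma_E)
  m <- nrow(Sigma_A)
  if (!all(dim(Sigma_E) == m)) stop("Sigma_A and Sigma_E sizes differ")
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  if (!is.null(seed)) set.seed(seed)
  LK <- .psd_factor(Km, "K")
  LA <- .psd_factor(Sigma_A, "Sigma_A")
  LE <- .psd_factor(Sigma_E, "Sigma_E")
  Y <- LK %*% matrix(rnorm(n * m), n, m) %*% t(LA) +
       matrix(rnorm(n * m), n, m) %*% t(LE)
  t_C <- 0
  if (!is.null(Sigma_C)) {
    if (is.null(Lambda)) stop("Lambda is required with Sigma_C")
    Sigma_C <- as.matrix(Sigma_C)
    LC <- .psd_factor(Sigma_C, "Sigma_C")
    LL <- .psd_factor(as.matrix(Lambda), "Lambda")
    Y <- Y + LL %*% matrix(rnorm(n * m), n, m) %*% t(LC)
    t_C <- sum(diag(Sigma_C))
  }
  out <- trait_matrix(Y, sample_ids = ids)
  attr(out, "true_h2") <- sum(diag(Sigma_A)) /
    (sum(diag(Sigma_A)) + t_C + sum(diag(Sigma_E)))
  out
}

#' Simulate a twin-study pedigree
#'
#' Builds a pedigree table of MZ twin pairs, DZ twin pairs, additional
#' non-twin full siblings of the twins (distributed round-robin over twin
#' families) and singletons, and derives the kinship and household
#' matrices. Defaults reproduce an extended-twin design of 72 MZ pairs,
#' 69 DZ pairs, 253 siblings and 55 singletons.
#'
#' @param n_mz,n_dz numbers of MZ and DZ twin pairs.
#' @param n_sib number of extra full siblings attached to twin families.
#' @param n_singleton number of single-birth individuals without siblings.
#' @return A [pedigree_structure()].
#' @export
simulate_twin_pedigree <- function(n_mz = 72L, n_dz = 69L, n_sib = 253L,
                                   n_singleton = 55L) {
  rows <- list()
  fam <- 0L
  add <- function(relation) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample = sprintf("I%04d", length(rows) + 1L),
      family = sprintf("F%03d", fam), relation = relation,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_mz)) { fam <- fam + 1L; add("MZ"); add("MZ") }
  for (i in seq_len(n_dz)) { fam <- fam + 1L; add("DZ"); add("DZ") }
  ped <- do.call(rbind, rows)
  n_twin_fam <- n_mz + n_dz
  if (n_sib > 0L) {
    if (n_twin_fam == 0L) stop("siblings need twin families to attach to")
    sib_fam <- sprintf("F%03d", rep_len(seq_len(n_twin_fam), n_sib))
    start <- nrow(ped)
    ped <- rbind(ped, data.frame(
      sample = sprintf("I%04d", start + seq_len(n_sib)),
      family = sib_fam, relation = "sib", stringsAsFactors = FALSE))
  }
  if (n_singleton > 0L) {
    start <- nrow(ped)
    ped <- rbind(ped, data.frame(
      sample = sprintf("I%04d", start + seq_len(n_singleton)),
      family = sprintf("F%03d", n_twin_fam + seq_len(n_singleton)),
      relation = "singleton", stringsAsFactors = FALSE))
  }
  ped <- ped[order(ped$family, ped$sample), ]
  rownames(ped) <- NULL
  pedigree_structure(ped)
}

# -- analytic test meshes ----------------------------------------------------

.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

.subdivide_sphere <- function(v, f) {
  # midpoint subdivision with edge cache; new vertices projected to sphere
  env <- new.env(hash = TRUE)
  nv <- nrow(v)
  verts <- vector("list", nrow(f) * 3)
  vmat <- v
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- env[[key]]
    if (!is.null(hit)) return(hit)
    p <- vmat[a, ] + vmat[b, ]
    p <- p / sqrt(sum(p^2))
    vmat <<- rbind(vmat, p)
    env[[key]] <- nrow(vmat)
    nrow(vmat)
  }
  nf <- matrix(0L, nrow(f) * 4, 3)
  for (t_ in seq_len(nrow(f))) {
    a <- f[t_, 1]; b <- f[t_, 2]; c_ <- f[t_, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
    nf[(t_ - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                      c(c_, ca, bc), c(ab, bc, ca))
  }
  list(v = vmat, f = nf)
}

.cube_mesh <- function(scale, refinement) {
  n <- 2L^max(0L, refinement)
  g <- seq(0, 1, length.out = n + 1)
  key <- function(p) paste(round(p[, 1], 9), round(p[, 2], 9),
                           round(p[, 3], 9))
  verts <- matrix(numeric(0), 0, 3)
  vkey <- character(0)
  faces <- matrix(integer(0), 0, 3)
  add_face_grid <- function(corner, du, dv) {
    # grid over a cube face; (du x dv) right-handed for outward normal
    uu <- rep(g, times = n + 1)
    vv <- rep(g, each = n + 1)
    pts <- matrix(corner, (n + 1)^2, 3, byrow = TRUE) +
      outer(uu, du) + outer(vv, dv)
    kk <- key(pts)
    idx <- match(kk, vkey)
    new <- which(is.na(idx))
    if (length(new)) {
      verts <<- rbind(verts, pts[new, , drop = FALSE])
      vkey <<- c(vkey, kk[new])
      idx[new] <- match(kk[new], vkey)
    }
    id <- matrix(idx, n + 1, n + 1)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      a <- id[i, j]; b <- id[i + 1, j]; c_ <- id[i + 1, j + 1]
      d <- id[i, j + 1]
      faces <<- rbind(faces, c(a, b, c_), c(a, c_, d))
    }
  }
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  add_face_grid(c(0, 0, 0), ey, ex)   # z = 0, normal -z
  add_face_grid(c(0, 0, 1), ex, ey)   # z = 1, normal +z
  add_face_grid(c(0, 0, 0), ex, ez)   # y = 0, normal -y
  add_face_grid(c(0, 1, 0), ez, ex)   # y = 1, normal +y
  add_face_grid(c(0, 0, 0), ez, ey)   # x = 0, normal -x
  add_face_grid(c(1, 0, 0), ey, ez)   # x = 1, normal +x
  triangle_mesh(verts * scale, faces)
}

#' Analytic test meshes
#'
#' Watertight meshes with known geometry: an icosphere (icosahedron with
#' `refinement` midpoint subdivisions, `10 * 4^r + 2` vertices), an
#' ellipsoid (icosphere scaled per axis) or a unit cube subdivided into a
#' surface grid. Sphere meshes have a known Laplace spectrum
#' (`l (l + 1) / scale^2` with multiplicity `2l + 1`), making them the
#' reference for spectral accuracy tests.
#'
#' @param shape `"sphere"`, `"ellipsoid"` or `"cube"`.
#' @param scale overall scale (sphere radius / cube edge), default 1.
#' @param refinement subdivision level, default 3.
#' @param axes length-3 semi-axis multipliers for the ellipsoid.
#' @return A closed [triangle_mesh()].
#' @export
make_test_mesh <- function(shape = c("sphere", "ellipsoid", "cube"),
                           scale = 1, refinement = 3L, axes = c(1, 1, 1)) {
  shape <- match.arg(shape)
  if (refinement < 0) stop("refinement must be nonnegative")
  if (shape == "cube") return(.cube_mesh(scale, refinement))
  s <- .icosahedron()
  for (r in seq_len(refinement)) s <- .subdivide_sphere(s$v, s$f)
  v <- s$v * scale
  if (shape == "ellipsoid") v <- sweep(v, 2L, axes, "*")
  triangle_mesh(v, s$f)
}
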