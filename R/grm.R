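#' Construct a genetic similarity object
#'
#' @param K N x N symmetric matrix of pairwise genetic similarities (an
#'   empirical SNP-based GRM, or twice the kinship matrix in pedigrees).
#' @param sample_ids character vector of length N.
#' @param source `"empirical"` or `"pedigree"`.
#' @return An object of class `genetic_similarity`.
#' @export
genetic_similarity <- function(K, sample_ids = rownames(K),
                               source = c("empirical", "pedigree")) {
  K <- as.matrix(K)
  source <- match.arg(source)
  if (nrow(K) != ncol(K)) stop("K must be square")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(K)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(K)) stop("sample_ids must match dim(K)")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("K must be symmetric")
  K <- (K + t(K)) / 2
  if (sum(diag(K)) <= 0) stop("tr[K] must be positive")
  dimnames(K) <- list(sample_ids, sample_ids)
  structure(list(K = K, sample_ids = sample_ids, source = source),
            class = "genetic_similarity")
}

#' @export
print.genetic_similarity <- function(x, ...) {
  cat("genetic_similarity (", x$source, "): ", nrow(x$K), " x ", nrow(x$K),
      ", mean diagonal ", signif(mean(diag(x$K)), 4), "\n", sep = "")
  invisible(x)
}

#' Compute the empirical genetic relationship matrix
#'
#' Allele-frequency-standardized cross-product GRM:
#' \deqn{K_{ij} = \frac{1}{S} \sum_s \frac{(x_{is} - 2p_s)(x_{js} - 2p_s)}
#'   {2 p_s (1 - p_s)}}
#' with \eqn{p_s} the sample allele frequency of variant s. Missing
#' genotypes are mean-imputed per variant before standardization, so they
#' contribute zero to the cross-products.
#'
#' @param g a [genotype_matrix()] with no monomorphic variants.
#' @return A [genetic_similarity()] with `source = "empirical"`.
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$dosages
  if (nrow(X) < 2L) stop("at least two samples are required")
  p <- colMeans(X, na.rm = TRUE) / 2
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("monomorphic or fully missing variants present; run qc_filter first")
  Z <- sweep(X, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  genetic_similarity(K, g$sample_ids, source = "empirical")
}

#' Principal components of a genetic similarity matrix
#'
#' Top eigenvectors of K, conventionally used as covariates to guard
#' against population stratification.
#'
#' @param K a [genetic_similarity()].
#' @param n_pc number of components, `n_pc < N`.
#' @return N x n_pc matrix of unit-norm eigenvectors in descending
#'   eigenvalue order; eigenvalues in attribute `"eigenvalues"`.
#' @export
grm_principal_components <- function(K, n_pc = 10L) {
  stopifnot(inherits(K, "genetic_similarity"))
  n <- nrow(K$K)
  if (n_pc >= n) stop("n_pc must be smaller than the number of samples")
  e <- eigen(K$K, symmetric = TRUE)
  V <- e$vectors[, seq_len(n_pc), drop = FALSE]
  rownames(V) <- K$sample_ids
  colnames(V) <- paste0("PC", seq_len(n_pc))
  attr(V, "eigenvalues") <- e$values[seq_len(n_pc)]
  V
}

# lower-triangle (row-major, diagonal included) pair indices, GCTA order
.grm_pair_index <- function(n) {
  i <- rep.int(seq_len(n), seq_len(n))
  j <- sequence(seq_len(n))
  cbind(i, j)
}

#' Read / write genetic similarity matrices
#'
#' `write_grm()` and `read_grm()` use the GCTA binary GRM dialect: `prefix
#' .grm.bin` stores the lower triangle (diagonal included, row-major) as
#' little-endian float32, `prefix.grm.id` the FID/IID pairs, and
#' `prefix.grm.N.bin` (optional) per-pair variant counts. A plain-text
#' square matrix with an ID column is supported through
#' `read_grm_text()` / `write_grm_text()`.
#'
#' @param K a [genetic_similarity()].
#' @param prefix file prefix (without `.grm.bin`).
#' @param n_snps optional variant count (scalar or per-pair) to store in
#'   `.grm.N.bin`.
#' @return `read_grm()` returns a [genetic_similarity()]; writers return
#'   the prefix/path invisibly.
#' @export
write_grm <- function(K, prefix, n_snps = NULL) {
  stopifnot(inherits(K, "genetic_similarity"))
  n <- nrow(K$K)
  idx <- .grm_pair_index(n)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(K$K[idx]), con, size = 4L, endian = "little")
  write.table(data.frame(K$sample_ids, K$sample_ids),
              paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(n_snps)) {
    conN <- file(paste0(prefix, ".grm.N.bin"), "wb")
    on.exit(close(conN), add = TRUE)
    writeBin(as.numeric(rep_len(n_snps, nrow(idx))), conN, size = 4L,
             endian = "little")
  }
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    colClasses = "character")
  n <- nrow(ids)
  n_pair <- n * (n + 1) / 2
  path <- paste0(prefix, ".grm.bin")
  n_stored <- file.size(path) / 4
  if (n_stored != n_pair)
    stop(sprintf("%s holds %d values but %s lists %d samples (%d expected)",
                 path, n_stored, paste0(prefix, ".grm.id"), n, n_pair))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, "numeric", n = n_pair, size = 4L, endian = "little")
  K <- matrix(0, n, n)
  idx <- .grm_pair_index(n)
  K[idx] <- v
  K[idx[, c(2, 1)]] <- v
  genetic_similarity(K, ids[[2]], source = "empirical")
}

#' @rdname write_grm
#' @param path text file path; first column sample ID, remaining columns the
#'   square matrix, whitespace or comma delimited, no header.
#' @export
read_grm_text <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- read.table(path, header = FALSE, sep = sep,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  K <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(K) <- "double"
  if (nrow(K) != ncol(K)) stop("matrix in ", path, " is not square")
  genetic_similarity(K, ids, source = "empirical")
}

#' @rdname write_grm
#' @export
write_grm_text <- function(K, path) {
  stopifnot(inherits(K, "genetic_similarity"))
  out <- data.frame(id = K$sample_ids, K$K, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
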