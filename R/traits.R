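#' Construct a trait matrix
#'
#' N x M phenotype container. Rows with any missing value are dropped
#' listwise (the variance-component model has no missingness mechanism).
#'
#' @param Y numeric matrix or data.frame, N x M.
#' @param sample_ids character vector of length N.
#' @param trait_names optional column names.
#' @return Object of class `trait_matrix`.
#' @export
trait_matrix <- function(Y, sample_ids = rownames(Y), trait_names = colnames(Y)) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(Y)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample IDs must be unique")
  if (length(sample_ids) != nrow(Y)) stop("sample_ids must match rows of Y")
  keep <- rowSums(!is.finite(Y)) == 0L
  if (!all(keep)) {
    Y <- Y[keep, , drop = FALSE]
    sample_ids <- sample_ids[keep]
  }
  if (nrow(Y) < 3L) stop("at least 3 complete samples are required")
  if (is.null(trait_names)) trait_names <- paste0("t", seq_len(ncol(Y)))
  dimnames(Y) <- list(sample_ids, trait_names)
  structure(list(Y = Y, sample_ids = sample_ids, trait_names = trait_names),
            class = "trait_matrix")
}

#' Construct a covariate matrix
#'
#' @param X numeric matrix or data.frame of covariates (no intercept
#'   needed; one is prepended unless `add_intercept = FALSE`).
#' @param sample_ids character vector of length N.
#' @param add_intercept prepend a column of ones (default `TRUE`).
#' @return Object of class `covariate_matrix` with full-column-rank `X`.
#' @export
covariate_matrix <- function(X, sample_ids = rownames(X), add_intercept = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X)) stop("sample_ids must match rows of X")
  if (ncol(X) > 0L && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (add_intercept) X <- cbind(intercept = 1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (ncol(X) >= nrow(X) - 1L)
    stop("too many covariates: q must be < N - 1")
  rownames(X) <- sample_ids
  structure(list(X = X, sample_ids = sample_ids), class = "covariate_matrix")
}

# Align trait, similarity and covariate objects on common sample IDs
# (in trait-matrix order). Returns plain matrices.
align_samples <- function(Y, K, X = NULL) {
  stopifnot(inherits(Y, "trait_matrix"), inherits(K, "genetic_similarity"))
  ids <- intersect(Y$sample_ids, K$sample_ids)
  if (!is.null(X)) {
    stopifnot(inherits(X, "covariate_matrix"))
    ids <- intersect(ids, X$sample_ids)
  }
  if (length(ids) < 3L) stop("fewer than 3 samples shared across inputs")
  list(Y = Y$Y[ids, , drop = FALSE],
       K = K$K[ids, ids],
       X = if (is.null(X)) NULL else X$X[ids, , drop = FALSE],
       ids = ids)
}

#' Read a phenotype or covariate table
#'
#' Delimited text with a header row; the first column is the sample ID and
#' remaining columns are numeric. Whitespace-, tab- or comma-delimited
#' files are detected automatically.
#'
#' @param path file path.
#' @return For `read_phenotypes()` a [trait_matrix()]; for
#'   `read_covariates()` a [covariate_matrix()] (intercept added).
#' @export
read_phenotypes <- function(path) {
  tab <- .read_id_table(path)
  trait_matrix(as.matrix(tab[-1]), sample_ids = tab[[1]])
}

#' @rdname read_phenotypes
#' @export
read_covariates <- function(path) {
  tab <- .read_id_table(path)
  covariate_matrix(as.matrix(tab[-1]), sample_ids = tab[[1]])
}

.read_id_table <- function(path) {
  first <- readLines(path, n = 2L)
  first <- first[!startsWith(first, "#")]
  sep <- if (grepl(",", first[1], fixed = TRUE)) "," else ""
  tab <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  tab[[1]] <- as.character(tab[[1]])
  if (anyDuplicated(tab[[1]])) stop("duplicate sample IDs in ", path)
  tab
}

#' Lin's concordance correlation coefficient
#'
#' Test-retest agreement of a measurement:
#' \deqn{CCC = \frac{2\,cov(x, y)}{var(x) + var(y) + (\bar x - \bar y)^2}}
#' with population (1/n) moments. For multi-column input the average CCC
#' across components is returned, the conventional summary for
#' multidimensional descriptors.
#'
#' @param y_test,y_retest numeric vectors or matrices of equal dimension.
#' @return Concordance in `[-1, 1]` (per-component values in attribute
#'   `"components"` for matrix input).
#' @export
trait_reliability <- function(y_test, y_retest) {
  x <- as.matrix(y_test)
  y <- as.matrix(y_retest)
  if (!all(dim(x) == dim(y))) stop("test and retest dimensions differ")
  if (nrow(x) < 3L) stop("at least 3 paired observations are required")
  ccc1 <- function(a, b) {
    n <- length(a)
    va <- mean((a - mean(a))^2)
    vb <- mean((b - mean(b))^2)
    cab <- mean((a - mean(a)) * (b - mean(b)))
    denom <- va + vb + (mean(a) - mean(b))^2
    if (denom <= 0) stop("zero total variance; concordance undefined")
    2 * cab / denom
  }
  comp <- vapply(seq_len(ncol(x)), function(j) ccc1(x[, j], y[, j]),
                 numeric(1))
  out <- mean(comp)
  if (ncol(x) > 1L) attr(out, "components") <- comp
  out
}
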