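#' Construct a genotype matrix
#'
#' Container for biallelic SNP genotypes coded as minor-allele dosages.
#'
#' @param dosages N x S numeric matrix of allele counts in \{0, 1, 2\};
#'   missing genotypes as `NA`.
#' @param sample_ids character vector of length N, unique.
#' @param variants optional data.frame with one row per variant (columns
#'   `id`, `chrom`, `pos`, `a1`, `a2`); a minimal frame is synthesised when
#'   omitted.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            variants = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample IDs must be unique")
  if (length(sample_ids) != nrow(dosages))
    stop("length of sample_ids does not match rows of dosages")
  if (ncol(dosages) < 1L) stop("at least one variant is required")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  if (is.null(variants)) {
    variants <- data.frame(id = paste0("snp", seq_len(ncol(dosages))),
                           chrom = 1L, pos = seq_len(ncol(dosages)),
                           a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }
  if (nrow(variants) != ncol(dosages))
    stop("variants table does not match number of dosage columns")
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  nm <- sum(is.na(x$dosages))
  if (nm > 0) cat("  missing genotypes:", nm, "\n")
  invisible(x)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test of Hardy-Weinberg proportions from genotype counts, using the
#' conditional distribution of the heterozygote count given the minor allele
#' count (Wigginton-style recurrence). The mid-p variant, which subtracts
#' half the probability of the observed configuration, is the default; it is
#' better calibrated at low minor-allele counts.
#'
#' @param n_aa,n_ab,n_bb counts of the three genotype classes (hom, het, hom).
#' @param midp use the mid-p correction (default `TRUE`).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb, midp = TRUE) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be nonnegative")
  n <- n_aa + n_ab + n_bb
  if (n == 0L) stop("no genotype observations")
  # orient to the rarer allele
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)
  h_obs <- n_ab
  # possible het counts share the parity of the rare allele count
  h_vals <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(h_vals))
  # start at the mode-ish midpoint and recurse both ways
  h_mid <- round(rare * (2 * n - rare) / (2 * n))
  if (h_mid %% 2L != rare %% 2L) h_mid <- h_mid + 1L
  h_mid <- min(max(h_mid, rare %% 2L), rare)
  i_mid <- match(h_mid, h_vals)
  probs[i_mid] <- 1
  # downward: P(h-2) = P(h) * h (h-1) / (4 (homr+1)(homc+1))
  h <- h_mid
  homr <- (rare - h) / 2
  homc <- n - h - homr
  i <- i_mid
  while (h >= 2) {
    probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (homr + 1) * (homc + 1))
    h <- h - 2L; i <- i - 1L
    homr <- homr + 1; homc <- homc + 1
  }
  # upward: P(h+2) = P(h) * 4 homr homc / ((h+2)(h+1))
  h <- h_mid
  homr <- (rare - h) / 2
  homc <- n - h - homr
  i <- i_mid
  while (h <= rare - 2L) {
    probs[i + 1L] <- probs[i] * 4 * homr * homc / ((h + 2) * (h + 1))
    h <- h + 2L; i <- i + 1L
    homr <- homr - 1; homc <- homc - 1
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(h_obs, h_vals)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  if (midp) p <- p - 0.5 * p_obs
  min(max(p, .Machine$double.xmin), 1)
}

#' Variant quality-control filter
#'
#' Removes variants failing any of three standard filters: genotype call
#' rate, minor allele frequency and an exact Hardy-Weinberg equilibrium
#' test. The sample set is unchanged.
#'
#' @param g a [genotype_matrix()].
#' @param call_rate_min minimum fraction of non-missing genotypes per
#'   variant (default 0.97).
#' @param maf_min minimum minor allele frequency (default 0.01; monomorphic
#'   variants always fail).
#' @param hwe_p_min minimum HWE exact mid-p value (default 1e-6).
#' @return A filtered `genotype_matrix`; the set of kept variant ids is
#'   recorded in attribute `"kept"`.
#' @export
qc_filter <- function(g, call_rate_min = 0.97, maf_min = 0.01,
                      hwe_p_min = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  thr <- c(call_rate_min, maf_min, hwe_p_min)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  X <- g$dosages
  n_obs <- colSums(!is.na(X))
  call_rate <- n_obs / nrow(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[n_obs == 0L] <- 0
  hwe_p <- vapply(seq_len(ncol(X)), function(s) {
    xs <- X[, s]
    n2 <- sum(xs == 2, na.rm = TRUE)
    n1 <- sum(xs == 1, na.rm = TRUE)
    n0 <- sum(xs == 0, na.rm = TRUE)
    if (n0 + n1 + n2 == 0L) return(0)
    hwe_exact_test(n2, n1, n0)
  }, numeric(1))
  keep <- call_rate >= call_rate_min & maf >= maf_min & hwe_p >= hwe_p_min
  if (!any(keep))
    stop("no variants pass the quality-control filters")
  out <- genotype_matrix(X[, keep, drop = FALSE], g$sample_ids,
                         g$variants[keep, , drop = FALSE])
  attr(out, "kept") <- g$variants$id[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}
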