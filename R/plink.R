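# PLINK 1 binary (bed/bim/fam) input/output.
#
# The .bed file is SNP-major: magic bytes 0x6c 0x1b 0x01, then ceil(N/4)
# bytes per variant, two bits per sample, least-significant pair first:
#   00 = homozygous A1 (dosage 2), 01 = missing, 10 = het, 11 = hom A2 (0).

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))
.bed_code_to_dosage <- c(2L, NA_integer_, 1L, 0L)      # code 0..3
.bed_dosage_to_code <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  code
}

#' Read / write PLINK 1 binary genotype files
#'
#' `read_plink()` reads `prefix.bed/.bim/.fam` into a [genotype_matrix()]
#' with dosages counting the A1 allele; `write_plink()` is its inverse.
#'
#' @param prefix path prefix of the fileset.
#' @return `read_plink()` returns a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  n <- nrow(fam)
  s <- nrow(bim)
  nb <- ceiling(n / 4)
  bed_path <- paste0(prefix, ".bed")
  con <- file(bed_path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", n = 3L)
  if (!identical(magic, .bed_magic))
    stop(bed_path, " is not a SNP-major PLINK 1 .bed file")
  body <- readBin(con, "raw", n = nb * s)
  if (length(body) != nb * s)
    stop(bed_path, " is truncated: expected ", nb * s, " genotype bytes")
  bytes <- as.integer(body)
  D <- matrix(NA_integer_, n, s)
  for (k in 0:3) {
    rows <- seq.int(k + 1L, n, by = 4L)
    if (length(rows) == 0L) next
    codes <- bitwAnd(bitwShiftR(bytes, 2L * k), 3L)
    cm <- matrix(codes, nb, s)
    D[rows, ] <- .bed_code_to_dosage[cm[seq_along(rows), , drop = FALSE] + 1L]
  }
  variants <- data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                         a1 = bim$a1, a2 = bim$a2, stringsAsFactors = FALSE)
  genotype_matrix(D, fam[[2]], variants)
}

#' @rdname read_plink
#' @param g a [genotype_matrix()].
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$dosages
  n <- nrow(X)
  s <- ncol(X)
  nb <- ceiling(n / 4)
  v <- g$variants
  bim <- data.frame(chrom = v$chrom, id = v$id, cm = 0, pos = v$pos,
                    a1 = v$a1, a2 = v$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = g$sample_ids, iid = g$sample_ids, pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # pack: pad samples to a multiple of 4 with missing code 01
  codes <- matrix(1L, nb * 4L, s)
  codes[seq_len(n), ] <- matrix(.bed_dosage_to_code(X), n, s)
  k0 <- codes[seq.int(1L, nb * 4L, 4L), , drop = FALSE]
  k1 <- codes[seq.int(2L, nb * 4L, 4L), , drop = FALSE]
  k2 <- codes[seq.int(3L, nb * 4L, 4L), , drop = FALSE]
  k3 <- codes[seq.int(4L, nb * 4L, 4L), , drop = FALSE]
  bytes <- k0 + bitwShiftL(k1, 2L) + bitwShiftL(k2, 4L) + bitwShiftL(k3, 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(.bed_magic, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
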