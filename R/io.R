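#' Read a PLINK 1 binary fileset
#'
#' Reads \code{prefix.bed} / \code{.bim} / \code{.fam} into the packed
#' [genotype_matrix()] container.  Only SNP-major bed files are supported
#' (the PLINK 1.9 default).  Genotypes are counts of the bim A1 allele.
#' Missing calls are imputed to the rounded per-SNP mean genotype (so the
#' \{0,1,2\} alphabet — required by the finite-alphabet multiplications — is
#' preserved); the number of imputed calls is reported with a warning, as is
#' any SNP with no observed calls at all (imputed to 0).
#'
#' @param prefix path prefix of the fileset (no extension).
#' @param verbose report dimensions and imputation counts (default TRUE).
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix, verbose = TRUE) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)

  bim <- read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(bim); n <- nrow(fam)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported: ", bed_path)
  expected <- 3 + as.numeric(m) * ((n + 3) %/% 4)
  if (length(raw) != expected)
    stop(sprintf("bed file has %d bytes; expected %d for %d SNPs x %d samples (bim/fam mismatch or truncation)",
                 length(raw), expected, m, n))

  dec <- cpp_bed_to_packed(raw[-(1:3)], m, n)
  if (dec$n_imputed > 0)
    warning(sprintf("%d missing genotype call(s) imputed to the rounded per-SNP mean%s",
                    dec$n_imputed,
                    if (dec$n_all_missing > 0)
                      sprintf(" (%d SNP(s) had no observed calls and were imputed to 0)", dec$n_all_missing)
                    else ""))
  if (verbose)
    message(sprintf("read %d SNPs x %d individuals from %s (%d call(s) imputed)",
                    m, n, bed_path, dec$n_imputed))
  new_genotype_matrix(dec$packed, m, n,
                      snp_ids = bim[[2]], sample_ids = as.character(fam[[2]]),
                      a1 = bim[[5]], a2 = bim[[6]],
                      chr = bim[[1]], pos = bim[[4]])
}

#' Write a PLINK 1 binary fileset
#'
#' Writes \code{prefix.bed} (SNP-major, bit-exact round trip with
#' [read_plink()]), \code{.bim} and \code{.fam}.  Chromosome and position
#' default to 1 and the row index when the object does not carry them.
#'
#' @param x a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(x, prefix) {
  stopifnot(inherits(x, "genotype_matrix"))
  bim <- data.frame(chr = if (!is.null(x$chr)) x$chr else rep("1", x$m),
                    id = x$snp_ids, cm = 0,
                    pos = if (!is.null(x$pos)) x$pos else seq_len(x$m),
                    a1 = x$a1, a2 = x$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = x$sample_ids, iid = x$sample_ids,
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(cpp_packed_to_bed(x$packed, x$m, x$n), con)
  invisible(prefix)
}

#' Read and write whitespace-delimited factor matrices
#'
#' Text layouts follow the ADMIXTURE convention: a Q file has n rows x k
#' columns (one individual per line), a P file has m rows x k columns (one
#' SNP per line), both printed to six decimals.  Internally Q is k x n, so
#' the Q writer/reader transpose.
#'
#' @param Q internal k x n admixture matrix.
#' @param P m x k frequency matrix.
#' @param path file path.
#' @return readers return the matrix (k x n for Q, m x k for P); writers
#'   return \code{path} invisibly.
#' @export
write_q_matrix <- function(Q, path) {
  write_num_matrix(t(as.matrix(Q)), path)
}

#' @rdname write_q_matrix
#' @export
read_q_matrix <- function(path) t(read_num_matrix(path))

#' @rdname write_q_matrix
#' @export
write_p_matrix <- function(P, path) write_num_matrix(as.matrix(P), path)

#' @rdname write_q_matrix
#' @export
read_p_matrix <- function(path) read_num_matrix(path)

write_num_matrix <- function(M, path) {
  if (any(!is.finite(M))) stop("refusing to write non-finite values to ", path)
  txt <- apply(format(M, nsmall = 6, digits = 6, scientific = FALSE, trim = TRUE),
               1, paste, collapse = " ")
  writeLines(txt, path)
  invisible(path)
}

read_num_matrix <- function(path) {
  as.matrix(read.table(path, header = FALSE))
}

#' Read a reference allele-frequency panel
#'
#' Tab-separated file with header \code{SNP A1 A2 <pop1> <pop2> ...}; each
#' frequency column gives the A1-allele frequency of the SNP in one
#' reference population.
#'
#' @param path panel file path.
#' @return An object of class \code{"ref_panel"}: list with \code{snp_ids},
#'   \code{a1}, \code{a2}, \code{freqs} (SNP x population matrix) and
#'   \code{populations}.
#' @export
read_panel <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (ncol(tab) < 4L || !identical(toupper(names(tab)[1:3]), c("SNP", "A1", "A2")))
    stop("panel must be a TSV with header 'SNP A1 A2 <pop...>': ", path)
  if (anyDuplicated(tab[[1]])) stop("panel SNP ids are not unique: ", path)
  freqs <- as.matrix(tab[, -(1:3), drop = FALSE])
  storage.mode(freqs) <- "double"
  if (anyNA(freqs) || min(freqs) < 0 || max(freqs) > 1)
    stop("panel frequencies must lie in [0, 1]: ", path)
  rownames(freqs) <- tab[[1]]
  structure(list(snp_ids = tab[[1]], a1 = tab[[2]], a2 = tab[[3]],
                 freqs = freqs, populations = colnames(freqs)),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("Reference frequency panel: %d SNPs x %d populations (%s)\n",
              length(x$snp_ids), length(x$populations),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}

#' Write a frequency matrix as a reference panel
#'
#' Inverse of [read_panel()]: writes SNP ids, alleles and per-population A1
#' frequencies as a TSV usable for supervised fitting.
#'
#' @param P m x k frequency matrix with SNP rownames (or aligned to
#'   \code{x}).
#' @param x the [genotype_matrix()] supplying SNP ids and alleles.
#' @param path output path.
#' @export
write_panel <- function(P, x, path) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == x$m)
  pops <- if (!is.null(colnames(P))) colnames(P) else paste0("pop", seq_len(ncol(P)))
  tab <- data.frame(SNP = x$snp_ids, A1 = x$a1, A2 = x$a2,
                    round(P, 6), check.names = FALSE)
  names(tab)[-(1:3)] <- pops
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonise a reference panel with a genotype matrix
#'
#' Intersects the panel with the data on SNP id; where the panel's counted
#' allele (A1) is the data's A2 (and vice versa) the frequency is flipped to
#' \code{1 - p}; SNPs whose allele pairs are incompatible are dropped and
#' counted.  No strand flipping is attempted: A/T and C/G ambiguity must be
#' resolved upstream.
#'
#' @param panel a [read_panel()] object.
#' @param x a [genotype_matrix()].
#' @return list with \code{P} (frequencies ordered as the retained rows of
#'   \code{x}), \code{rows} (row indices into \code{x}), \code{n_flipped},
#'   \code{n_dropped}.
#' @export
align_panel <- function(panel, x) {
  stopifnot(inherits(panel, "ref_panel"), inherits(x, "genotype_matrix"))
  idx <- match(x$snp_ids, panel$snp_ids)
  present <- which(!is.na(idx))
  if (!length(present)) stop("no SNPs shared between panel and genotype data")
  pi <- idx[present]
  same <- panel$a1[pi] == x$a1[present] & panel$a2[pi] == x$a2[present]
  swap <- panel$a1[pi] == x$a2[present] & panel$a2[pi] == x$a1[present] & !same
  keep <- same | swap
  n_dropped <- sum(!keep) + (x$m - length(present))
  rows <- present[keep]
  if (!length(rows)) stop("no SNPs shared between panel and genotype data after allele matching")
  P <- panel$freqs[pi[keep], , drop = FALSE]
  P[swap[keep], ] <- 1 - P[swap[keep], , drop = FALSE]
  rownames(P) <- x$snp_ids[rows]
  list(P = P, rows = rows, n_flipped = sum(swap), n_dropped = n_dropped)
}
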