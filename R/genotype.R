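#' Packed genotype matrix
#'
#' Construct the package's genotype container: m SNPs x n diploid individuals
#' with calls in \{0, 1, 2\} (counts of the A1 allele), stored packed at 2
#' bits per call.  All downstream computation (heterozygosity diagonal,
#' matrix-free operator products, alternating least squares) works directly
#' on the packed storage; the dense matrix is only materialised on explicit
#' request via [as.matrix()].
#'
#' @param x integer (or numeric) matrix with entries in \{0, 1, 2\}; rows are
#'   SNPs, columns are individuals.
#' @param snp_ids character vector of SNP identifiers (default
#'   \code{"snp1"..."snpm"}, or rownames of \code{x}).
#' @param sample_ids character vector of sample identifiers (default
#'   \code{"ind1"..."indn"}, or colnames of \code{x}).
#' @param a1,a2 allele labels per SNP (defaults \code{"A"} / \code{"B"});
#'   genotypes count copies of \code{a1}.
#' @return An object of class \code{"genotype_matrix"}.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L, 0L, 2L), nrow = 3))
#' dim(g)
#' as.matrix(g)
#' @export
genotype_matrix <- function(x, snp_ids = NULL, sample_ids = NULL,
                            a1 = NULL, a2 = NULL) {
  if (!is.matrix(x)) stop("'x' must be a matrix")
  if (is.double(x)) {
    if (any(x != round(x))) stop("genotypes must be integers in {0,1,2}")
    storage.mode(x) <- "integer"
  }
  if (anyNA(x)) stop("genotypes must not contain NA; impute before packing")
  m <- nrow(x); n <- ncol(x)
  if (m < 1L || n < 1L) stop("genotype matrix must have at least one SNP and one sample")
  if (is.null(snp_ids)) snp_ids <- if (!is.null(rownames(x))) rownames(x) else paste0("snp", seq_len(m))
  if (is.null(sample_ids)) sample_ids <- if (!is.null(colnames(x))) colnames(x) else paste0("ind", seq_len(n))
  new_genotype_matrix(cpp_pack(x), m, n, snp_ids, sample_ids, a1, a2)
}

# Internal constructor from already-packed storage.
new_genotype_matrix <- function(packed, m, n, snp_ids, sample_ids,
                                a1 = NULL, a2 = NULL,
                                chr = NULL, pos = NULL) {
  stopifnot(length(snp_ids) == m, length(sample_ids) == n)
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("B", m)
  structure(
    list(packed = packed, m = as.integer(m), n = as.integer(n),
         snp_ids = as.character(snp_ids),
         sample_ids = as.character(sample_ids),
         a1 = as.character(a1), a2 = as.character(a2),
         chr = chr, pos = pos,
         cache = new.env(parent = emptyenv())),
    class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) c(x$m, x$n)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Packed genotype matrix: %d SNPs x %d individuals (%.1f KB)\n",
              x$m, x$n, length(x$packed) / 1024))
  het <- het_diagonal(x)
  cat(sprintf("Mean per-individual heterozygosity: %.4f\n", mean(het)))
  invisible(x)
}

#' @export
as.matrix.genotype_matrix <- function(x, ...) {
  out <- cpp_unpack(x$packed, x$m, x$n)
  dimnames(out) <- list(x$snp_ids, x$sample_ids)
  out
}

#' Subset a genotype matrix
#'
#' Row (SNP) and column (individual) subsetting; indices follow the usual
#' matrix conventions.  Returns a new packed object.
#' @param x a [genotype_matrix()].
#' @param i,j SNP and sample indices (numeric, logical, or character ids).
#' @param ... ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(x$m)
  if (missing(j)) j <- seq_len(x$n)
  if (is.character(i)) i <- match(i, x$snp_ids)
  if (is.character(j)) j <- match(j, x$sample_ids)
  i <- seq_len(x$m)[i]
  j <- seq_len(x$n)[j]
  if (anyNA(i) || anyNA(j)) stop("subscript out of bounds")
  dense <- cpp_unpack(x$packed, x$m, x$n)[i, j, drop = FALSE]
  new_genotype_matrix(cpp_pack(dense), length(i), length(j),
                      x$snp_ids[i], x$sample_ids[j],
                      x$a1[i], x$a2[i],
                      if (!is.null(x$chr)) x$chr[i], if (!is.null(x$pos)) x$pos[i])
}

#' Heterozygosity diagonal of the latent-subspace operator
#'
#' The operator whose top eigenvectors span the admixture row space is
#' \code{G = (1/m) X'X - D}, where \code{D} is diagonal with
#' \code{d_j = (1/m) sum_i (2 x_ij - x_ij^2)}.  Since \code{2x - x^2} is 1
#' for a heterozygote and 0 for either homozygote, \code{d_j} is the fraction
#' of heterozygous calls in column j.
#'
#' @param x a [genotype_matrix()].
#' @return numeric vector of length n with entries in \code{[0, 1]}.
#' @export
het_diagonal <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  cpp_het_counts(x$packed, x$m, x$n) / x$m
}

# Mailman segmentation plan, built once per object and cached.  Rows are
# grouped into segments of d = ceiling(log3 n) rows whose columns are encoded
# as base-3 numbers; tiny matrices (m or n < 27) skip the encoding and every
# product falls through to the naive packed multiply.
mailman_plan <- function(x) {
  cache <- x$cache
  if (!is.null(cache$plan)) return(cache$plan)
  m <- x$m; n <- x$n
  if (m < 27L || n < 27L) {
    plan <- list(d = 1L, nseg = 0L, codes = integer(0))
  } else {
    d <- as.integer(ceiling(log(n) / log(3) - 1e-12))
    while (3^d < n) d <- d + 1L
    nseg <- m %/% d
    plan <- list(d = d, nseg = nseg,
                 codes = cpp_mailman_codes(x$packed, m, n, d, nseg))
  }
  cache$plan <- plan
  plan
}

#' Matrix-free genotype products
#'
#' Multiply the packed genotype matrix (or its transpose) with a dense
#' vector using the Mailman finite-alphabet algorithm: after a one-time
#' base-3 encoding of row segments, each product costs O(mn / log3 n)
#' instead of O(mn).  Results equal the naive dense product up to
#' floating-point summation order.  Matrices with fewer than 27 rows or
#' columns are multiplied naively (the encoding cannot pay off there).
#'
#' @param x a [genotype_matrix()].
#' @param v numeric vector of length \code{ncol(x)}.
#' @param w numeric vector of length \code{nrow(x)}.
#' @return \code{mailman_matvec} returns \code{X v} (length m);
#'   \code{mailman_rmatvec} returns \code{X'w} (length n).
#' @examples
#' g <- genotype_matrix(matrix(sample(0:2, 50 * 40, TRUE), 50, 40))
#' v <- rnorm(40)
#' max(abs(mailman_matvec(g, v) - as.matrix(g) %*% v))
#' @export
mailman_matvec <- function(x, v) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (length(v) != x$n)
    stop(sprintf("length(v) = %d but X has %d columns", length(v), x$n))
  plan <- mailman_plan(x)
  cpp_matvec(x$packed, x$m, x$n, plan$codes, plan$d, plan$nseg, as.numeric(v))
}

#' @rdname mailman_matvec
#' @export
mailman_rmatvec <- function(x, w) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (length(w) != x$m)
    stop(sprintf("length(w) = %d but X has %d rows", length(w), x$m))
  plan <- mailman_plan(x)
  cpp_rmatvec(x$packed, x$m, x$n, plan$codes, plan$d, plan$nseg, as.numeric(w))
}

#' Apply the latent-subspace operator G without forming it
#'
#' Computes \code{G v = ((1/m) X'X - D) v} as
#' \code{(1/m) X'(X v) - d * v} using two Mailman products and the cached
#' heterozygosity diagonal; no n x n or m x n real matrix is allocated.
#'
#' @param x a [genotype_matrix()].
#' @param v numeric vector of length n.
#' @param d optional precomputed [het_diagonal()] (computed and cached
#'   otherwise).
#' @return numeric vector \code{G v} of length n.
#' @export
g_matvec <- function(x, v, d = NULL) {
  if (is.null(d)) {
    d <- x$cache$het
    if (is.null(d)) d <- x$cache$het <- het_diagonal(x)
  }
  mailman_rmatvec(x, mailman_matvec(x, v)) / x$m - d * v
}

# X %*% M and X' %*% W for skinny dense M/W; the batched kernels read the
# segment codes once for all columns.
x_multiply <- function(x, M) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  plan <- mailman_plan(x)
  cpp_matmat(x$packed, x$m, x$n, plan$codes, plan$d, plan$nseg, M)
}

xt_multiply <- function(x, W) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  plan <- mailman_plan(x)
  cpp_rmatmat(x$packed, x$m, x$n, plan$codes, plan$d, plan$nseg, W)
}
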