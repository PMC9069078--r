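# Run `expr` under a temporarily seeded RNG, restoring the caller's stream.
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Balding-Nichols ancestral allele frequencies
#'
#' Draws the m x k matrix of population allele frequencies with
#' \code{p_il ~ Beta(c * pA_i, c * (1 - pA_i))}, \code{c = (1 - FST_i) / FST_i}:
#' mean \code{pA_i}, variance \code{FST_i * pA_i * (1 - pA_i)}.  One
#' \code{(pA, FST)} pair per SNP, shared across the k populations.
#'
#' @param m number of SNPs.
#' @param k number of populations.
#' @param p_anc ancestral frequency, scalar or length-m vector in (0, 1).
#' @param fst per-SNP fixation index, scalar or length-m vector in (0, 1).
#' @param seed integer seed (NULL: use the current RNG stream).
#' @return m x k matrix of frequencies in (0, 1).
#' @export
draw_bn_frequencies <- function(m, k, p_anc, fst, seed = NULL) {
  p_anc <- rep_len(p_anc, m)
  fst <- rep_len(fst, m)
  if (any(p_anc <= 0 | p_anc >= 1)) stop("p_anc must lie strictly in (0, 1)")
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie strictly in (0, 1)")
  cc <- (1 - fst) / fst
  with_seed(seed, matrix(rbeta(m * k, cc * p_anc, cc * (1 - p_anc)), m, k))
}

#' Dirichlet admixture proportions
#'
#' Columns drawn i.i.d. \code{Dirichlet(alpha * 1_k)} via normalised gamma
#' variates; every column sums to one exactly.
#'
#' @param n number of individuals.
#' @param k number of populations.
#' @param alpha Dirichlet concentration (> 0); \code{alpha = 1} is uniform
#'   on the simplex.
#' @param seed integer seed (NULL: current stream).
#' @return k x n admixture matrix.
#' @export
draw_dirichlet_admixture <- function(n, k, alpha = 1, seed = NULL) {
  if (alpha <= 0) stop("alpha must be > 0")
  with_seed(seed, {
    g <- matrix(rgamma(k * n, shape = alpha), k, n)
    cs <- colSums(g)
    degenerate <- cs <= 0
    if (any(degenerate)) g[, degenerate] <- 1   # underflow at tiny alpha
    sweep(g, 2, colSums(g), "/")
  })
}

#' Spatial (1D geography) admixture proportions
#'
#' Populations sit at integer positions \code{z = 1..k} on a line; each
#' individual's position is \code{y_j ~ Uniform(0, k + 1)} and its admixture
#' proportions are normal-density weights
#' \code{q_lj = phi((y_j - z_l) / sigma) / sum_l ...} with variance
#' \code{sigma2}, normalised per column.
#'
#' @param n number of individuals.
#' @param k number of populations.
#' @param sigma2 spatial kernel variance (default 4).
#' @param seed integer seed (NULL: current stream).
#' @return list with \code{Q} (k x n admixture matrix) and \code{positions}
#'   (length-n individual positions).
#' @export
draw_spatial_admixture <- function(n, k, sigma2 = 4, seed = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  with_seed(seed, {
    y <- runif(n, 0, k + 1)
    list(Q = matrix(vapply(y, spatial_weights, numeric(k), k = k, sigma2 = sigma2),
                    nrow = k),
         positions = y)
  })
}

# Normalised normal-density weights of one individual at position y against
# populations at 1..k.
spatial_weights <- function(y, k, sigma2) {
  dens <- dnorm(y, mean = seq_len(k), sd = sqrt(sigma2))
  dens / sum(dens)
}

#' Draw genotypes from factor matrices
#'
#' Given frequencies P (m x k) and admixture Q (k x n), draws
#' \code{x_ij ~ Binomial(2, (PQ)_ij)} independently, packing rows into the
#' 2-bit genotype container in blocks so the full real-valued m x n product
#' is never held at once.
#'
#' @param P m x k frequency matrix (entries in \code{[0, 1]}).
#' @param Q k x n admixture matrix (columns on the simplex).
#' @param seed integer seed (NULL: current stream).
#' @param snp_ids,sample_ids optional identifiers for the result.
#' @return a [genotype_matrix()].
#' @export
draw_genotypes <- function(P, Q, seed = NULL, snp_ids = NULL, sample_ids = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (ncol(P) != nrow(Q)) stop("ncol(P) must equal nrow(Q)")
  if (min(P) < 0 || max(P) > 1) stop("P entries must lie in [0, 1]")
  if (min(Q) < 0 || max(abs(colSums(Q) - 1)) > 1e-8)
    stop("Q columns must be non-negative and sum to one")
  m <- nrow(P); n <- ncol(Q)
  with_seed(seed, {
    block <- max(1L, min(m, as.integer(2^22 %/% max(n, 1L))))
    starts <- seq(1L, m, by = block)
    chunks <- lapply(starts, function(s) {
      rows <- s:min(s + block - 1L, m)
      f <- P[rows, , drop = FALSE] %*% Q
      f[f < 0] <- 0; f[f > 1] <- 1          # guard FP round-off
      g <- matrix(rbinom(length(f), 2L, f), nrow = length(rows))
      cpp_pack(g)
    })
    packed <- do.call(c, chunks)
    if (is.null(snp_ids)) snp_ids <- rownames(P)
    if (is.null(sample_ids)) sample_ids <- colnames(Q)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
    if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(n))
    new_genotype_matrix(packed, m, n, snp_ids, sample_ids)
  })
}

#' Simulate an admixed dataset under the PSD model
#'
#' The Pritchard-Stephens-Donnelly generative model: Balding-Nichols
#' frequencies ([draw_bn_frequencies()]), Dirichlet admixture columns
#' ([draw_dirichlet_admixture()]), binomial genotypes
#' ([draw_genotypes()]).  When \code{p_anc} is NULL, per-SNP ancestral
#' frequencies are drawn \code{Uniform(0.1, 0.9)} (a download-free stand-in
#' for frequencies estimated from a real panel; pass a vector to use real
#' ones).
#'
#' @param m,n,k SNPs, individuals, populations.
#' @param p_anc per-SNP ancestral frequencies (scalar, length-m vector, or
#'   NULL for the Uniform(0.1, 0.9) default).
#' @param fst per-SNP fixation index (default 0.1).
#' @param alpha Dirichlet concentration (default 1).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return An object of class \code{"admix_sim"}: list with \code{X}
#'   ([genotype_matrix()]), \code{P} (true frequencies, m x k), \code{Q}
#'   (true admixture, k x n), \code{params}, \code{seed}, \code{model}.
#' @examples
#' sim <- sim_psd(m = 200, n = 50, k = 3, seed = 1)
#' dim(sim$X); colSums(sim$Q)[1:3]
#' @export
sim_psd <- function(m, n, k, p_anc = NULL, fst = 0.1, alpha = 1, seed = 1L) {
  with_seed(seed, {
    if (is.null(p_anc)) p_anc <- runif(m, 0.1, 0.9)
    P <- draw_bn_frequencies(m, k, p_anc, fst)
    Q <- draw_dirichlet_admixture(n, k, alpha)
    finish_sim(P, Q, model = "psd",
               params = list(m = m, n = n, k = k, fst = fst, alpha = alpha),
               seed = seed)
  })
}

#' Simulate an admixed dataset under the spatial model
#'
#' Balding-Nichols frequencies as in [sim_psd()], admixture proportions from
#' a one-dimensional geography ([draw_spatial_admixture()]); a standard
#' model-violation stress test for PSD-model estimators.
#'
#' @inheritParams sim_psd
#' @param sigma2 spatial kernel variance (default 4).
#' @return An \code{"admix_sim"} object (as [sim_psd()]) with the extra
#'   component \code{positions}.
#' @export
sim_spatial <- function(m, n, k, p_anc = NULL, fst = 0.1, sigma2 = 4, seed = 1L) {
  with_seed(seed, {
    if (is.null(p_anc)) p_anc <- runif(m, 0.1, 0.9)
    P <- draw_bn_frequencies(m, k, p_anc, fst)
    sp <- draw_spatial_admixture(n, k, sigma2)
    out <- finish_sim(P, sp$Q, model = "spatial",
                      params = list(m = m, n = n, k = k, fst = fst, sigma2 = sigma2),
                      seed = seed)
    out$positions <- sp$positions
    out
  })
}

finish_sim <- function(P, Q, model, params, seed) {
  m <- nrow(P); n <- ncol(Q); k <- ncol(P)
  snp_ids <- paste0("snp", seq_len(m))
  sample_ids <- paste0("ind", seq_len(n))
  dimnames(P) <- list(snp_ids, paste0("pop", seq_len(k)))
  dimnames(Q) <- list(paste0("pop", seq_len(k)), sample_ids)
  X <- draw_genotypes(P, Q, snp_ids = snp_ids, sample_ids = sample_ids)
  structure(list(X = X, P = P, Q = Q, params = params,
                 seed = as.integer(seed), model = model),
            class = "admix_sim")
}

#' @export
print.admix_sim <- function(x, ...) {
  cat(sprintf("Simulated admixture dataset (%s model): %d SNPs x %d individuals, k = %d, seed = %d\n",
              x$model, x$params$m, x$params$n, x$params$k, x$seed))
  invisible(x)
}
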