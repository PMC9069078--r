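#' Latent subspace estimation
#'
#' Estimates the k-dimensional latent subspace spanned by the rows of the
#' admixture matrix Q as the span of the top-k eigenvectors of
#' \code{G = (1/m) X'X - D}.  G is never formed: a Krylov (Lanczos) basis is
#' built from repeated [g_matvec()] calls with full reorthogonalisation,
#' eigenpairs are extracted by Rayleigh-Ritz projection, and the basis is
#' enlarged until every requested pair has residual
#' \code{||G v - lambda v|| <= tol * |lambda_1|}.  Because the basis can grow
#' to the full dimension n, convergence is guaranteed; on structured genotype
#' data it stops at a small multiple of k products.
#'
#' @param x a [genotype_matrix()].
#' @param k number of latent populations (eigenvectors), \code{1 <= k < n}.
#' @param seed integer seed for the random starting vector; results are
#'   deterministic given the seed.
#' @param tol relative residual tolerance (default \code{1e-8}).
#' @param max_matvecs cap on operator applications before giving up
#'   (default \code{1000 * k + 100}).
#' @return An object of class \code{"latent_subspace"}: list with \code{V}
#'   (n x k orthonormal), \code{eigenvalues} (descending), \code{residuals},
#'   \code{k}, \code{n}, \code{matvecs}, \code{seed}.
#' @examples
#' sim <- sim_psd(m = 300, n = 60, k = 3, seed = 7)
#' s <- latent_subspace(sim$X, k = 3, seed = 1)
#' s$eigenvalues
#' max(abs(crossprod(s$V) - diag(3)))
#' @export
latent_subspace <- function(x, k, seed = 1L, tol = 1e-8,
                            max_matvecs = 1000L * k + 100L) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- x$n
  if (k < 1L || k >= n) stop(sprintf("k must satisfy 1 <= k < n (k = %d, n = %d)", k, n))
  d <- x$cache$het
  if (is.null(d)) d <- x$cache$het <- het_diagonal(x)
  opfun <- function(v) g_matvec(x, v, d = d)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  q1 <- runif(n, -1, 1)
  q1 <- q1 / sqrt(sum(q1^2))

  ncv <- min(n, max(2L * k + 10L, 20L))
  matvecs <- 0L
  repeat {
    rr <- rayleigh_ritz(opfun, n, ncv, q1)
    matvecs <- matvecs + rr$nops
    scale <- max(abs(rr$values[1]), .Machine$double.eps)
    top_res <- rr$residuals[seq_len(k)]
    if (all(top_res <= max(tol, 1e-12) * scale) || ncv >= n) break
    if (matvecs > max_matvecs)
      stop(sprintf(
        "latent subspace iteration did not converge after %d operator products; residuals: %s",
        matvecs, paste(signif(top_res, 3), collapse = ", ")))
    ncv <- min(n, as.integer(ceiling(ncv * 1.6)) + 5L)
  }

  vals <- rr$values[seq_len(k)]
  V <- rr$vectors[, seq_len(k), drop = FALSE]
  res <- rr$residuals[seq_len(k)]
  scale <- max(abs(vals[1]), .Machine$double.eps)
  if (any(res > 1e-6 * scale))
    stop(sprintf("eigenpair residuals exceed 1e-6 * |lambda_1|: %s",
                 paste(signif(res, 3), collapse = ", ")))
  if (any(vals <= 0))
    warning("some of the top-k eigenvalues of G are <= 0; ",
            "k likely exceeds the detectable structure in the data")
  structure(list(V = V, eigenvalues = vals, residuals = res,
                 k = as.integer(k), n = n, matvecs = matvecs,
                 seed = as.integer(seed)),
            class = "latent_subspace")
}

# Build an orthonormal basis by a Lanczos-style recurrence with full (twice)
# reorthogonalisation, then extract eigenpairs of the projected operator
# H = B' (G B).  Residuals are computed exactly from the stored products
# G B, so breakdown (invariant subspace hit early) is handled by injecting a
# fresh random direction without invalidating the extraction.
rayleigh_ritz <- function(opfun, n, ncv, q1) {
  B <- matrix(0, n, ncv)
  W <- matrix(0, n, ncv)
  B[, 1] <- q1
  nops <- 0L
  for (j in seq_len(ncv)) {
    w <- opfun(B[, j])
    nops <- nops + 1L
    W[, j] <- w
    if (j == ncv) break
    # next basis vector: orthogonalise G b_j against the current basis
    for (pass in 1:2) {
      w <- w - B[, 1:j, drop = FALSE] %*% crossprod(B[, 1:j, drop = FALSE], w)
    }
    nb <- sqrt(sum(w^2))
    if (nb < 1e-10 * max(sqrt(sum(W[, j]^2)), 1)) {
      # invariant subspace: continue from a random direction
      w <- runif(n, -1, 1)
      for (pass in 1:2) {
        w <- w - B[, 1:j, drop = FALSE] %*% crossprod(B[, 1:j, drop = FALSE], w)
      }
      nb <- sqrt(sum(w^2))
    }
    B[, j + 1] <- w / nb
  }
  H <- crossprod(B, W)
  H <- (H + t(H)) / 2
  e <- eigen(H, symmetric = TRUE)
  Y <- B %*% e$vectors
  GY <- W %*% e$vectors
  resid <- sqrt(colSums((GY - Y %*% diag(e$values, ncv))^2))
  list(values = e$values, vectors = Y, residuals = resid, nops = nops)
}

#' @export
print.latent_subspace <- function(x, ...) {
  cat(sprintf("Latent subspace estimate: n = %d, k = %d (%d operator products)\n",
              x$n, x$k, x$matvecs))
  cat("Eigenvalues:", paste(signif(x$eigenvalues, 5), collapse = ", "), "\n")
  invisible(x)
}
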