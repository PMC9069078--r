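#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("Admixture model fit (%s): %d SNPs x %d individuals, k = %d\n",
              if (x$supervised) "supervised" else "unsupervised", x$m, x$n, x$k))
  if (x$supervised) {
    cat("Single-step constrained solve against reference frequencies\n")
  } else {
    cat(sprintf("ALS iterations: %d (%s, final change %.3g, tol %.1g)\n",
                x$iterations,
                if (x$converged) "converged" else "iteration cap reached",
                x$final_delta, x$tol))
  }
  cat("Top eigenvalues of G:",
      paste(signif(x$subspace$eigenvalues[seq_len(x$k)], 4), collapse = ", "), "\n")
  cat("Mean admixture proportions:",
      paste(sprintf("%s %.3f", rownames(x$Q), rowMeans(x$Q)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.admix_fit <- function(object, ...) {
  Q <- object$Q
  pops <- data.frame(
    population = rownames(Q),
    mean = rowMeans(Q),
    median = apply(Q, 1, stats::median),
    max = apply(Q, 1, max),
    n_major = rowSums(Q == apply(Q, 2, max)[col(Q)] & Q >= 1/object$k),
    row.names = NULL)
  out <- list(fit = object, populations = pops,
              eigenvalues = object$subspace$eigenvalues,
              p_range = range(object$P))
  class(out) <- "summary.admix_fit"
  out
}

#' @export
print.summary.admix_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-population admixture summary:\n")
  print(x$populations, digits = 3)
  cat(sprintf("\nAncestral frequency range: [%.3f, %.3f]\n",
              x$p_range[1], x$p_range[2]))
  invisible(x)
}

#' Extract fitted factors
#'
#' \code{coef()} returns the admixture matrix Q (k x n) by default, or the
#' ancestral frequency matrix P (m x k) with \code{matrix = "P"}.
#' @param object an [admix_fit()] result.
#' @param matrix which factor, \code{"Q"} or \code{"P"}.
#' @param ... ignored.
#' @export
coef.admix_fit <- function(object, matrix = c("Q", "P"), ...) {
  switch(match.arg(matrix), Q = object$Q, P = object$P)
}

#' Fitted individual allele frequencies
#'
#' Returns the dense m x n matrix \code{P Q} of fitted per-individual allele
#' frequencies.  This is the one place the package materialises an m x n
#' real matrix; it is intended for small data (plots, residual checks), not
#' for biobank-scale fits.
#' @param object an [admix_fit()] result.
#' @param ... ignored.
#' @export
fitted.admix_fit <- function(object, ...) {
  object$P %*% object$Q
}

#' Raw residuals on the genotype scale
#'
#' \code{X - 2 P Q}: observed minus expected allele count under the binomial
#' model.  Dense (m x n); small-data diagnostic only.
#' @param object an [admix_fit()] result.
#' @param ... ignored.
#' @export
residuals.admix_fit <- function(object, ...) {
  as.matrix(object$genotypes) - 2 * fitted(object)
}

#' Simulate genotypes from a fitted model
#'
#' Draws new genotype matrices \code{x_ij ~ Binomial(2, (P Q)_ij)} from the
#' fitted factors; parametric-bootstrap style replicates.
#' @param object an [admix_fit()] result.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (optional).
#' @param ... ignored.
#' @return list of [genotype_matrix()] objects of length \code{nsim}.
#' @export
simulate.admix_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  lapply(seq_len(nsim), function(i)
    draw_genotypes(object$P, object$Q,
                   snp_ids = rownames(object$P),
                   sample_ids = colnames(object$Q)))
}

#' Diagnostic plot for an admixture fit
#'
#' Two base-graphics panels: the eigenvalue scree of the latent-subspace
#' operator (is k well separated from the bulk?) and, for unsupervised fits,
#' the per-iteration ALS change on a log scale (did the factorisation
#' converge?).
#' @param x an [admix_fit()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.admix_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (length(x$deltas)) 2 else 1))
  on.exit(graphics::par(op))
  ev <- x$subspace$eigenvalues
  graphics::plot(seq_along(ev), ev, type = "b", pch = 19,
                 xlab = "component", ylab = "eigenvalue of G",
                 main = "Latent subspace scree", ...)
  if (length(x$deltas)) {
    graphics::plot(seq_along(x$deltas) + 1L, x$deltas, type = "l", log = "y",
                   xlab = "ALS iteration", ylab = "RMSE change in Q",
                   main = "ALS convergence")
    graphics::abline(h = x$tol, lty = 2)
  }
  invisible(x)
}
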