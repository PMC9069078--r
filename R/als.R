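#' Euclidean projection onto the probability simplex
#'
#' Projects each column of \code{y} (or a single vector) onto
#' \code{\{q : q >= 0, sum(q) = 1\}} by the sort-based algorithm: find the
#' largest support size rho with positive shifted entries, subtract the
#' corresponding threshold, clamp at zero.
#'
#' @param y numeric vector, or matrix whose columns are projected
#'   independently.
#' @return object of the same shape with every column on the simplex.
#' @examples
#' project_simplex(c(0.6, 0.1, 0.9))
#' @export
project_simplex <- function(y) {
  if (is.matrix(y)) return(cpp_project_simplex_cols(y))
  drop(cpp_project_simplex_cols(matrix(as.numeric(y), ncol = 1)))
}

#' Clip a frequency matrix to the unit interval
#'
#' Elementwise \code{min(max(p, 0), 1)}; the truncation step applied to the
#' ancestral-frequency factor after each least-squares update.
#' @param p numeric matrix or vector.
#' @return clipped object of the same shape.
#' @export
clip_unit_interval <- function(p) pmin(pmax(p, 0), 1)

# Solve M %*% Z = B for symmetric k x k M, falling back to the Moore-Penrose
# pseudoinverse (with a warning) when M is numerically rank deficient, so
# exploratory large-k runs degrade gracefully instead of failing.
solve_gram <- function(M, B, what) {
  if (rcond(M) < 1e-12) {
    warning(sprintf("%s is numerically rank deficient (degenerate latent population); using pseudoinverse", what))
    return(MASS::ginv(M) %*% B)
  }
  solve(M, B)
}

#' One alternating-least-squares update of the admixture factor
#'
#' Solves the least-squares problem \code{min ||F_hat - P Q||_F} over Q at
#' fixed P, where \code{F_hat = (1/2) X V V'} is the subspace-projected
#' individual allele frequency matrix, and projects every column onto the
#' probability simplex.  The closed form
#' \code{Q = (1/2) (P'P)^{-1} ((P'X) V) V'} is evaluated right-to-left so the
#' m x n matrix \code{F_hat} is never materialised; \code{P'X} uses k Mailman
#' products.
#'
#' @param x a [genotype_matrix()].
#' @param V n x k orthonormal basis (a [latent_subspace()] object or plain
#'   matrix).
#' @param P m x k frequency matrix, full column rank.
#' @param project project columns onto the simplex (default TRUE; FALSE
#'   exposes the raw least-squares solution, used by tests).
#' @return k x n admixture matrix.
#' @export
update_q <- function(x, V, P, project = TRUE) {
  if (inherits(V, "latent_subspace")) V <- V$V
  P <- as.matrix(P)
  A <- t(xt_multiply(x, P))            # P'X, k x n
  B <- (A %*% V) %*% t(V)              # (P'X) V V'
  Q <- 0.5 * solve_gram(crossprod(P), B, "P'P")
  if (project) Q <- cpp_project_simplex_cols(Q)
  Q
}

#' One alternating-least-squares update of the frequency factor
#'
#' Closed-form least squares for P at fixed Q,
#' \code{P = (1/2) X (V (V'Q')) (Q Q')^{-1}}, evaluated without forming the
#' m x n projected frequency matrix, followed by truncation of every entry
#' to \code{[0, 1]}.
#'
#' @inheritParams update_q
#' @param Q k x n admixture matrix, full row rank.
#' @param clip truncate entries to the unit interval (default TRUE).
#' @return m x k frequency matrix.
#' @export
update_p <- function(x, V, Q, clip = TRUE) {
  if (inherits(V, "latent_subspace")) V <- V$V
  Q <- as.matrix(Q)
  C <- crossprod(V, t(Q))              # V'Q', k x k
  XW <- x_multiply(x, V %*% C)         # X V V' Q', m x k
  P <- 0.5 * t(solve_gram(tcrossprod(Q), t(XW), "QQ'"))
  if (clip) P <- clip_unit_interval(P)
  P
}

#' Fit the admixture model
#'
#' The package's main estimator.  Runs latent subspace estimation
#' ([latent_subspace()]) to obtain the n x k orthonormal basis V, then
#' factorises the implicitly represented individual allele frequency matrix
#' \code{(1/2) X V V'} into ancestral allele frequencies \code{P} (m x k,
#' entries in \code{[0,1]}) and admixture proportions \code{Q} (k x n,
#' columns on the simplex) by truncated alternating least squares:
#' \code{P} is initialised i.i.d. uniform(0,1) from \code{seed}, and
#' Q-then-P updates alternate until the RMSE between successive Q iterates,
#' \code{||Q_t - Q_(t-1)||_F / sqrt(nk)}, drops below \code{tol} or
#' \code{max_iter} iterations are reached.
#'
#' With a reference frequency panel in \code{ref} the fit is supervised:
#' \code{P} is fixed at the supplied frequencies and \code{Q} is obtained in
#' a single constrained least-squares step after the subspace estimate.
#'
#' @param x a [genotype_matrix()] (or a plain \{0,1,2\} matrix, which is
#'   packed on the fly).
#' @param k number of latent populations; ignored (taken from the panel)
#'   when \code{ref} is given.
#' @param ref optional supervision: an m x k numeric matrix of reference
#'   allele frequencies row-aligned to \code{x}'s SNPs, or a
#'   [read_panel()] object covering every SNP of \code{x} (use
#'   [align_panel()] and subsetting first when the panel covers fewer SNPs).
#' @param seed integer seed controlling the eigensolver start vector and the
#'   P initialisation; fits are deterministic given the seed.
#' @param max_iter maximum ALS iterations (default 1000).
#' @param tol convergence tolerance on the RMSE between successive Q
#'   estimates (default 1e-5).
#' @param subspace optional precomputed [latent_subspace()] to reuse across
#'   fits (e.g. one unsupervised and one supervised fit of the same data).
#' @param verbose print the per-iteration change (default FALSE).
#' @return An object of class \code{"admix_fit"} with components \code{Q},
#'   \code{P}, \code{subspace}, \code{iterations}, \code{deltas},
#'   \code{final_delta}, \code{converged}, \code{supervised}, \code{seed}.
#' @examples
#' sim <- sim_psd(m = 500, n = 80, k = 3, seed = 11)
#' fit <- admix_fit(sim$X, k = 3, seed = 1)
#' fit
#' colSums(coef(fit))[1:5]   # columns on the simplex
#' @export
admix_fit <- function(x, k, ref = NULL, seed = 1L, max_iter = 1000L,
                      tol = 1e-5, subspace = NULL, verbose = FALSE) {
  if (!inherits(x, "genotype_matrix")) x <- genotype_matrix(x)
  m <- x$m; n <- x$n
  supervised <- !is.null(ref)
  pop_labels <- NULL
  if (supervised) {
    ref <- resolve_reference(ref, x)
    pop_labels <- colnames(ref)
    k <- ncol(ref)
  }
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  if (k < 1L || k >= min(m, n))
    stop(sprintf("k must satisfy 1 <= k < min(m, n) (k = %d, m = %d, n = %d)", k, m, n))

  if (is.null(subspace)) {
    subspace <- latent_subspace(x, k, seed = seed)
  } else {
    stopifnot(inherits(subspace, "latent_subspace"))
    if (subspace$n != n || subspace$k < k)
      stop("supplied subspace does not match the data / requested k")
  }
  V <- subspace$V[, seq_len(k), drop = FALSE]

  if (supervised) {
    Q <- update_q(x, V, ref)
    check_factor_constraints(Q, ref)
    fit <- list(Q = Q, P = ref, subspace = subspace,
                iterations = 1L, deltas = numeric(0), final_delta = NA_real_,
                converged = TRUE, supervised = TRUE)
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed + 1L)        # distinct stream from the eigensolver start
    P <- matrix(runif(m * k), m, k)
    Q_prev <- NULL
    deltas <- numeric(0)
    converged <- FALSE
    restarts <- 0L
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      # A numerically singular Gram matrix means two latent populations have
      # collapsed onto each other; the pseudoinverse keeps them merged
      # forever, so the cure is a fresh (still seeded-uniform) start.
      degenerate <- FALSE
      withCallingHandlers({
        Q <- update_q(x, V, P)
        P <- update_p(x, V, Q)
      }, warning = function(w) {
        if (grepl("rank deficient", conditionMessage(w))) {
          degenerate <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
      if (degenerate && restarts < 10L) {
        restarts <- restarts + 1L
        if (verbose) message(sprintf("iteration %d: degenerate factors, restarting initialisation (%d)", it, restarts))
        P <- matrix(runif(m * k), m, k)
        Q_prev <- NULL
        deltas <- numeric(0)
        next
      }
      check_factor_constraints(Q, P)
      if (!is.null(Q_prev)) {
        delta <- sqrt(sum((Q - Q_prev)^2) / (n * k))
        deltas <- c(deltas, delta)
        if (verbose) message(sprintf("iteration %d: delta = %.3g", it, delta))
        if (delta < tol) { converged <- TRUE; break }
      }
      Q_prev <- Q
    }
    fit <- list(Q = Q, P = P, subspace = subspace,
                iterations = it, deltas = deltas,
                final_delta = if (length(deltas)) deltas[length(deltas)] else NA_real_,
                converged = converged, supervised = FALSE, restarts = restarts)
  }

  rownames(fit$Q) <- if (!is.null(pop_labels)) pop_labels else paste0("pop", seq_len(k))
  colnames(fit$Q) <- x$sample_ids
  rownames(fit$P) <- x$snp_ids
  colnames(fit$P) <- rownames(fit$Q)
  fit$k <- as.integer(k); fit$m <- m; fit$n <- n
  fit$seed <- as.integer(seed); fit$tol <- tol; fit$max_iter <- as.integer(max_iter)
  fit$genotypes <- x
  fit$call <- match.call()
  class(fit) <- "admix_fit"
  fit
}

# Defensive invariant check run after every ALS iteration: Q columns on the
# simplex to 1e-12, P inside the unit box.
check_factor_constraints <- function(Q, P) {
  if (min(Q) < 0 || max(abs(colSums(Q) - 1)) > 1e-12)
    stop("internal error: admixture columns left the simplex")
  if (min(P) < -1e-15 || max(P) > 1 + 1e-15)
    stop("internal error: frequency entries left [0, 1]")
  invisible(TRUE)
}

# Turn the `ref` argument of admix_fit into an m x k matrix row-aligned to
# x's SNPs, validating identifiers where available.
resolve_reference <- function(ref, x) {
  if (inherits(ref, "ref_panel")) {
    al <- align_panel(ref, x)
    if (length(al$rows) < x$m) {
      missing_id <- setdiff(x$snp_ids, x$snp_ids[al$rows])[1]
      stop(sprintf(
        "reference panel does not cover every SNP of the data (first missing/incompatible: %s); align and subset first",
        missing_id))
    }
    return(al$P)
  }
  ref <- as.matrix(ref)
  if (nrow(ref) != x$m)
    stop(sprintf("reference frequencies have %d rows but X has %d SNPs", nrow(ref), x$m))
  if (!is.null(rownames(ref))) {
    bad <- which(rownames(ref) != x$snp_ids)
    if (length(bad))
      stop(sprintf("reference SNP order mismatch at row %d: '%s' vs '%s'",
                   bad[1], rownames(ref)[bad[1]], x$snp_ids[bad[1]]))
  }
  if (min(ref) < 0 || max(ref) > 1) stop("reference frequencies must lie in [0, 1]")
  ref
}
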