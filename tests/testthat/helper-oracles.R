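# Independent dense oracles used across the suite.  Everything here works on
# plain dense matrices and base-R linear algebra, never on the package's
# packed/matrix-free code paths.

rand_genotypes <- function(m, n) {
  matrix(sample(0:2, m * n, replace = TRUE), m, n)
}

# Dense operator G = (1/m) X'X - D with d_j = mean(2x - x^2) per column.
dense_G <- function(X) {
  crossprod(X) / nrow(X) - diag(colMeans(2 * X - X^2), ncol(X))
}

# Largest principal angle (radians) between the column spans of A and B.
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(0, min(s))))
}

# Exhaustive KKT oracle for Euclidean projection onto the simplex: try every
# support subset, keep feasible candidates, return the closest.
brute_simplex <- function(y) {
  k <- length(y)
  best <- NULL; best_d <- Inf
  for (mask in 1:(2^k - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    q <- numeric(k)
    q[S] <- y[S] - (sum(y[S]) - 1) / length(S)
    if (any(q[S] < -1e-12)) next
    d <- sum((q - y)^2)
    if (d < best_d) { best_d <- d; best <- pmax(q, 0) }
  }
  best
}

# Brute-force assignment: best permutation by full enumeration.
all_perms <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- all_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))
  }))
}

brute_match <- function(cost) {
  perms <- all_perms(nrow(cost))
  scores <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(nrow(cost)), p)]))
  list(permutation = perms[which.min(scores), ], score = min(scores))
}

# Noiseless rank-k construction: one-hot admixture (every population
# represented), 0/1 frequencies, X = 2 P Q exactly.
onehot_construction <- function(m, n, k, seed = 1) {
  set.seed(seed)
  P <- matrix(rbinom(m * k, 1, 0.5), m, k)
  while (qr(P)$rank < k) P <- matrix(rbinom(m * k, 1, 0.5), m, k)
  assign_pop <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
  Q <- diag(k)[, assign_pop, drop = FALSE]
  list(P = P, Q = Q, X = 2 * P %*% Q)
}
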