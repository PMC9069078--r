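#' Match inferred populations to reference populations
#'
#' Population structure estimates are identifiable only up to a relabelling
#' of the k latent populations, so estimates must be aligned before scoring.
#' The cost of assigning inferred population b to reference population a is
#' the mean absolute difference between the two length-n admixture rows; the
#' minimum-total-cost bijection is found with an exact assignment
#' (Hungarian-class) solver.
#'
#' @param q_ref reference admixture matrix, k x n.
#' @param q_est estimated admixture matrix, k x n.
#' @return An object of class \code{"admix_match"}: list with
#'   \code{permutation} (integer vector; reference population a is matched
#'   by estimated population \code{permutation[a]}), \code{total_score}
#'   (summed assignment cost), and \code{cost} (the k x k cost matrix).
#' @examples
#' q <- draw_dirichlet_admixture(20, 3, seed = 1)
#' match_populations(q, q[c(2, 3, 1), ])$permutation
#' @export
match_populations <- function(q_ref, q_est) {
  q_ref <- as.matrix(q_ref); q_est <- as.matrix(q_est)
  if (!all(dim(q_ref) == dim(q_est)))
    stop("admixture matrices must have identical dimensions")
  k <- nrow(q_ref)
  cost <- matrix(0, k, k)
  for (a in seq_len(k))
    for (b in seq_len(k))
      cost[a, b] <- mean(abs(q_ref[a, ] - q_est[b, ]))
  perm <- cpp_solve_assignment(cost)
  structure(list(permutation = perm,
                 total_score = sum(cost[cbind(seq_len(k), perm)]),
                 cost = cost),
            class = "admix_match")
}

#' @export
print.admix_match <- function(x, ...) {
  cat("Population matching:", paste(seq_along(x$permutation), "<-", x$permutation,
                                    collapse = ", "),
      sprintf("(total cost %.4g)\n", x$total_score))
  invisible(x)
}

#' Permutation-matched accuracy metrics for admixture estimates
#'
#' \code{admix_rmse} is the root-mean-square error
#' \code{||Q - Q_hat||_F / sqrt(nk)}.  \code{admix_kl} is the
#' Kullback-Leibler divergence averaged over individuals,
#' \code{(1/n) sum_j sum_l q_lj log(q_lj / qhat_lj)} (natural log), with
#' zeros in either matrix replaced by \code{eps} beforehand.
#' \code{admix_jsd} is the Jensen-Shannon divergence
#' \code{(1/2)[KL(Q, M) + KL(Q_hat, M)]}, \code{M = (Q + Q_hat)/2}, using
#' the same zero-replacement rule.  All three expect the estimate to be
#' permutation-matched already; [evaluate_admixture()] does the matching
#' first.
#'
#' @param q_ref true / reference admixture matrix, k x n.
#' @param q_est estimated admixture matrix, k x n, already matched.
#' @param eps zero-replacement constant for the divergences (default 1e-9).
#' @return a non-negative scalar.
#' @export
admix_rmse <- function(q_ref, q_est) {
  q_ref <- as.matrix(q_ref); q_est <- as.matrix(q_est)
  if (!all(dim(q_ref) == dim(q_est)))
    stop("admixture matrices must have identical dimensions")
  sqrt(sum((q_ref - q_est)^2) / length(q_ref))
}

#' @rdname admix_rmse
#' @export
admix_kl <- function(q_ref, q_est, eps = 1e-9) {
  q_ref <- as.matrix(q_ref); q_est <- as.matrix(q_est)
  if (!all(dim(q_ref) == dim(q_est)))
    stop("admixture matrices must have identical dimensions")
  q_ref[q_ref == 0] <- eps
  q_est[q_est == 0] <- eps
  sum(q_ref * log(q_ref / q_est)) / ncol(q_ref)
}

#' @rdname admix_rmse
#' @export
admix_jsd <- function(q_ref, q_est, eps = 1e-9) {
  q_ref <- as.matrix(q_ref); q_est <- as.matrix(q_est)
  mid <- (q_ref + q_est) / 2
  (admix_kl(q_ref, mid, eps) + admix_kl(q_est, mid, eps)) / 2
}

#' Match, then score, an admixture estimate
#'
#' Runs [match_populations()], applies the optimal relabelling to the
#' estimate, and reports all three metrics on the matched matrices.
#'
#' @inheritParams admix_rmse
#' @param percent report metrics multiplied by 100 (the scale on which
#'   simulation-accuracy tables are usually printed).
#' @return An object of class \code{"admix_eval"}: list with \code{rmse},
#'   \code{jsd}, \code{kl}, \code{match} (the [match_populations()] result),
#'   \code{percent}.
#' @examples
#' q <- draw_dirichlet_admixture(30, 3, seed = 2)
#' evaluate_admixture(q, q[c(3, 1, 2), ])   # relabelling scores zero
#' @export
evaluate_admixture <- function(q_ref, q_est, percent = FALSE, eps = 1e-9) {
  q_ref <- as.matrix(q_ref); q_est <- as.matrix(q_est)
  mt <- match_populations(q_ref, q_est)
  q_m <- q_est[mt$permutation, , drop = FALSE]
  scale <- if (percent) 100 else 1
  structure(list(rmse = scale * admix_rmse(q_ref, q_m),
                 jsd = scale * admix_jsd(q_ref, q_m, eps),
                 kl = scale * admix_kl(q_ref, q_m, eps),
                 match = mt, percent = percent),
            class = "admix_eval")
}

#' @export
print.admix_eval <- function(x, ...) {
  unit <- if (x$percent) "%" else ""
  cat(sprintf("RMSE %.4g%s  JSD %.4g%s  KL %.4g%s  (populations matched: %s)\n",
              x$rmse, unit, x$jsd, unit, x$kl, unit,
              paste(x$match$permutation, collapse = " ")))
  invisible(x)
}
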