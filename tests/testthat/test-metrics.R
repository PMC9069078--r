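test_that("permutation matching recovers relabelings exactly", {
  set.seed(50)
  for (k in c(2, 5, 8)) {
    Q <- draw_dirichlet_admixture(n = 30, k = k, alpha = 1)
    perm <- sample(k)
    mt <- match_populations(Q, Q[perm, ])
    # reference row a should be matched by the estimate row holding it
    expect_identical(mt$permutation, order(perm))
    expect_lt(mt$total_score, 1e-12)
  }
  mt_id <- match_populations(diag(3), diag(3))
  expect_identical(mt_id$permutation, 1:3)
  expect_error(match_populations(diag(3), diag(4)), "dimensions")
})

test_that("the assignment solver agrees with brute-force enumeration", {
  set.seed(51)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    Qr <- draw_dirichlet_admixture(10, k, alpha = 0.5)
    Qe <- draw_dirichlet_admixture(10, k, alpha = 0.5)
    mt <- match_populations(Qr, Qe)
    bf <- brute_match(mt$cost)
    expect_equal(mt$total_score, bf$score, tolerance = 1e-12)
  }
})

test_that("RMSE follows the Frobenius formula", {
  Q <- diag(2)[, 1, drop = FALSE]          # one-hot column, n = 1
  expect_equal(admix_rmse(Q, matrix(0.5, 2, 1)), 0.5)
  set.seed(52)
  A <- draw_dirichlet_admixture(10, 3)
  expect_equal(admix_rmse(A, A), 0)
  expect_equal(admix_rmse(A, A + 0.01), 0.01)   # constant-pattern error of c
  expect_error(admix_rmse(A, A[, 1:5]), "dimensions")
})

test_that("KL and JSD use natural log with 1e-9 zero replacement", {
  q <- matrix(c(1, 0), 2, 1)
  qh <- matrix(c(0.5, 0.5), 2, 1)
  expect_equal(admix_kl(q, qh), 1 * log(2) + 1e-9 * log(1e-9 / 0.5),
               tolerance = 1e-12)
  expect_equal(admix_kl(q, q), 0)
  expect_equal(admix_jsd(q, q), 0)

  set.seed(53)
  A <- draw_dirichlet_admixture(8, 3)
  B <- draw_dirichlet_admixture(8, 3)
  expect_false(isTRUE(all.equal(admix_kl(A, B), admix_kl(B, A))))
  expect_lt(abs(admix_jsd(A, B) - admix_jsd(B, A)), 1e-12)
  expect_gte(admix_jsd(A, B), 0)

  # maximally divergent distributions reach log 2 (up to the eps rule)
  expect_equal(admix_jsd(matrix(c(1, 0), 2, 1), matrix(c(0, 1), 2, 1)),
               log(2), tolerance = 1e-7)
})

test_that("evaluate matches first and then scores", {
  set.seed(54)
  Q <- draw_dirichlet_admixture(10, 3)
  perm <- c(3, 1, 2)
  ev <- evaluate_admixture(Q, Q[perm, ])
  expect_equal(ev$rmse, 0)
  expect_equal(ev$jsd, 0, tolerance = 1e-7)
  expect_equal(ev$kl, 0, tolerance = 1e-7)

  # equals metrics at the brute-force best permutation
  Qe <- draw_dirichlet_admixture(10, 3)
  ev2 <- evaluate_admixture(Q, Qe)
  best <- Inf
  for (r in seq_len(nrow(all_perms(3)))) {
    p <- all_perms(3)[r, ]
    best <- min(best, admix_rmse(Q, Qe[p, ]))
  }
  expect_equal(ev2$rmse, best, tolerance = 1e-12)

  # applying a common permutation to both inputs changes nothing
  ev3 <- evaluate_admixture(Q[perm, ], Qe[perm, ])
  expect_equal(ev3$rmse, ev2$rmse, tolerance = 1e-12)
  expect_equal(ev3$jsd, ev2$jsd, tolerance = 1e-12)

  # percentage reporting is a pure scale change
  ev_pct <- evaluate_admixture(Q, Qe, percent = TRUE)
  expect_equal(ev_pct$rmse, 100 * ev2$rmse)
  expect_equal(ev_pct$jsd, 100 * ev2$jsd)

  # composition of the hand-computed examples: uniform vs one-hot at k = 2
  one_hot <- matrix(c(1, 0), 2, 1)
  uni <- matrix(0.5, 2, 1)
  ev4 <- evaluate_admixture(one_hot, uni)
  expect_equal(ev4$rmse, 0.5)
  expect_equal(ev4$jsd, admix_jsd(one_hot, uni))
})
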