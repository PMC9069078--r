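test_that("simplex projection matches the exhaustive KKT oracle", {
  expect_equal(project_simplex(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_equal(project_simplex(c(2, 0, 0)), c(1, 0, 0))
  expect_equal(project_simplex(c(0.6, 0.1, 0.9)), brute_simplex(c(0.6, 0.1, 0.9)))

  set.seed(20)
  for (i in 1:40) {
    k <- sample(2:6, 1)
    y <- rnorm(k, sd = 2)
    q <- project_simplex(y)
    expect_equal(q, brute_simplex(y), tolerance = 1e-10)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_gte(min(q), 0)
  }
  # matrix form projects columns independently
  Y <- matrix(rnorm(12), 3, 4)
  expect_equal(project_simplex(Y), vapply(1:4, function(j) project_simplex(Y[, j]),
                                          numeric(3)))
})

test_that("unit-interval clipping is elementwise truncation", {
  expect_equal(clip_unit_interval(c(0.5, -0.2, 1.7)), c(0.5, 0, 1))
})

test_that("factor updates equal the dense closed forms", {
  set.seed(21)
  X <- rand_genotypes(8, 6)
  g <- genotype_matrix(X)
  V <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  P <- matrix(runif(8 * 2), 8, 2)
  raw_q <- update_q(g, V, P, project = FALSE)
  expect_lt(max(abs(raw_q - 0.5 * solve(crossprod(P)) %*% t(P) %*% X %*% V %*% t(V))),
            1e-10)
  Q <- update_q(g, V, P)
  raw_p <- update_p(g, V, Q, clip = FALSE)
  expect_lt(max(abs(raw_p - 0.5 * X %*% V %*% t(V) %*% t(Q) %*% solve(tcrossprod(Q)))),
            1e-10)

  # k = 1 degenerate forms: Q is all ones; with the full basis P is the
  # clipped per-SNP mean of X/2
  expect_equal(unname(update_q(g, V, matrix(runif(8), 8, 1))),
               matrix(1, 1, 6))
  Vfull <- diag(6)
  expect_equal(unname(update_p(g, Vfull, matrix(1, 1, 6))),
               matrix(rowMeans(X) / 2, 8, 1))
})

test_that("rank-deficient factors fall back to the pseudoinverse with a warning", {
  set.seed(22)
  X <- rand_genotypes(12, 9)
  g <- genotype_matrix(X)
  V <- qr.Q(qr(matrix(rnorm(9 * 2), 9, 2)))
  P_dup <- cbind(rep(0.5, 12), rep(0.5, 12))
  expect_warning(update_q(g, V, P_dup), "rank deficient")
})

test_that("the noiseless rank-k construction is recovered exactly", {
  con <- onehot_construction(m = 300, n = 60, k = 3, seed = 23)
  g <- genotype_matrix(con$X)
  sub <- latent_subspace(g, 3, seed = 1)
  # with the true factors supplied, single updates reproduce them
  expect_lt(max(abs(update_q(g, sub, con$P) - con$Q)), 1e-8)
  expect_lt(max(abs(update_p(g, sub, con$Q) - con$P)), 1e-8)

  # and the full fit recovers Q up to population permutation
  fit <- admix_fit(g, 3, seed = 5)
  perm <- match_populations(con$Q, coef(fit))$permutation
  expect_lt(max(abs(coef(fit)[perm, ] - con$Q)), 1e-6)
  expect_true(fit$converged)
})

test_that("fitted factors always satisfy their constraints", {
  sim <- sim_psd(m = 400, n = 80, k = 3, seed = 24)
  fit <- admix_fit(sim$X, 3, seed = 1)
  expect_lt(max(abs(colSums(coef(fit)) - 1)), 1e-12)
  expect_gte(min(coef(fit)), 0)
  expect_gte(min(coef(fit, "P")), 0)
  expect_lte(max(coef(fit, "P")), 1)
  expect_identical(dim(coef(fit)), c(3L, 80L))
  expect_identical(dim(coef(fit, "P")), c(400L, 3L))
})

test_that("PSD simulations are recovered and replicate across seeds", {
  sim <- sim_psd(m = 5000, n = 500, k = 3, fst = 0.1, alpha = 1, seed = 42)
  sub <- latent_subspace(sim$X, 3, seed = 1)
  fit1 <- admix_fit(sim$X, 3, seed = 1, subspace = sub)
  ev <- evaluate_admixture(sim$Q, coef(fit1))
  expect_lt(ev$rmse, 0.1)
  # replicate consistency: a different ALS initialisation lands on the same
  # factorisation up to permutation
  fit2 <- admix_fit(sim$X, 3, seed = 2, subspace = sub)
  perm <- match_populations(coef(fit1), coef(fit2))$permutation
  expect_lt(admix_rmse(coef(fit1), coef(fit2)[perm, ]), 0.05)
})

test_that("recovery error shrinks as SNPs accumulate", {
  med_rmse <- vapply(c(1000, 5000, 20000), function(m) {
    errs <- vapply(1:5, function(s) {
      sim <- sim_psd(m = m, n = 500, k = 3, fst = 0.1, alpha = 1, seed = 300 + s)
      fit <- admix_fit(sim$X, 3, seed = s)
      evaluate_admixture(sim$Q, coef(fit))$rmse
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_rmse) < 0))
})

test_that("supervised fitting uses the reference frequencies in one step", {
  con <- onehot_construction(m = 200, n = 40, k = 3, seed = 26)
  g <- genotype_matrix(con$X)
  fit <- admix_fit(g, ref = con$P, seed = 1)
  expect_true(fit$supervised)
  expect_identical(fit$iterations, 1L)
  expect_lt(max(abs(coef(fit) - con$Q)), 1e-8)
  expect_equal(unname(coef(fit, "P")), con$P)   # returned unchanged

  # k = 1 panel: admixture is forced to one
  fit1 <- admix_fit(g, ref = matrix(0.5, 200, 1), seed = 1)
  expect_equal(unname(coef(fit1)), matrix(1, 1, 40))

  # SNP misalignment is reported with the offending id
  Pr <- con$P
  rownames(Pr) <- c("bad_id", g$snp_ids[-1])
  expect_error(admix_fit(g, ref = Pr), "bad_id")
})

test_that("supervision with the true frequencies improves on unsupervised fits", {
  # spatial structure violates the Dirichlet prior, which is where fixing P
  # at the truth helps most clearly
  sim <- sim_spatial(m = 3000, n = 500, k = 6, sigma2 = 4, seed = 27)
  sub <- latent_subspace(sim$X, 6, seed = 1)
  fit_u <- admix_fit(sim$X, 6, seed = 1, subspace = sub)
  fit_s <- admix_fit(sim$X, ref = sim$P, seed = 1, subspace = sub)
  jsd_u <- evaluate_admixture(sim$Q, coef(fit_u))$jsd
  jsd_s <- evaluate_admixture(sim$Q, coef(fit_s))$jsd
  expect_lt(jsd_s, jsd_u)
})

test_that("fit configuration is validated", {
  g <- genotype_matrix(rand_genotypes(20, 10))
  expect_error(admix_fit(g, 0), "k must satisfy")
  expect_error(admix_fit(g, 10), "k must satisfy")
  expect_error(admix_fit(g, 2, tol = 0), "tol")
  expect_error(admix_fit(g, 2, max_iter = 0), "max_iter")
  expect_error(admix_fit(g, 2, ref = matrix(0.5, 3, 2)), "rows")
})
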