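test_that("packing round-trips and validates the alphabet", {
  set.seed(1)
  X <- rand_genotypes(13, 9)
  g <- genotype_matrix(X, snp_ids = paste0("rs", 1:13))
  expect_identical(dim(g), c(13L, 9L))
  expect_identical(unname(as.matrix(g)), X)
  expect_identical(rownames(as.matrix(g)), paste0("rs", 1:13))
  expect_error(genotype_matrix(matrix(3L, 2, 2)), "alphabet")
  expect_error(genotype_matrix(matrix(c(0L, NA), 1, 2)), "NA")

  sub <- g[c(3, 1), c(2, 5, 7)]
  expect_identical(unname(as.matrix(sub)), X[c(3, 1), c(2, 5, 7)])
  expect_identical(sub$snp_ids, c("rs3", "rs1"))
})

test_that("heterozygosity diagonal matches the dense formula", {
  # homozygote-only and heterozygote-only columns hit the extremes
  g <- genotype_matrix(cbind(c(0L, 2L, 2L, 0L), c(1L, 1L, 1L, 1L)))
  expect_equal(het_diagonal(g), c(0, 1))

  set.seed(2)
  X <- rand_genotypes(5, 4)
  expect_equal(het_diagonal(genotype_matrix(X)),
               colMeans(2 * X - X^2))
})

test_that("mailman products equal naive dense products", {
  g0 <- genotype_matrix(matrix(2L, 3, 4))
  expect_equal(mailman_matvec(g0, rep(1, 4)), rep(8, 3))
  expect_equal(mailman_matvec(g0, rep(0, 4)), rep(0, 3))
  gI <- genotype_matrix(diag(2L, 3))
  expect_equal(mailman_rmatvec(gI, c(1, 2, 3)), c(2, 4, 6))

  # property: random sizes spanning the dense-fallback and segmented regimes
  set.seed(3)
  for (dims in list(c(20, 17), c(23, 11), c(5, 120), c(120, 5),
                    c(81, 81), c(200, 150), c(150, 200), c(200, 200))) {
    X <- rand_genotypes(dims[1], dims[2])
    g <- genotype_matrix(X)
    v <- rnorm(dims[2]); w <- rnorm(dims[1])
    expect_lt(max(abs(mailman_matvec(g, v) - X %*% v)), 1e-10)
    expect_lt(max(abs(mailman_rmatvec(g, w) - crossprod(X, w))), 1e-10)
    M <- matrix(rnorm(dims[2] * 3), dims[2], 3)
    W <- matrix(rnorm(dims[1] * 3), dims[1], 3)
    expect_lt(max(abs(lfadmix:::x_multiply(g, M) - X %*% M)), 1e-10)
    expect_lt(max(abs(lfadmix:::xt_multiply(g, W) - crossprod(X, W))), 1e-10)
  }
  expect_error(mailman_matvec(g0, rep(0, 5)), "columns")
  expect_error(mailman_rmatvec(g0, rep(0, 5)), "rows")
})

test_that("the implicit operator G matches its dense form and is symmetric", {
  set.seed(4)
  X <- rand_genotypes(6, 5)
  g <- genotype_matrix(X)
  Gd <- dense_G(X)
  v <- rnorm(5)
  expect_lt(max(abs(g_matvec(g, v) - Gd %*% v)), 1e-10)
  expect_equal(g_matvec(g, rep(0, 5)), rep(0, 5))

  # all-identical columns: Gv constant for the constant test vector
  Xc <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 2L), 5), 6, 5)
  gc_ <- genotype_matrix(Xc)
  out <- g_matvec(gc_, rep(1, 5))
  expect_lt(diff(range(out)), 1e-12)
  expect_lt(max(abs(out - dense_G(Xc) %*% rep(1, 5))), 1e-10)

  # symmetry: v1' (G v2) = v2' (G v1) on larger random instances
  set.seed(5)
  X <- rand_genotypes(90, 70)
  g <- genotype_matrix(X)
  for (i in 1:5) {
    v1 <- rnorm(70); v2 <- rnorm(70)
    expect_lt(abs(sum(v1 * g_matvec(g, v2)) - sum(v2 * g_matvec(g, v1))), 1e-8)
  }
})
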