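test_that("Balding-Nichols draws have the model's mean and variance", {
  p <- draw_bn_frequencies(m = 100000, k = 1, p_anc = 0.3, fst = 0.2, seed = 30)
  n_draw <- length(p)
  # Beta mean pA, variance FST * pA * (1 - pA)
  se_mean <- sqrt(0.2 * 0.3 * 0.7 / n_draw)
  expect_lt(abs(mean(p) - 0.3), 3 * se_mean)
  v <- 0.2 * 0.3 * 0.7
  se_var <- sd((p - mean(p))^2) / sqrt(n_draw)
  expect_lt(abs(var(p) - v), 3 * se_var)

  # small FST concentrates draws at pA
  p_tight <- draw_bn_frequencies(100000, 1, p_anc = 0.5, fst = 0.001, seed = 31)
  expect_lt(sd(p_tight), 0.02)

  expect_error(draw_bn_frequencies(10, 2, p_anc = 1.2, fst = 0.1), "p_anc")
  expect_error(draw_bn_frequencies(10, 2, p_anc = 0.5, fst = 0), "fst")
})

test_that("Dirichlet admixture columns live on the simplex with the right moments", {
  Q <- draw_dirichlet_admixture(n = 100000, k = 3, alpha = 1, seed = 32)
  expect_equal(colSums(Q), rep(1, 100000), tolerance = 1e-12)
  expect_gte(min(Q), 0)
  # symmetric Dirichlet: mean 1/k, component variance (k-1)/(k^2 (k alpha + 1))
  se_mean <- sqrt(1 / 18) / sqrt(100000)
  expect_lt(abs(mean(Q[1, ]) - 1 / 3), 3 * se_mean)
  v <- 2 / (9 * 4)
  se_var <- sd((Q[1, ] - mean(Q[1, ]))^2) / sqrt(100000)
  expect_lt(abs(var(Q[1, ]) - v), 3 * se_var)
})

test_that("spatial admixture proportions are normal-density weights", {
  # midpoint of two populations splits evenly whatever the variance
  for (s2 in c(0.5, 4, 25)) {
    sp <- draw_spatial_admixture(n = 1, k = 2, sigma2 = s2, seed = 33)
    q_mid <- lfadmix:::spatial_weights(1.5, k = 2, sigma2 = s2)
    expect_equal(q_mid, c(0.5, 0.5))
  }
  # direct density-evaluation oracle at y = 1, k = 3, sigma2 = 4
  w <- lfadmix:::spatial_weights(1, k = 3, sigma2 = 4)
  phi <- dnorm(c(0, 1, 2), 0, 2)
  expect_equal(w, phi / sum(phi), tolerance = 1e-12)
  # tiny variance pins an individual sitting on a population to it
  w0 <- lfadmix:::spatial_weights(2, k = 3, sigma2 = 1e-4)
  expect_equal(w0, c(0, 1, 0), tolerance = 1e-12)

  sp <- draw_spatial_admixture(n = 500, k = 4, sigma2 = 4, seed = 34)
  expect_equal(colSums(sp$Q), rep(1, 500), tolerance = 1e-12)
  expect_true(all(sp$positions >= 0 & sp$positions <= 5))
})

test_that("genotype draws follow Binomial(2, f)", {
  # degenerate frequencies are deterministic
  P <- matrix(c(0, 1), 2, 1)
  Q <- matrix(1, 1, 50)
  X <- as.matrix(draw_genotypes(P, Q, seed = 35))
  expect_true(all(X[1, ] == 0) && all(X[2, ] == 2))

  # f = 0.25: genotype frequencies (9, 6, 1)/16; f = 0.5: mean 1
  P <- matrix(c(0.25, 0.5), 2, 1)
  Q <- matrix(1, 1, 100000)
  X <- as.matrix(draw_genotypes(P, Q, seed = 36))
  freq <- tabulate(X[1, ] + 1L, 3) / 100000
  expected <- dbinom(0:2, 2, 0.25)
  se <- sqrt(expected * (1 - expected) / 100000)
  expect_true(all(abs(freq - expected) < 3 * se))
  expect_lt(abs(mean(X[2, ]) - 1), 3 * sqrt(0.5 / 100000))

  expect_error(draw_genotypes(matrix(1.5, 1, 1), matrix(1, 1, 2)), "lie in")
})

test_that("composed simulations are valid and reproducible", {
  sim <- sim_psd(m = 50, n = 20, k = 3, seed = 37)
  expect_s3_class(sim$X, "genotype_matrix")
  expect_identical(dim(sim$X), c(50L, 20L))
  expect_true(all(as.matrix(sim$X) %in% 0:2))
  expect_lt(max(abs(colSums(sim$Q) - 1)), 1e-12)
  expect_true(min(sim$P) >= 0 && max(sim$P) <= 1)

  sim2 <- sim_psd(m = 50, n = 20, k = 3, seed = 37)
  expect_identical(sim$X$packed, sim2$X$packed)
  expect_identical(sim$P, sim2$P)
  sim3 <- sim_psd(m = 50, n = 20, k = 3, seed = 38)
  expect_false(identical(sim$X$packed, sim3$X$packed))

  spat <- sim_spatial(m = 40, n = 15, k = 3, seed = 39)
  expect_identical(spat$model, "spatial")
  expect_length(spat$positions, 15)
  expect_identical(spat$X$packed, sim_spatial(m = 40, n = 15, k = 3, seed = 39)$X$packed)
})

test_that("simulated heterozygosity matches the binomial expectation", {
  sim <- sim_psd(m = 4000, n = 30, k = 3, seed = 40)
  f <- sim$P %*% sim$Q
  expected_het <- colMeans(2 * f * (1 - f))
  observed_het <- het_diagonal(sim$X)
  # per-column binomial sampling error at m SNPs
  se <- sqrt(expected_het * (1 - expected_het) / nrow(f))
  expect_true(all(abs(observed_het - expected_het) < 4 * se))
})
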