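test_that("log-likelihood matches direct arithmetic and the entry loop oracle", {
  g1 <- genotype_matrix(matrix(1L, 1, 1), "s1", "l1")
  expect_equal(admixture_loglik(g1, matrix(1, 1, 1), matrix(0.5, 1, 1)),
               log(0.5) + log(0.5), tolerance = 1e-12)

  # g = 2 at p -> 1 gives vanishing penalty
  g2 <- genotype_matrix(matrix(2L, 1, 1), "s1", "l1")
  expect_equal(admixture_loglik(g2, matrix(1, 1, 1), matrix(1 - 1e-6, 1, 1)),
               0, tolerance = 1e-5)

  G <- rand_geno(8, 15, miss = 0.2, seed = 77)
  K <- 3
  set.seed(7)
  Q <- matrix(rgamma(8 * K, 1), 8); Q <- Q / rowSums(Q)
  F_ <- matrix(runif(K * 15, 0.1, 0.9), K)
  expect_equal(admixture_loglik(G, Q, F_), loglik_oracle(G, Q, F_),
               tolerance = 1e-10)
})

test_that("EM ascends monotonically and keeps Q rows on the simplex", {
  p <- sim_params(K_true = 3, m = 200, seed = 5)
  des <- admixture_design(3, 15, n_f1 = 5, seed = 5)
  sim <- simulate_genotypes(simulate_founders(p), des$Q, seed = 6)
  fit <- fit_admixture(sim$genotypes, 3, seed = 2, n_restarts = 1)
  expect_true(all(diff(fit$loglik_path) > -1e-6 * abs(fit$loglik)))
  expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-8)
  expect_true(all(fit$Q >= 0))
  expect_true(all(fit$F > 0 & fit$F < 1))
})

test_that("pure founders and F1 hybrids are recovered from separated founders", {
  p <- sim_params(K_true = 3, m = 1000, seed = 41)
  des <- admixture_design(3, 30, n_f1 = 12, seed = 41)
  sim <- simulate_genotypes(simulate_founders(p), des$Q, seed = 42)
  fit <- fit_admixture(sim$genotypes, 3, seed = 1, n_restarts = 2)
  perm <- align_labels(sim$truth$Q_true, fit$Q)
  Qa <- fit$Q[, perm]
  pure <- des$class == "pure"
  expect_true(all(apply(Qa[pure, ], 1, max) > 0.95))
  f1_major <- apply(Qa[!pure, ], 1, max)
  expect_true(all(abs(f1_major - 0.5) < 0.05))
})

test_that("fully supervised fits reduce F to observed per-founder frequencies", {
  p <- sim_params(K_true = 2, m = 300, seed = 9)
  des <- admixture_design(2, 25, seed = 9)
  sim <- simulate_genotypes(simulate_founders(p), des$Q, seed = 10)
  labels <- apply(des$Q, 1, which.max)
  fit <- fit_admixture(sim$genotypes, 2, seed = 1, supervised_labels = labels,
                       n_restarts = 1)
  G <- sim$genotypes
  for (k in 1:2) {
    f_obs <- colMeans(G[labels == k, , drop = FALSE]) / 2
    f_obs <- pmin(pmax(f_obs, 1e-6), 1 - 1e-6)
    expect_equal(unname(fit$F[k, ]), unname(f_obs), tolerance = 1e-4)
  }
  expect_true(all(fit$Q[cbind(seq_along(labels), labels)] == 1))
})

test_that("label alignment recovers permutations, survives noise, handles K = 1", {
  set.seed(3)
  Q <- matrix(rgamma(50 * 4, 1), 50); Q <- Q / rowSums(Q)
  perm_true <- c(3L, 1L, 4L, 2L)
  Qb <- Q[, order(perm_true)]
  # Qb[, perm] must restore Q: perm is the inverse of the applied ordering
  expect_identical(as.integer(align_labels(Q, Qb)), perm_true)

  Qn <- Qb + matrix(rnorm(length(Qb), sd = 0.01), nrow(Qb))
  expect_identical(as.integer(align_labels(Q, Qn)), perm_true)

  expect_identical(as.integer(align_labels(Q[, 1, drop = FALSE],
                                           Q[, 1, drop = FALSE])), 1L)
  # degenerate constant column does not break the assignment
  Qc <- Qb; Qc[, 2] <- 0.25
  expect_length(align_labels(Q, Qc), 4L)
})

test_that("cross-validation is reproducible under a fixed seed", {
  p <- sim_params(K_true = 2, m = 80, seed = 15)
  des <- admixture_design(2, 12, seed = 15)
  sim <- simulate_genotypes(simulate_founders(p), des$Q, seed = 16)
  cv1 <- cross_validate_k(sim$genotypes, K_range = 2:3, folds = 4, seed = 8,
                          max_iter = 60)
  cv2 <- cross_validate_k(sim$genotypes, K_range = 2:3, folds = 4, seed = 8,
                          max_iter = 60)
  expect_identical(cv1$fold_errors, cv2$fold_errors)
  expect_true(all(cv1$fold_errors >= 0))
  expect_equal(cv1$best_K, cv1$K_values[which.min(cv1$mean_error)])
})

test_that("homogeneous data gains nothing from extra ancestral populations", {
  p <- sim_params(K_true = 1, m = 300, seed = 19)
  des <- admixture_design(1, 60, seed = 19)
  sim <- simulate_genotypes(simulate_founders(p), des$Q, seed = 20)
  cv <- cross_validate_k(sim$genotypes, K_range = 1:2, folds = 5, seed = 3,
                         max_iter = 150)
  # held-out error of K = 1 is about the binomial variance of the dosages,
  # and K = 2 offers no measurable improvement
  F_ <- sim$truth$F_true
  binom_var <- mean(2 * F_ * (1 - F_))
  expect_lt(abs(cv$mean_error[1] - binom_var) / binom_var, 0.15)
  expect_gt(cv$mean_error[2], cv$mean_error[1] * 0.95)
})
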