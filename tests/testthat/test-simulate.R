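test_that("founder frequencies are reproducible Beta draws on the open interval", {
  p <- sim_params(K_true = 3, m = 800, seed = 101)
  F1 <- simulate_founders(p)
  F2 <- simulate_founders(p)
  expect_identical(F1, F2)
  expect_identical(dim(F1), c(3L, 800L))
  expect_true(all(F1 >= 1e-3 & F1 <= 1 - 1e-3))
  # U-shaped Beta(0.5, 0.5) spectrum: two-sided KS not rejected at 1 %
  ks <- suppressWarnings(ks.test(as.vector(F1), function(q) pbeta(q, 0.5, 0.5)))
  expect_gt(ks$p.value, 0.01)

  p1 <- sim_params(K_true = 1, m = 50, seed = 3)
  expect_identical(dim(simulate_founders(p1)), c(1L, 50L))
})

test_that("genotypes follow the binomial admixture moments", {
  p <- sim_params(K_true = 2, m = 300, seed = 7)
  F_ <- simulate_founders(p)
  Q <- matrix(0, 500, 2); Q[, 1] <- 1
  rownames(Q) <- sprintf("s%03d", 1:500)
  sim <- simulate_genotypes(F_, Q, seed = 8)
  G <- sim$genotypes
  # per-locus dosage mean approx 2 f_1j within 4 binomial SEs
  se <- sqrt(2 * F_[1, ] * (1 - F_[1, ]) / 500)
  expect_true(all(abs(colMeans(G) - 2 * F_[1, ]) < 4 * se + 1e-9))
  # heterozygosity matches 2p(1-p) in aggregate
  expect_equal(mean(G == 1), mean(2 * F_[1, ] * (1 - F_[1, ])),
               tolerance = 0.02)
  # determinism
  expect_identical(simulate_genotypes(F_, Q, seed = 8)$genotypes, G)
})

test_that("clonal copies reproduce the het-miscall error budget", {
  p <- sim_params(K_true = 1, m = 4000, seed = 71)
  F_ <- simulate_founders(p)
  Q <- matrix(1, 1, 1, dimnames = list("src", NULL))
  G <- simulate_genotypes(F_, Q, seed = 72)$genotypes

  # no error, no missing: identical copies at distance zero
  cp0 <- make_clonal_copies(G, "src", copies = 2, eps = 0, mu = 0, seed = 1)
  expect_identical(unname(cp0$genotypes[1, ]), unname(G["src", ]))
  D0 <- ibs_distance(rbind(G, cp0$genotypes))
  expect_equal(max(D0$d), 0)

  # eps > 0: copy-vs-source distance concentrates at H * eps / 2
  eps <- 0.05
  H <- mean(G["src", ] == 1)
  cps <- make_clonal_copies(G, "src", copies = 30, eps = eps, mu = 0, seed = 2)
  D <- ibs_cross_distance(G, cps$genotypes)
  expected <- H * eps / 2
  se <- sqrt(expected * 0.5 / ncol(G)) / sqrt(30)  # rough MC error of the mean
  expect_lt(abs(mean(D$d) - expected), 4 * se)

  # copy-vs-copy distance: per het locus, one flip (0.5) or two flips (avg 0.5)
  pair_expected <- H * (2 * eps * (1 - eps) * 0.5 + eps^2 * 0.5)
  Dp <- ibs_distance(cps$genotypes)
  pair_mean <- mean(Dp$d[upper.tri(Dp$d)])
  expect_lt(abs(pair_mean - pair_expected), 0.15 * pair_expected + 2e-4)

  # missingness masks roughly mu of the calls
  cpm <- make_clonal_copies(G, "src", copies = 10, eps = 0, mu = 0.1, seed = 3)
  expect_lt(abs(mean(is.na(cpm$genotypes)) - 0.1), 0.01)
})

test_that("emitted scenarios do truth bookkeeping and round-trip through files", {
  p <- sim_params(K_true = 4, m = 250, n_library_cultivars = 6,
                  n_library_accessions = 8, library_founders = 3,
                  n_released = 2, n_field_clones = 15,
                  n_unrepresented_genets = 1, n_unrepresented_clones = 4,
                  n_f1 = 5, n_backcross = 3, n_multi = 2, seed = 77)
  sc <- emit_scenario(p)
  n_total <- 8L * 2L + 15L + 4L + 5L + 3L + 2L
  expect_identical(nrow(sc$genotypes), n_total)
  # every sample in exactly one truth category
  expect_identical(length(sc$truth$class), n_total)
  expect_identical(sort(names(sc$truth$class)), sort(rownames(sc$genotypes)))
  census <- table(sc$truth$class)
  expect_equal(unname(as.vector(census[c("library", "clone_of_library",
                                         "clone_unrepresented", "f1",
                                         "backcross", "multi")])),
               c(16, 15, 4, 5, 3, 2))
  # true Q rows are on the simplex
  expect_equal(unname(rowSums(sc$truth$Q_true)), rep(1, n_total),
               tolerance = 1e-12)

  # no multi requested -> none generated
  p0 <- sim_params(K_true = 3, m = 100, n_library_cultivars = 3,
                   n_library_accessions = 3, library_founders = 3,
                   n_released = 1, n_field_clones = 4,
                   n_unrepresented_genets = 0, n_unrepresented_clones = 0,
                   n_f1 = 2, n_backcross = 0, n_multi = 0, seed = 5)
  sc0 <- emit_scenario(p0)
  expect_false("multi" %in% sc0$truth$class)

  # file emission: identical bytes under the same seed, parseable back
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- emit_scenario(p0, dir = d1)
  s2 <- emit_scenario(p0, dir = d2)
  expect_identical(readLines(s1$paths$genotypes), readLines(s2$paths$genotypes))
  expect_identical(readLines(s1$paths$metadata), readLines(s2$paths$metadata))
  expect_identical(readLines(s1$paths$truth), readLines(s2$paths$truth))
  G <- read_genotype_table(s1$paths$genotypes)
  expect_identical(G, s1$genotypes)
  meta <- read_sample_metadata(s1$paths$metadata)
  expect_identical(meta$sample_id, s1$meta$sample_id)
  truth <- jsonlite::read_json(s1$paths$truth)
  expect_identical(length(truth$class), nrow(G))
})

test_that("multi-ancestry designs respect the sub-0.5 constraint", {
  des <- admixture_design(5, 2, n_f1 = 3, n_backcross = 3, n_multi = 10,
                          seed = 13)
  expect_equal(unname(rowSums(des$Q)), rep(1, nrow(des$Q)), tolerance = 1e-12)
  multi <- des$Q[des$class == "multi", , drop = FALSE]
  expect_true(all(apply(multi, 1, max) < 0.5))
  bc <- des$Q[des$class == "half_hybrid", ][-seq_len(3), , drop = FALSE]
  expect_true(all(apply(bc, 1, max) == 0.75))
})
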