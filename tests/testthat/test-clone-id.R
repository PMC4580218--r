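test_that("IBS distance matches hand-computed cases and is a bounded semimetric", {
  G <- genotype_matrix(rbind(a = c(0L, 1L, 2L, 1L), b = c(0L, 2L, 2L, 0L)),
                       locus_ids = sprintf("l%d", 1:4))
  D <- ibs_distance(G)
  expect_equal(D$d["a", "b"], 0.25)  # (0 + 0.5 + 0 + 0.5) / 4

  G2 <- genotype_matrix(rbind(a = c(0L, 2L), b = c(2L, 0L), c = c(0L, 2L)),
                        locus_ids = c("l1", "l2"))
  D2 <- ibs_distance(G2)
  expect_equal(D2$d["a", "b"], 1)    # maximal
  expect_equal(D2$d["a", "c"], 0)    # identical
  expect_identical(D2$d, t(D2$d))
  expect_true(all(D2$d >= 0 & D2$d <= 1))
  expect_true(all(diag(D2$d) == 0))
})

test_that("missing calls shrink n_shared and a fully disjoint pair errors", {
  G <- genotype_matrix(rbind(a = c(0L, 1L, NA), b = c(0L, NA, 2L)),
                       locus_ids = c("l1", "l2", "l3"))
  D <- ibs_distance(G)
  expect_equal(D$n_shared["a", "b"], 1)
  expect_equal(D$d["a", "b"], 0)

  G2 <- genotype_matrix(rbind(a = c(0L, NA), b = c(NA, 2L)),
                        locus_ids = c("l1", "l2"))
  expect_error(ibs_distance(G2), "share no jointly genotyped locus")
})

test_that("IBS distance equals a per-pair loop on random missing data", {
  G <- rand_geno(12, 40, miss = 0.2, seed = 13)
  D <- ibs_distance(G)
  for (i in 1:11) for (j in (i + 1):12) {
    ok <- !is.na(G[i, ]) & !is.na(G[j, ])
    expect_equal(D$d[i, j], mean(abs(G[i, ok] - G[j, ok]) / 2))
    expect_equal(unname(D$n_shared[i, j]), sum(ok))
  }
})

test_that("ward_tree reproduces the brute-force Lance-Williams agglomeration", {
  set.seed(99)
  for (rep in 1:8) {
    X <- matrix(rnorm(8 * 4), 8)
    D <- as.matrix(dist(X))
    ids <- sprintf("s%d", 1:8)
    dimnames(D) <- list(ids, ids)
    tree <- ward_tree(fake_ibs(D, ids))
    oracle <- ward_oracle(unname(D))
    expect_equal(tree$height, oracle$height, tolerance = 1e-10)
    expect_identical(t(apply(tree$merge, 1, sort)), oracle$merge)
    expect_false(is.unsorted(tree$height))  # Ward heights non-decreasing
  }
})

test_that("ward_tree merges tight pairs first and handles n = 2", {
  d <- matrix(0.5, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.01
  d[3, 4] <- d[4, 3] <- 0.01
  diag(d) <- 0
  tree <- ward_tree(fake_ibs(d))
  first_two <- lapply(asplit(tree$merge[1:2, ], 1), sort)
  expect_setequal(first_two, list(c(-2L, -1L), c(-4L, -3L)))

  d2 <- matrix(c(0, 0.3, 0.3, 0), 2)
  tree2 <- ward_tree(fake_ibs(d2))
  expect_equal(tree2$height, 0.3)
})

test_that("threshold calibration applies the safety factor with a 2-decimal ceiling", {
  d <- matrix(0.5, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.03
  d[3, 4] <- d[4, 3] <- 0.04
  meta <- data.frame(sample_id = sprintf("s%d", 1:4), source = "library",
                     duplicate_group = c("A", "A", "B", "B"))
  t <- calibrate_threshold(fake_ibs(d), meta)
  expect_equal(t$value, 0.05)  # 1.25 * 0.04
  expect_setequal(t$duplicate_distances, c(0.03, 0.04))

  # no duplicate pairs -> directed error
  meta2 <- data.frame(sample_id = sprintf("s%d", 1:4), source = "field",
                      duplicate_group = NA_character_)
  expect_error(calibrate_threshold(fake_ibs(d), meta2), "manually")

  # degenerate all-zero duplicates -> warning
  d0 <- matrix(0.5, 2, 2); diag(d0) <- 0; d0[1, 2] <- d0[2, 1] <- 0
  meta0 <- data.frame(sample_id = c("s1", "s2"), source = "library",
                      duplicate_group = "A")
  expect_warning(t0 <- calibrate_threshold(fake_ibs(d0), meta0), "degenerate")
  expect_equal(t0$value, 0)

  # threshold crossing the smallest between-clone distance -> warning
  dx <- matrix(0.045, 4, 4); diag(dx) <- 0
  dx[1, 2] <- dx[2, 1] <- 0.04; dx[3, 4] <- dx[4, 3] <- 0.04
  expect_warning(calibrate_threshold(fake_ibs(dx), meta), "between-clone")
})

test_that("clone grouping rules behave as documented on the chain case", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.04
  d[2, 3] <- d[3, 2] <- 0.04
  d[1, 3] <- d[3, 1] <- 0.08
  D <- fake_ibs(d, c("A", "B", "C"))
  comp <- clone_groups(D, identity_threshold(0.05), rule = "components")
  expect_equal(length(unique(comp$clone_group)), 1L)  # chain merges

  # all pairwise above the threshold -> singletons under both rules
  d2 <- matrix(0.5, 3, 3); diag(d2) <- 0
  D2 <- fake_ibs(d2)
  expect_equal(length(unique(clone_groups(D2, 0.05)$clone_group)), 3L)
  expect_equal(length(unique(clone_groups(D2, 0.05, rule = "tree_cut")$clone_group)), 3L)
})

test_that("raising the threshold never splits a components-rule group", {
  set.seed(31)
  G <- rand_geno(15, 60, seed = 31)
  D <- ibs_distance(G)
  thresholds <- sort(runif(6, 0, 1))
  prev <- clone_groups(D, thresholds[1])$clone_group
  for (t in thresholds[-1]) {
    cur <- clone_groups(D, t)$clone_group
    # monotone coarsening: samples together at a smaller t stay together
    for (g in unique(prev)) {
      members <- which(prev == g)
      expect_length(unique(cur[members]), 1L)
    }
    prev <- cur
  }
})

test_that("library collapsing keeps unique cultivars and records synonyms", {
  p <- sim_params(K_true = 4, m = 400, n_library_cultivars = 6,
                  n_library_accessions = 8, library_founders = 4,
                  n_released = 2, n_field_clones = 0,
                  n_unrepresented_genets = 0, n_unrepresented_clones = 0,
                  n_f1 = 0, n_backcross = 0, n_multi = 0, seed = 17)
  sc <- emit_scenario(p)
  D <- ibs_distance(sc$genotypes)
  # double-entered cultivars sit between duplicate groups at clone distance,
  # which legitimately triggers the calibration caution
  t <- suppressWarnings(calibrate_threshold(D, sc$meta))
  lib <- collapse_library(sc$genotypes, t, meta = sc$meta)
  expect_equal(nrow(lib$cultivars), 6L)
  # every genotyped replicate of every accession lands in some cultivar group
  n_members <- lengths(strsplit(lib$cultivars$members, ";"))
  expect_equal(sum(n_members), 16L)  # 8 accessions x 2 replicates
  expect_true(all(n_members >= 2))

  # a library with no duplicates collapses to itself
  G <- rand_geno(5, 300, seed = 4)
  lib2 <- collapse_library(G, identity_threshold(0.05))
  expect_equal(nrow(lib2$cultivars), 5L)
  expect_identical(sort(rownames(lib2$genotypes)), sort(rownames(G)))
})

test_that("field accessions match their source cultivar; strangers stay unmatched", {
  p <- sim_params(K_true = 5, m = 600, n_library_cultivars = 8,
                  n_library_accessions = 8, library_founders = 4,
                  n_released = 3, n_field_clones = 20,
                  n_unrepresented_genets = 2, n_unrepresented_clones = 6,
                  n_f1 = 0, n_backcross = 0, n_multi = 0, seed = 23)
  sc <- emit_scenario(p)
  lib_ids <- sc$meta$sample_id[sc$meta$source == "library"]
  fld_ids <- sc$meta$sample_id[sc$meta$source == "field"]
  D <- ibs_distance(sc$genotypes)
  t <- calibrate_threshold(D, sc$meta)
  lib <- collapse_library(sc$genotypes[lib_ids, ], t, meta = sc$meta)
  matches <- match_to_library(sc$genotypes[fld_ids, ], lib)

  truth_genet <- sc$truth$genet_of[fld_ids]
  lib_genet <- sc$meta_full$genet[match(lib$cultivars$representative,
                                        sc$meta_full$sample_id)]
  matched_genet <- lib_genet[match(matches$matched_cultivar,
                                   lib$cultivars$cultivar_id)]
  from_library <- sc$truth$class[fld_ids] == "clone_of_library"
  expect_true(all(matched_genet[from_library] == truth_genet[from_library]))
  expect_true(all(is.na(matches$matched_cultivar[!from_library])))

  # an exact copy of a library representative matches at distance zero
  rep1 <- lib$genotypes[1, , drop = FALSE]
  rownames(rep1) <- "probe"
  m0 <- match_to_library(rep1, lib)
  expect_equal(m0$matched_distance, 0)
  expect_identical(m0$matched_cultivar, lib$cultivars$cultivar_id[1])
})
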