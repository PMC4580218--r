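# Shared fixtures and independent oracles used across the suite.

rand_geno <- function(n, m, miss = 0, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) g[matrix(runif(n * m) < miss, n, m)] <- NA
  genotype_matrix(g, sample_ids = sprintf("s%03d", seq_len(n)),
                  locus_ids = sprintf("l%03d", seq_len(m)))
}

# Brute-force Lance-Williams agglomeration on squared distances
# (independent of stats::hclust): merge list in hclust encoding.
ward_oracle <- function(D) {
  n <- nrow(D)
  sizes <- rep(1, n)
  id <- -(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  cur <- D^2
  diag(cur) <- Inf
  for (step in seq_len(n - 1L)) {
    k <- length(id)
    best <- Inf; bi <- bj <- NA
    for (j in seq_len(k)) for (i in seq_len(k))
      if (i < j && cur[i, j] < best) { best <- cur[i, j]; bi <- i; bj <- j }
    height[step] <- sqrt(best)
    merge[step, ] <- sort(c(id[bi], id[bj]))
    ni <- sizes[bi]; nj <- sizes[bj]
    newrow <- vapply(seq_len(k), function(t) {
      if (t == bi || t == bj) return(Inf)
      nk <- sizes[t]
      ((ni + nk) * cur[min(bi, t), max(bi, t)] +
       (nj + nk) * cur[min(bj, t), max(bj, t)] - nk * best) / (ni + nj + nk)
    }, numeric(1))
    keep <- setdiff(seq_len(k), c(bi, bj))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newrow[keep]),
                 c(newrow[keep], Inf))
    sizes <- c(sizes[keep], ni + nj)
    id <- c(id[keep], step)
  }
  list(merge = merge, height = height)
}

# Scalar Weir-Cockerham components for one locus, stepping through the
# component formulas one quantity at a time (independent of the package's
# vectorized path).  geno_by_pop: list of dosage vectors, one per subpop.
wc_oracle <- function(geno_by_pop) {
  r <- length(geno_by_pop)
  n_i <- vapply(geno_by_pop, length, numeric(1))
  p_i <- vapply(geno_by_pop, function(g) mean(g) / 2, numeric(1))
  h_i <- vapply(geno_by_pop, function(g) mean(g == 1), numeric(1))
  nbar <- sum(n_i) / r
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# Entry-by-entry admixture log-likelihood (independent of the C++ path).
loglik_oracle <- function(G, Q, F_, delta = 1e-6) {
  ll <- 0
  for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G))) {
    g <- G[i, j]
    if (is.na(g)) next
    p <- sum(Q[i, ] * F_[, j])
    p <- min(max(p, delta), 1 - delta)
    ll <- ll + g * log(p) + (2 - g) * log(1 - p)
  }
  ll
}

# ibs_dist object with prescribed distances (for threshold-calibration
# arithmetic tests that do not need genotypes behind the distances).
fake_ibs <- function(d, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  structure(list(sample_ids = ids, d = d,
                 n_shared = matrix(100, nrow(d), ncol(d))),
            class = "ibs_dist")
}
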