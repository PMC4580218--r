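#' Log-likelihood of the admixture model
#'
#' Each genotype is modelled as `g_ij ~ Binomial(2, p_ij)` with
#' `p_ij = sum_k q_ik f_kj`, where `q_ik` is the fraction of individual i's
#' ancestry drawn from founder population k and `f_kj` is that founder's
#' alternate-allele frequency at locus j.  The constant binomial coefficient
#' is dropped; missing genotypes are skipped.
#'
#' @param G genotype matrix.
#' @param Q n x K ancestry fractions (rows on the simplex).
#' @param F_ K x m founder allele frequencies in (0, 1).
#' @param delta frequency clamp keeping `p` in `[delta, 1 - delta]`; must be
#'   positive so that an informative genotype at a boundary frequency yields
#'   a finite penalty rather than `-Inf`.
#' @return log-likelihood (a single number).
#' @export
admixture_loglik <- function(G, Q, F_, delta = 1e-6) {
  stopifnot(nrow(G) == nrow(Q), ncol(G) == ncol(F_), ncol(Q) == nrow(F_),
            delta > 0)
  .admix_loglik_cpp(.encode_geno(G), as.matrix(Q), as.matrix(F_), delta)
}

.encode_geno <- function(G) {
  X <- matrix(as.double(G), nrow = nrow(G))
  X[is.na(X)] <- -1
  X
}

#' Fit the admixture model by EM
#'
#' Block EM updates for Q and F with the log-likelihood recomputed every
#' iteration (it never decreases, a property the tests assert).  Multiple
#' seeded restarts guard against local optima; the best log-likelihood wins.
#' In supervised mode, samples with a known founder of origin have their Q
#' row pinned to the corresponding indicator vector and only F (plus the
#' unlabelled rows of Q) is estimated.
#'
#' @param G genotype matrix.
#' @param K number of founder populations (>= 1).
#' @param seed integer seed for the random simplex initialization.
#' @param supervised_labels optional integer vector (length n) of founder
#'   indices in `1..K`, `NA` for unlabelled samples.  Every founder must have
#'   at least one labelled sample.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter iteration cap; hitting it returns `converged = FALSE`
#'   with a warning.
#' @param n_restarts independent initializations (best kept).
#' @param delta frequency clamp.
#' @param refine_support after convergence, select each sample's ancestry
#'   support by BIC: components below 5 percent are dropped and the
#'   restricted per-sample refit (F fixed) is kept unless the likelihood
#'   loss exceeds the BIC penalty for the removed parameters.  A founder
#'   with zero true contribution sits on the simplex boundary, where its ML
#'   estimate is positive with probability about one half, so raw-likelihood
#'   comparison can never remove it; the BIC margin restores exact zeros.
#' @return list of class `admixture_fit`: `K`, `Q`, `F`, `loglik`,
#'   `loglik_path`, `n_iter`, `converged`, `seed`.
#' @export
fit_admixture <- function(G, K, seed = 1L, supervised_labels = NULL,
                          tol = 1e-6, max_iter = 2000L, n_restarts = 3L,
                          delta = 1e-6, refine_support = TRUE) {
  validate_genotypes(G)
  stopifnot(K >= 1, n_restarts >= 1)
  n <- nrow(G); m <- ncol(G)
  X <- .encode_geno(G)
  fixed <- integer(n)
  if (!is.null(supervised_labels)) {
    stopifnot(length(supervised_labels) == n)
    lab <- as.integer(supervised_labels)
    if (!all(is.na(lab) | (lab >= 1 & lab <= K)))
      stop("supervised labels must be founder indices in 1..K (or NA)")
    if (!all(seq_len(K) %in% lab))
      stop("every founder must have at least one labelled sample in supervised mode")
    fixed <- as.integer(!is.na(lab))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + (r - 1L) * 1000L)
    Q0 <- matrix(stats::rgamma(n * K, shape = 1), n, K)
    Q0 <- Q0 / rowSums(Q0)
    if (any(fixed == 1L)) {
      idx <- which(fixed == 1L)
      Q0[idx, ] <- 0
      Q0[cbind(idx, lab[idx])] <- 1
    }
    F0 <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
    fit <- .admix_em_cpp(X, Q0, F0, fixed, delta, as.integer(max_iter), tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within ", max_iter, " iterations")
  if (refine_support && K > 1) {
    best$Q <- .admix_refine_q_cpp(X, best$Q, best$F, fixed, 0.05, 50L, delta)
    best$loglik <- .admix_loglik_cpp(X, best$Q, best$F, delta)
  }
  dimnames(best$Q) <- list(rownames(G), paste0("pop", seq_len(K)))
  dimnames(best$F) <- list(paste0("pop", seq_len(K)), colnames(G))
  structure(list(K = K, Q = best$Q, F = best$F, loglik = best$loglik,
                 loglik_path = best$loglik_path, n_iter = best$n_iter,
                 converged = best$converged, seed = seed),
            class = "admixture_fit")
}

#' Choose the number of founder populations by masked-entry cross-validation
#'
#' Non-missing genotype entries are partitioned at random into `folds`
#' folds.  For each fold and each K, the model is refit with that fold's
#' entries masked out, and the prediction error is the mean squared
#' deviation between each masked dosage and its fitted expectation
#' `2 * p_hat`.  The best K minimizes the mean error over folds.  If masking
#' a fold would leave some locus with no observed genotype, offending
#' entries are reassigned to another fold and logged in `reassigned`.
#'
#' The per-fit controls default to a lighter setting than [fit_admixture()]
#' (single restart, `tol = 1e-5`, `max_iter = 300`): held-out prediction
#' error stabilizes long before the likelihood tail does, and a K scan
#' performs `folds * |K_range|` fits.
#'
#' @param G genotype matrix.
#' @param K_range integer vector of K values to scan.
#' @param folds number of cross-validation folds.
#' @param seed seed driving fold assignment and fit initialization.
#' @param tol,max_iter,n_restarts per-fit EM controls.
#' @return list of class `admixture_cv`: `K_values`, `mean_error` (per K),
#'   `fold_errors` (folds x K matrix), `best_K`, `folds`, `seed`,
#'   `reassigned` (count of reassigned entries).
#' @export
cross_validate_k <- function(G, K_range = 2:18, folds = 10L, seed = 1L,
                             tol = 1e-5, max_iter = 300L, n_restarts = 1L) {
  validate_genotypes(G)
  X <- .encode_geno(G)
  obs <- which(X >= 0)
  if (length(obs) < folds) stop("fewer observed entries than folds")
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs)))
  # every locus must keep >= 1 observation when any single fold is masked
  col_of <- ((obs - 1L) %/% nrow(X)) + 1L
  reassigned <- 0L
  for (j in unique(col_of)) {
    at <- which(col_of == j)
    tab <- table(fold_of[at])
    if (length(tab) == 1L && length(at) > 1L) {
      move <- at[seq_len(ceiling(length(at) / 2))]
      fold_of[move] <- (fold_of[move] %% folds) + 1L
      reassigned <- reassigned + length(move)
    }
  }
  fold_errors <- matrix(NA_real_, nrow = folds, ncol = length(K_range),
                        dimnames = list(NULL, paste0("K", K_range)))
  for (f in seq_len(folds)) {
    held <- obs[fold_of == f]
    Xf <- X
    Xf[held] <- -1
    rows <- ((held - 1L) %% nrow(X))
    cols <- ((held - 1L) %/% nrow(X))
    truth <- X[held]
    for (ki in seq_along(K_range)) {
      K <- K_range[ki]
      fit <- .fit_encoded(Xf, K, seed = seed + 37L * f + ki,
                          tol = tol, max_iter = max_iter,
                          n_restarts = n_restarts)
      pred <- .admix_expected_dosage_cpp(fit$Q, fit$F, rows, cols)
      fold_errors[f, ki] <- mean((truth - pred)^2)
    }
  }
  mean_error <- colMeans(fold_errors)
  structure(list(K_values = K_range, mean_error = mean_error,
                 fold_errors = fold_errors,
                 best_K = K_range[which.min(mean_error)],
                 folds = folds, seed = seed, reassigned = reassigned),
            class = "admixture_cv")
}

# EM on an already-encoded matrix (internal; skips validation/labels)
.fit_encoded <- function(X, K, seed, tol, max_iter, n_restarts) {
  n <- nrow(X); m <- ncol(X)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + (r - 1L) * 1000L)
    Q0 <- matrix(stats::rgamma(n * K, shape = 1), n, K)
    Q0 <- Q0 / rowSums(Q0)
    F0 <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
    fit <- .admix_em_cpp(X, Q0, F0, integer(n), 1e-6, as.integer(max_iter), tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' Align the ancestry columns of one fit to another
#'
#' Mixture labels are arbitrary: two fits of the same data can name the same
#' founder differently.  This finds the column permutation of `Q_b`
#' maximizing the summed Pearson correlation with the columns of `Q_a`
#' (exact assignment by dynamic programming over column subsets; constant
#' columns contribute correlation 0).
#'
#' @param Q_a,Q_b n x K ancestry matrices over the same samples.
#' @return integer permutation `perm` such that `Q_b[, perm]` aligns with
#'   `Q_a`, with attribute `score` (the summed correlation).
#' @export
align_labels <- function(Q_a, Q_b) {
  stopifnot(nrow(Q_a) == nrow(Q_b), ncol(Q_a) == ncol(Q_b))
  K <- ncol(Q_a)
  if (K == 1L) return(structure(1L, score = .safe_cor(Q_a[, 1], Q_b[, 1])))
  C <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    C[i, j] <- .safe_cor(Q_a[, i], Q_b[, j])
  # Held-Karp style assignment: f[mask] = best score assigning the first
  # popcount(mask) rows of Q_a to the column subset `mask` of Q_b.
  nmask <- bitwShiftL(1L, K)
  f <- rep(-Inf, nmask); f[1] <- 0
  choice <- integer(nmask)
  for (mask in seq_len(nmask - 1L)) {
    i <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(K) - 1L)) != 0)
    for (j in seq_len(K)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0) next
      cand <- f[mask - bit + 1L] + C[i, j]
      if (cand > f[mask + 1L]) { f[mask + 1L] <- cand; choice[mask + 1L] <- j }
    }
  }
  perm <- integer(K)
  mask <- nmask - 1L
  for (i in rev(seq_len(K))) {
    j <- choice[mask + 1L]
    perm[i] <- j
    mask <- mask - bitwShiftL(1L, j - 1L)
  }
  structure(perm, score = f[nmask])
}

.safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Write ancestry fractions / founder frequencies as TSV
#' @param fit `admixture_fit`.
#' @param q_path,f_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_admixture_tsv <- function(fit, q_path = NULL, f_path = NULL) {
  if (!is.null(q_path))
    utils::write.table(fit$Q, q_path, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(f_path))
    utils::write.table(fit$F, f_path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(c(q_path, f_path))
}
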