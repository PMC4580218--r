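#' PCA scores of a genotype matrix
#'
#' Column-centers the dosage matrix (missing entries replaced by the locus
#' mean, i.e. zero after centering) and projects onto the top right singular
#' vectors.  A deterministic sign convention is applied: within each
#' component, the loading with the largest absolute value is made positive.
#'
#' @param G genotype matrix.
#' @param n_pcs number of components; silently reduced (with a warning) if
#'   it exceeds the matrix rank.
#' @return list with `scores` (n x n_pcs), `loadings`, `sdev`,
#'   `var_explained` (fraction per component).
#' @export
pca_transform <- function(G, n_pcs) {
  validate_genotypes(G)
  X <- matrix(as.double(G), nrow = nrow(G), dimnames = dimnames(G))
  mu <- colMeans(X, na.rm = TRUE)
  X <- sweep(X, 2, mu, "-")
  X[is.na(X)] <- 0
  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d, 1)
  rank <- sum(pos)
  if (n_pcs > rank) {
    warning("n_pcs = ", n_pcs, " exceeds matrix rank ", rank, "; truncated")
    n_pcs <- rank
  }
  keep <- seq_len(n_pcs)
  V <- sv$v[, keep, drop = FALSE]
  flip <- vapply(keep, function(k) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) -1 else 1
  }, numeric(1))
  V <- sweep(V, 2, flip, "*")
  scores <- X %*% V
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", keep)
  list(scores = scores, loadings = V, sdev = sv$d[keep] / sqrt(max(1, nrow(X) - 1)),
       var_explained = sv$d[keep]^2 / sum(sv$d^2))
}

#' k-means scan with BIC model selection
#'
#' For each k in `1..k_max`, runs `n_init` seeded k-means starts on the PCA
#' scores and keeps the best within-cluster sum of squares `W_k`; the model
#' score is `BIC(k) = n * log(W_k / n) + k * log(n)` and the chosen k
#' minimizes it.  `k = 1` uses the total sum of squares (no clustering).
#'
#' @param scores PCA scores (samples x components).
#' @param k_max largest k scanned; must be below the sample count.
#' @param seed seed for the k-means starts.
#' @param n_init random starts per k.
#' @return list of class `kmeans_scan`: `bic_curve` (length `k_max`), `wss`,
#'   `chosen_k`, `labels` (for `chosen_k`), `all_labels` (list per k).
#' @export
kmeans_bic_scan <- function(scores, k_max = 40L, seed = 1L, n_init = 10L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k_max >= n) stop("k_max must be smaller than the number of samples")
  wss <- numeric(k_max)
  all_labels <- vector("list", k_max)
  tot <- sum(sweep(scores, 2, colMeans(scores), "-")^2)
  wss[1] <- tot
  all_labels[[1]] <- rep(1L, n)
  for (k in seq(2L, length.out = max(0L, k_max - 1L))) {
    set.seed(seed + k)
    km <- suppressWarnings(
      stats::kmeans(scores, centers = k, nstart = n_init, iter.max = 100L))
    wss[k] <- km$tot.withinss
    all_labels[[k]] <- km$cluster
  }
  bic <- n * log(pmax(wss, .Machine$double.xmin) / n) +
    seq_len(k_max) * log(n)
  chosen <- which.min(bic)
  structure(list(bic_curve = bic, wss = wss, chosen_k = chosen,
                 labels = all_labels[[chosen]], all_labels = all_labels,
                 k_max = k_max, seed = seed),
            class = "kmeans_scan")
}

#' Discriminant analysis of principal components
#'
#' Builds linear discriminant axes from the between- and within-group
#' scatter of the retained PCs (within-scatter ridge-regularized if
#' singular), then assigns each individual a membership probability for
#' every group proportional to `exp(-d^2/2)` where `d` is its distance to
#' the group centroid in the sphered discriminant space (shared unit
#' covariance), normalized per individual.
#'
#' @param scores PCA scores.
#' @param labels group labels (>= 2 groups with >= 2 members each).
#' @param n_pcs retained PCs (default 70, truncated to what is available).
#' @return list of class `dapc_fit`: `retained_pcs`, `axes` (PC-space
#'   discriminant directions), `centroids` (in discriminant space),
#'   `ld_scores`, `membership` (rows on the simplex), `assigned` (max
#'   membership group), `groups`.
#' @export
dapc_fit <- function(scores, labels, n_pcs = 70L) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  tab <- table(labels)
  if (nlevels(labels) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 members each")
  n_pcs <- min(n_pcs, ncol(scores))
  X <- scores[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(X); g <- nlevels(labels)
  mu <- colMeans(X)
  centro <- apply(X, 2, function(col) tapply(col, labels, mean))
  W <- matrix(0, n_pcs, n_pcs)
  for (lv in levels(labels)) {
    Xi <- X[labels == lv, , drop = FALSE]
    Xi <- sweep(Xi, 2, centro[lv, ], "-")
    W <- W + crossprod(Xi)
  }
  W <- W / (n - g)
  B <- matrix(0, n_pcs, n_pcs)
  for (lv in levels(labels)) {
    dm <- centro[lv, ] - mu
    B <- B + tab[[lv]] * tcrossprod(dm)
  }
  B <- B / n
  # regularize if within-scatter is singular
  ridge <- 0
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    ridge <- 1e-8 * max(ev)
    W <- W + diag(ridge, n_pcs)
  }
  # generalized eigenproblem via symmetric whitening: W^{-1/2} B W^{-1/2}
  eW <- eigen(W, symmetric = TRUE)
  Wih <- eW$vectors %*% diag(1 / sqrt(eW$values), n_pcs) %*% t(eW$vectors)
  eB <- eigen(Wih %*% B %*% Wih, symmetric = TRUE)
  n_axes <- min(g - 1L, n_pcs)
  A <- Wih %*% eB$vectors[, seq_len(n_axes), drop = FALSE]
  # axes are W-orthonormal => discriminant space has unit within covariance
  ld <- X %*% A
  cent_ld <- centro %*% A
  d2 <- outer(rowSums(ld^2), rowSums(cent_ld^2), "+") - 2 * ld %*% t(cent_ld)
  logm <- -0.5 * pmax(d2, 0)
  logm <- logm - apply(logm, 1, max)
  memb <- exp(logm)
  memb <- memb / rowSums(memb)
  dimnames(memb) <- list(rownames(X), levels(labels))
  structure(list(retained_pcs = n_pcs, axes = A, centroids = cent_ld,
                 ld_scores = ld, membership = memb,
                 assigned = factor(levels(labels)[apply(memb, 1, which.max)],
                                   levels = levels(labels)),
                 groups = levels(labels), ridge = ridge),
            class = "dapc_fit")
}

#' Agreement between DAPC clusters and admixture ancestry groups
#'
#' Cross-tabulates the major-ancestry assignment of admixture-pure samples
#' (maximum ancestry above `purity`) against DAPC maximum-membership
#' clusters, reports the per-ancestry best-matching DAPC cluster and its
#' agreement rate, and counts samples below the purity threshold under each
#' method (DAPC "purity" is its maximum membership probability).
#'
#' @param dapc `dapc_fit`.
#' @param adm `admixture_fit` over the same samples (same order).
#' @param purity threshold on maximum ancestry / membership.
#' @return list of class `cluster_agreement`: `table` (admixture cluster x
#'   DAPC cluster counts over pure samples), `per_cluster` data frame
#'   (`adm_cluster`, `best_dapc_cluster`, `n`, `agreement`),
#'   `overall_agreement`, `n_admixed_adm`, `n_admixed_dapc`.
#' @export
compare_clusterings <- function(dapc, adm, purity = 0.90) {
  stopifnot(inherits(dapc, "dapc_fit"), inherits(adm, "admixture_fit"),
            nrow(dapc$membership) == nrow(adm$Q))
  mx <- apply(adm$Q, 1, max)
  major <- apply(adm$Q, 1, which.max)
  pure <- mx > purity
  tab <- table(adm_cluster = major[pure],
               dapc_cluster = as.character(dapc$assigned)[pure])
  per <- lapply(rownames(tab), function(k) {
    row <- tab[k, ]
    data.frame(adm_cluster = k,
               best_dapc_cluster = colnames(tab)[which.max(row)],
               n = sum(row), agreement = max(row) / sum(row),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  overall <- sum(per$n * per$agreement) / sum(per$n)
  structure(list(table = tab, per_cluster = per,
                 overall_agreement = overall,
                 n_admixed_adm = sum(!pure),
                 n_admixed_dapc = sum(apply(dapc$membership, 1, max) <= purity)),
            class = "cluster_agreement")
}
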