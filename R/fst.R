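#' Per-locus Weir-Cockerham F_ST
#'
#' Computes the variance components of the Weir-Cockerham (1984) estimator
#' per biallelic locus across two or more subpopulations: `a` (among
#' populations), `b` (among individuals within populations), `c` (within
#' individuals), and `theta = a / (a + b + c)`.  With subpopulation sample
#' sizes `n_i`, alt-allele frequencies `p_i` and observed heterozygote
#' fractions `h_i`:
#' \deqn{\bar n = \sum n_i / r, \quad
#'       n_c = (r \bar n - \sum n_i^2/(r \bar n)) / (r - 1)}
#' \deqn{\bar p = \sum n_i p_i / (r \bar n), \quad
#'       S^2 = \sum n_i (p_i - \bar p)^2 / ((r-1) \bar n), \quad
#'       \bar h = \sum n_i h_i / (r \bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[S^2 - \frac{1}{\bar n - 1}
#'       \left(\bar p(1-\bar p) - \frac{r-1}{r} S^2 -
#'       \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'       \frac{r-1}{r} S^2 - \frac{2\bar n - 1}{4 \bar n}\bar h\right],
#'       \quad c = \bar h / 2}
#' Loci monomorphic across all subpopulations have `a + b + c = 0` and an
#' undefined theta (`NA`, flagged in `defined`).
#'
#' @param G genotype matrix.
#' @param subpop_labels vector (length n) of subpopulation labels; `NA`
#'   samples are dropped.  Each retained subpopulation must have at least two
#'   genotyped samples at a locus for that locus to be evaluated.
#' @return data frame of class `fst_table`: `locus_id`, `a`, `b`, `c`,
#'   `theta`, `defined`, plus the pooled quantities `nbar`, `nc`, `pbar`,
#'   `s2`, `hbar` and `r`.
#' @export
weir_cockerham_fst <- function(G, subpop_labels) {
  validate_genotypes(G)
  stopifnot(length(subpop_labels) == nrow(G))
  keep <- !is.na(subpop_labels)
  G <- G[keep, , drop = FALSE]
  labs <- factor(subpop_labels[keep])
  r <- nlevels(labs)
  if (r < 2) stop("need at least two subpopulations")
  m <- ncol(G)
  # per-subpop per-locus counts via indicator matmuls
  Z <- stats::model.matrix(~ labs - 1)            # n x r membership
  Obs <- (!is.na(G)) * 1
  X <- G; X[is.na(X)] <- 0L; storage.mode(X) <- "double"
  Het <- (G == 1L & !is.na(G)) * 1
  n_i <- t(Z) %*% Obs                              # r x m genotyped counts
  if (any(n_i < 2))
    stop("every subpopulation needs >= 2 genotyped samples at every locus; ",
         "locus ", colnames(G)[which(colSums(n_i < 2) > 0)[1]], " fails")
  p_i <- (t(Z) %*% X) / (2 * n_i)
  h_i <- (t(Z) %*% Het) / n_i
  nbar <- colSums(n_i) / r
  nc <- (colSums(n_i) - colSums(n_i^2) / colSums(n_i)) / (r - 1)
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * sweep(p_i, 2, pbar, "-")^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  defined <- tot != 0
  theta <- ifelse(defined, a / tot, NA_real_)
  structure(data.frame(locus_id = colnames(G), a = a, b = b, c = cc,
                       theta = theta, defined = defined, r = r,
                       nbar = nbar, nc = nc, pbar = pbar, s2 = s2, hbar = hbar,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("fst_table", "data.frame"))
}

#' Assign subpopulation labels from an admixture fit
#'
#' Samples whose largest ancestry fraction exceeds `purity` are labelled
#' with that founder; admixed samples get `NA` and are excluded from F_ST.
#'
#' @param fit `admixture_fit`.
#' @param purity threshold on the maximum ancestry fraction.
#' @return integer vector of founder indices with `NA` for admixed samples.
#' @export
subpop_labels_from_fit <- function(fit, purity = 0.90) {
  mx <- apply(fit$Q, 1, max)
  lab <- apply(fit$Q, 1, which.max)
  lab[mx <= purity] <- NA_integer_
  as.integer(lab)
}

#' Select an ancestry-informative marker panel
#'
#' @param fst `fst_table` from [weir_cockerham_fst()].
#' @param threshold keep loci with `theta > threshold`; input order preserved.
#' @return list of class `aim_panel`: `threshold`, `locus_ids`, `size`.
#' @export
select_aims <- function(fst, threshold) {
  stopifnot(inherits(fst, "fst_table"))
  keep <- fst$defined & fst$theta > threshold
  if (!any(keep))
    stop("no locus exceeds F_ST threshold ", threshold, "; lower the threshold")
  structure(list(threshold = threshold, locus_ids = fst$locus_id[keep],
                 size = sum(keep)),
            class = "aim_panel")
}

#' Accuracy of ancestry estimation with reduced marker panels
#'
#' For each candidate panel, the admixture model is refit in supervised mode
#' on the panel's loci (labelled samples pinned, as in the full fit) and the
#' accuracy is the squared Pearson correlation (R^2) between all aligned Q
#' entries of the reduced fit and the full fit.  For comparison, `reps`
#' random panels of the same size are drawn uniformly with replacement from
#' all loci and refit the same way; their mean R^2 and SD are reported.
#'
#' @param G genotype matrix (same loci as `full_fit`).
#' @param full_fit `admixture_fit` on all loci.
#' @param panels list of [select_aims()] panels (or bare locus-id vectors).
#' @param reps random replicates per panel size.
#' @param seed seed for random panel draws and refits.
#' @param supervised_labels labels pinned during refits; default derives
#'   pure samples (`> 0.90`) from `full_fit`.
#' @param per_column also record per-ancestry-column R^2.
#' @param tol,max_iter per-refit EM controls.
#' @return data frame of class `subset_accuracy`: one row per (panel, rep)
#'   with `panel_kind` (`"fst"`/`"random"`), `size`, `rep`, `r2`, plus the
#'   per-column R^2 matrix in attribute `per_column_r2` when requested.
#' @export
subset_accuracy_experiment <- function(G, full_fit, panels, reps = 20L,
                                       seed = 1L, supervised_labels = NULL,
                                       per_column = TRUE,
                                       tol = 1e-5, max_iter = 500L) {
  validate_genotypes(G)
  stopifnot(inherits(full_fit, "admixture_fit"), length(panels) >= 1)
  if (is.null(supervised_labels))
    supervised_labels <- subpop_labels_from_fit(full_fit)
  if (!all(seq_len(full_fit$K) %in% supervised_labels))
    stop("full fit yields no pure representative for some founder; ",
         "supply supervised_labels explicitly")
  sizes <- vapply(panels, function(p)
    if (inherits(p, "aim_panel")) p$size else length(p), integer(1))
  rows <- list()
  percol <- list()
  one_fit <- function(loci, fit_seed) {
    sub <- G[, loci, drop = FALSE]
    colnames(sub) <- make.unique(colnames(sub))  # random draws are with replacement
    fit <- fit_admixture(sub, K = full_fit$K, seed = fit_seed,
                         supervised_labels = supervised_labels,
                         tol = tol, max_iter = max_iter, n_restarts = 1L)
    perm <- align_labels(full_fit$Q, fit$Q)
    Qa <- fit$Q[, perm, drop = FALSE]
    r2 <- stats::cor(as.vector(full_fit$Q), as.vector(Qa))^2
    colr2 <- vapply(seq_len(full_fit$K), function(k)
      .safe_cor(full_fit$Q[, k], Qa[, k])^2, numeric(1))
    list(r2 = r2, colr2 = colr2, converged = fit$converged)
  }
  for (pi in seq_along(panels)) {
    loci <- if (inherits(panels[[pi]], "aim_panel")) panels[[pi]]$locus_ids
            else panels[[pi]]
    res <- one_fit(match(loci, colnames(G)), fit_seed = seed + 811L * pi)
    rows[[length(rows) + 1L]] <-
      data.frame(panel_kind = "fst", size = sizes[pi], rep = 1L, r2 = res$r2)
    percol[[length(percol) + 1L]] <- res$colr2
    for (rep_i in seq_len(reps)) {
      set.seed(seed + 7919L * pi + rep_i)
      draw <- sample.int(ncol(G), sizes[pi], replace = TRUE)
      res_r <- one_fit(draw, fit_seed = seed + 7919L * pi + 500L + rep_i)
      rows[[length(rows) + 1L]] <-
        data.frame(panel_kind = "random", size = sizes[pi], rep = rep_i,
                   r2 = res_r$r2)
      percol[[length(percol) + 1L]] <- res_r$colr2
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("subset_accuracy", "data.frame")
  if (per_column) attr(out, "per_column_r2") <- do.call(rbind, percol)
  attr(out, "seed") <- seed
  out
}

#' Summarize a subset-accuracy experiment
#' @param acc `subset_accuracy` data frame.
#' @return data frame with mean and SD of R^2 per (panel_kind, size).
#' @export
summarize_subset_accuracy <- function(acc) {
  agg <- stats::aggregate(r2 ~ panel_kind + size, data = acc,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(panel_kind = agg$panel_kind, size = agg$size,
                    mean_r2 = agg$r2[, "mean"], sd_r2 = agg$r2[, "sd"],
                    n = agg$r2[, "n"])
  out$sd_r2[is.na(out$sd_r2)] <- 0
  out[order(out$panel_kind, -out$size), ]
}
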