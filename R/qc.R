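#' SNP curation configuration
#'
#' Defaults reproduce the standard curation applied to GBS dosage data
#' before clone fingerprinting: drop loci with minor allele frequency below
#' 0.01 and loci with more than 40 percent missing calls, then impute the
#' residual missing genotypes.
#'
#' @param min_maf minimum minor allele frequency, in `[0, 0.5]`.
#' @param max_locus_missing maximum tolerated per-locus missing fraction.
#' @param imputer `"per_locus_mean_round"` (default) or `"knn"`.
#' @param knn_k neighbours used by the knn imputer.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(min_maf = 0.01, max_locus_missing = 0.40,
                      imputer = c("per_locus_mean_round", "knn"), knn_k = 5L) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            max_locus_missing >= 0, max_locus_missing <= 1, knn_k >= 1)
  structure(list(min_maf = min_maf, max_locus_missing = max_locus_missing,
                 imputer = match.arg(imputer), knn_k = as.integer(knn_k)),
            class = "qc_config")
}

#' Per-locus allele frequency and missingness
#' @param G genotype matrix.
#' @return data frame with `locus_id`, `p` (alt-allele frequency over
#'   non-missing calls), `maf`, `missing_frac`, `n_obs`.
#' @export
locus_stats <- function(G) {
  validate_genotypes(G)
  n_obs <- colSums(!is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  p[n_obs == 0] <- NA_real_
  data.frame(locus_id = colnames(G), p = p, maf = pmin(p, 1 - p),
             missing_frac = 1 - n_obs / nrow(G), n_obs = n_obs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter loci on missingness and minor allele frequency
#'
#' The missingness rule is applied first, then the MAF rule (computed on
#' non-missing calls of all samples).  A locus failing both is reported under
#' the missingness reason.
#'
#' @param G genotype matrix, `n >= 1` samples.
#' @param cfg [qc_config()].
#' @return list with `genotypes` (retained loci, same samples) and `report`,
#'   a data frame with one row per input locus (`locus_id`, `maf`,
#'   `missing_frac`, `retained`, `reason` in `{"", "missing", "maf"}`).
#' @export
filter_loci <- function(G, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  st <- locus_stats(G)
  if (nrow(G) < 1) stop("need at least one sample")
  drop_missing <- st$missing_frac > cfg$max_locus_missing
  drop_maf <- !drop_missing & (is.na(st$maf) | st$maf < cfg$min_maf)
  retained <- !(drop_missing | drop_maf)
  if (!any(retained))
    stop("all ", ncol(G), " loci removed by QC filters; relax min_maf/max_locus_missing")
  report <- data.frame(locus_id = st$locus_id, maf = st$maf,
                       missing_frac = st$missing_frac, retained = retained,
                       reason = ifelse(drop_missing, "missing",
                                       ifelse(drop_maf, "maf", "")),
                       stringsAsFactors = FALSE)
  list(genotypes = G[, retained, drop = FALSE], report = report)
}

#' Impute residual missing genotypes
#'
#' `per_locus_mean_round` replaces each missing call with the locus mean
#' dosage rounded to the nearest of 0/1/2 (half away from zero).  `knn`
#' finds, per sample, the `knn_k` nearest samples by identity-by-state
#' distance on pairwise-complete loci and imputes each missing call with the
#' rounded mean of the neighbours observed at that locus (falling back to
#' the locus mean when no neighbour is observed).  Observed entries are
#' never altered.
#'
#' @param G genotype matrix; every locus must have at least one observed call.
#' @param cfg [qc_config()].
#' @param seed optional seed (tie-breaking among equidistant neighbours is
#'   deterministic, so the default imputers are seed-independent; kept for
#'   interface stability).
#' @return genotype matrix with no missing values.
#' @export
impute_missing <- function(G, cfg = qc_config(), seed = NULL) {
  stopifnot(inherits(cfg, "qc_config"))
  validate_genotypes(G)
  if (!anyNA(G)) return(G)
  n_obs <- colSums(!is.na(G))
  if (any(n_obs == 0))
    stop("all-missing locus: ", colnames(G)[n_obs == 0][1])
  locus_mean <- colMeans(G, na.rm = TRUE)
  out <- G
  if (cfg$imputer == "per_locus_mean_round") {
    for (j in which(colSums(is.na(G)) > 0)) {
      out[is.na(G[, j]), j] <- .round_dosage(locus_mean[j])
    }
  } else {
    D <- ibs_distance(G)$d
    diag(D) <- Inf
    for (i in which(rowSums(is.na(G)) > 0)) {
      nb <- order(D[i, ])[seq_len(min(cfg$knn_k, nrow(G) - 1L))]
      for (j in which(is.na(G[i, ]))) {
        v <- G[nb, j]
        v <- v[!is.na(v)]
        out[i, j] <- .round_dosage(if (length(v)) mean(v) else locus_mean[j])
      }
    }
  }
  out
}

.round_dosage <- function(x) {
  # round half away from zero, clamp to valid dosage
  as.integer(pmin(2L, pmax(0L, floor(x + 0.5))))
}
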