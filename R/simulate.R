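#' Parameters of the synthetic clonal-survey generator
#'
#' The generator emulates a clonal crop survey: K founder populations with
#' distinct allele-frequency vectors; cultivars ("genets") that are pure
#' clones of one founder; field accessions that are vegetative copies
#' (ramets) of cultivars, re-genotyped with the dominant GBS error mode
#' (heterozygotes miscalled as a random homozygote) plus missing data; F1
#' (0.5/0.5), backcross (0.75/0.25) and multi-founder admixed individuals;
#' a duplicated reference library; and a noisy farmer naming layer with
#' synonyms and homonyms.
#'
#' @param K_true number of founder populations.
#' @param m number of SNP loci.
#' @param founder_freq_beta shape parameters of the Beta distribution the
#'   founder allele frequencies are drawn from (default `c(0.5, 0.5)`, the
#'   U-shaped spectrum typical of genome-wide SNP panels).
#' @param n_library_cultivars genetically unique library cultivars.
#' @param n_library_accessions library DNA accessions (>= cultivars; the
#'   surplus are independently collected duplicates of random cultivars
#'   carrying different names).
#' @param duplicates_per_accession times each library accession is
#'   re-genotyped (the duplicate pairs used for threshold calibration).
#' @param n_released library cultivars flagged as released varieties.
#' @param library_founders founders represented in the library (first
#'   `library_founders` of the K; the rest exist only in farmers' fields).
#' @param n_field_clones field accessions that are ramets of library cultivars.
#' @param n_unrepresented_genets unique field cultivars from founders absent
#'   from the library.
#' @param n_unrepresented_clones field accessions that are ramets of those.
#' @param n_f1,n_backcross,n_multi admixed field accessions.
#' @param het_miscall_rate per-call probability that a heterozygote is
#'   miscalled as a random homozygote when a clone is re-genotyped.
#' @param missing_rate per-call missing probability at re-genotyping.
#' @param synonyms_per_cluster farmer names per cultivar.
#' @param homonym_prob probability that a cultivar reuses a name already
#'   given to another cultivar.
#' @param seed integer seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(K_true = 11L, m = 1000L,
                       founder_freq_beta = c(0.5, 0.5),
                       n_library_cultivars = 34L, n_library_accessions = 64L,
                       duplicates_per_accession = 2L, n_released = 16L,
                       library_founders = min(8L, K_true),
                       n_field_clones = 600L,
                       n_unrepresented_genets = 3L, n_unrepresented_clones = 120L,
                       n_f1 = 100L, n_backcross = 40L, n_multi = 40L,
                       het_miscall_rate = 0.03, missing_rate = 0.02,
                       synonyms_per_cluster = 2L, homonym_prob = 0.10,
                       seed = 1L) {
  p <- list(K_true = as.integer(K_true), m = as.integer(m),
            founder_freq_beta = founder_freq_beta,
            n_library_cultivars = as.integer(n_library_cultivars),
            n_library_accessions = as.integer(n_library_accessions),
            duplicates_per_accession = as.integer(duplicates_per_accession),
            n_released = as.integer(n_released),
            library_founders = as.integer(library_founders),
            n_field_clones = as.integer(n_field_clones),
            n_unrepresented_genets = as.integer(n_unrepresented_genets),
            n_unrepresented_clones = as.integer(n_unrepresented_clones),
            n_f1 = as.integer(n_f1), n_backcross = as.integer(n_backcross),
            n_multi = as.integer(n_multi),
            het_miscall_rate = het_miscall_rate, missing_rate = missing_rate,
            synonyms_per_cluster = as.integer(synonyms_per_cluster),
            homonym_prob = homonym_prob, seed = as.integer(seed))
  stopifnot(p$K_true >= 1, p$m >= 1,
            p$het_miscall_rate >= 0, p$het_miscall_rate < 1,
            p$missing_rate >= 0, p$missing_rate < 1,
            p$n_library_accessions >= p$n_library_cultivars,
            p$library_founders <= p$K_true,
            p$n_released <= p$n_library_cultivars)
  structure(p, class = "sim_params")
}

#' Draw founder allele-frequency vectors
#'
#' Frequencies are iid Beta(alpha, beta) per founder and locus, clamped to
#' `[1e-3, 1 - 1e-3]` so no founder is fixed anywhere.
#'
#' @param params [sim_params()].
#' @return K x m matrix of alternate-allele frequencies.
#' @export
simulate_founders <- function(params) {
  set.seed(params$seed)
  F_true <- matrix(stats::rbeta(params$K_true * params$m,
                                params$founder_freq_beta[1],
                                params$founder_freq_beta[2]),
                   nrow = params$K_true)
  F_true <- pmin(pmax(F_true, 1e-3), 1 - 1e-3)
  dimnames(F_true) <- list(paste0("founder", seq_len(params$K_true)),
                           sprintf("L%05d", seq_len(params$m)))
  F_true
}

#' Build an admixture design matrix of ancestry rows
#'
#' Pure rows are indicator vectors; F1 rows mix two founders 0.5/0.5;
#' backcross rows 0.75/0.25; multi rows are Dirichlet(1, ..., 1) draws
#' rejected until no component reaches 0.5.
#'
#' @param K number of founders.
#' @param n_pure_per_founder pure individuals per founder.
#' @param n_f1,n_backcross,n_multi admixed individuals.
#' @param seed integer seed.
#' @return list with `Q` (n x K) and `class` (character vector:
#'   `pure`/`half_hybrid`/`multi`; backcrosses are half-hybrids by design).
#' @export
admixture_design <- function(K, n_pure_per_founder, n_f1 = 0L,
                             n_backcross = 0L, n_multi = 0L, seed = 1L) {
  set.seed(seed)
  rows <- list(); cls <- character(0)
  for (k in seq_len(K)) {
    for (i in seq_len(n_pure_per_founder)) {
      q <- numeric(K); q[k] <- 1
      rows[[length(rows) + 1L]] <- q; cls <- c(cls, "pure")
    }
  }
  pick2 <- function() sample.int(K, 2L)
  for (i in seq_len(n_f1)) {
    q <- numeric(K); q[pick2()] <- 0.5
    rows[[length(rows) + 1L]] <- q; cls <- c(cls, "half_hybrid")
  }
  for (i in seq_len(n_backcross)) {
    q <- numeric(K); q[pick2()] <- c(0.75, 0.25)
    rows[[length(rows) + 1L]] <- q; cls <- c(cls, "half_hybrid")
  }
  for (i in seq_len(n_multi)) {
    repeat {
      q <- stats::rgamma(K, shape = 1); q <- q / sum(q)
      if (max(q) < 0.5) break
    }
    rows[[length(rows) + 1L]] <- q; cls <- c(cls, "multi")
  }
  Q <- do.call(rbind, rows)
  rownames(Q) <- sprintf("S%04d", seq_len(nrow(Q)))
  list(Q = Q, class = cls)
}

#' Sample genotypes under the admixture model
#'
#' `g_ij ~ Binomial(2, p_ij)` with `p_ij = sum_k q_ik f_kj`.
#'
#' @param F_true K x m founder frequencies.
#' @param Q_design n x K ancestry rows (on the simplex).
#' @param seed integer seed.
#' @param sample_ids optional ids (default from `rownames(Q_design)`).
#' @return list with `genotypes` (genotype matrix) and `truth`
#'   (list: `F_true`, `Q_true`).
#' @export
simulate_genotypes <- function(F_true, Q_design, seed = 1L, sample_ids = NULL) {
  Q_design <- as.matrix(Q_design)
  stopifnot(ncol(Q_design) == nrow(F_true),
            max(abs(rowSums(Q_design) - 1)) < 1e-8)
  set.seed(seed)
  P <- Q_design %*% F_true
  n <- nrow(P); m <- ncol(P)
  G <- matrix(stats::rbinom(n * m, size = 2L, prob = as.vector(P)), n, m)
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(Q_design))) rownames(Q_design)
                  else sprintf("S%04d", seq_len(n))
  G <- genotype_matrix(G, sample_ids = sample_ids, locus_ids = colnames(F_true))
  list(genotypes = G, truth = list(F_true = F_true, Q_true = Q_design))
}

#' Re-genotype clonal copies with heterozygote-miscall error
#'
#' Each requested copy equals its source genotype except that every
#' heterozygous call is, independently with probability `eps`, flipped to a
#' random homozygote (0 or 2 with equal probability), and every call is
#' masked missing with probability `mu` — the error structure of duplicate
#' DNAs re-genotyped at low read depth.
#'
#' @param G genotype matrix holding the source samples.
#' @param which_samples sample ids (or indices) to copy.
#' @param copies copies per source.
#' @param eps heterozygote miscall probability.
#' @param mu missing probability.
#' @param seed integer seed.
#' @param id_fmt sprintf format for copy ids (source id, copy number).
#' @return list with `genotypes` (copies only, rows named by `id_fmt`) and
#'   `copy_of` (character vector mapping copy id to source id).
#' @export
make_clonal_copies <- function(G, which_samples, copies = 1L, eps = 0.03,
                               mu = 0.02, seed = 1L, id_fmt = "%s_rep%d") {
  validate_genotypes(G)
  stopifnot(eps >= 0, eps < 1, mu >= 0, mu < 1)
  if (is.numeric(which_samples)) which_samples <- rownames(G)[which_samples]
  stopifnot(all(which_samples %in% rownames(G)))
  set.seed(seed)
  out <- list(); copy_of <- character(0)
  for (s in which_samples) {
    for (cp in seq_len(copies)) {
      g <- G[s, ]
      het <- which(!is.na(g) & g == 1L)
      flip <- het[stats::runif(length(het)) < eps]
      if (length(flip))
        g[flip] <- ifelse(stats::runif(length(flip)) < 0.5, 0L, 2L)
      miss <- stats::runif(length(g)) < mu
      g[miss] <- NA_integer_
      id <- sprintf(id_fmt, s, cp)
      out[[id]] <- g
      copy_of[id] <- s
    }
  }
  Gc <- do.call(rbind, out)
  rownames(Gc) <- names(out)
  list(genotypes = genotype_matrix(Gc, locus_ids = colnames(G)),
       copy_of = copy_of)
}

#' Generate a complete synthetic survey scenario
#'
#' Emits a desk-scale study with the full structure the pipeline expects:
#' a reference library of cultivars sampled in duplicate (some cultivars
#' entering the library more than once under different names), field
#' accessions that are clones of library cultivars, clones of cultivars
#' from founders missing from the library, F1 / backcross / multi-founder
#' admixed accessions, genotyping error and missingness on every
#' re-genotyped copy, and farmer names with synonyms and homonyms.
#'
#' @param params [sim_params()].
#' @param dir optional directory; when given, writes `genotypes.tsv`
#'   (dosage_tsv), `metadata.csv` and `truth.json`.
#' @return list of class `sim_scenario`: `genotypes` (all samples),
#'   `meta` (metadata data frame), `truth` (list: `F_true`, `Q_true`,
#'   `genet_of` sample -> cultivar map, `class` per field sample,
#'   `cultivar_founder`, `names_map`, `params`), and `paths` when written.
#' @export
emit_scenario <- function(params = sim_params(), dir = NULL) {
  F_true <- simulate_founders(params)
  K <- params$K_true
  set.seed(params$seed + 1L)

  ## --- cultivars (genets) ---------------------------------------------
  n_cult <- params$n_library_cultivars
  cult_founder <- rep_len(seq_len(params$library_founders), n_cult)
  unrep_founders <- setdiff(seq_len(K), seq_len(params$library_founders))
  n_un <- params$n_unrepresented_genets
  un_founder <- if (n_un > 0 && length(unrep_founders))
    rep_len(unrep_founders, n_un) else integer(0)
  genet_founder <- c(cult_founder, un_founder)
  n_genet <- length(genet_founder)
  Qg <- matrix(0, n_genet, K)
  Qg[cbind(seq_len(n_genet), genet_founder)] <- 1
  genet_ids <- c(sprintf("GEN%03d", seq_len(n_cult)),
                 if (n_un) sprintf("UGEN%02d", seq_len(n_un)))
  rownames(Qg) <- genet_ids
  sim <- simulate_genotypes(F_true, Qg, seed = params$seed + 2L)
  G_genet <- sim$genotypes

  ## --- farmer names: synonyms and homonyms ----------------------------
  set.seed(params$seed + 3L)
  pool <- sprintf("Name%03d", seq_len(5L * n_genet))
  used <- character(0)
  names_map <- vector("list", n_genet)
  for (gi in seq_len(n_genet)) {
    nm <- character(params$synonyms_per_cluster)
    for (s in seq_len(params$synonyms_per_cluster)) {
      if (length(used) && stats::runif(1) < params$homonym_prob) {
        nm[s] <- sample(used, 1L)
      } else {
        fresh <- setdiff(pool, used)
        nm[s] <- fresh[1L]
        used <- c(used, nm[s])
      }
    }
    names_map[[gi]] <- unique(nm)
  }
  names(names_map) <- genet_ids
  released <- c(rep(TRUE, params$n_released),
                rep(FALSE, n_genet - params$n_released))
  released_names <- ifelse(released, sprintf("Released%02d",
                                             cumsum(released)), NA_character_)

  ## --- library accessions, genotyped in duplicate ---------------------
  set.seed(params$seed + 4L)
  acc_genet <- c(seq_len(n_cult),
                 if (params$n_library_accessions > n_cult)
                   sample(n_cult, params$n_library_accessions - n_cult,
                          replace = TRUE))
  lib_rows <- list(); lib_meta <- list()
  for (ai in seq_along(acc_genet)) {
    gi <- acc_genet[ai]
    acc_id <- sprintf("LIB%03d", ai)
    cpy <- make_clonal_copies(G_genet, genet_ids[gi],
                              copies = params$duplicates_per_accession,
                              eps = params$het_miscall_rate,
                              mu = params$missing_rate,
                              seed = params$seed + 100L + ai)
    ids <- sprintf("%s_r%d", acc_id, seq_len(params$duplicates_per_accession))
    rownames(cpy$genotypes) <- ids
    lib_rows[[ai]] <- cpy$genotypes
    lib_meta[[ai]] <- data.frame(
      sample_id = ids, source = "library", duplicate_group = acc_id,
      elicited_name = sample(names_map[[gi]], 1L),
      released_name = released_names[gi],
      household_id = NA_character_, lat = NA_real_, lon = NA_real_,
      genet = genet_ids[gi], stringsAsFactors = FALSE)
  }

  ## --- field accessions ------------------------------------------------
  set.seed(params$seed + 5L)
  field_rows <- list(); field_meta <- list(); field_class <- character(0)
  genet_of <- character(0)
  add_field <- function(gmat, genet, cls, nm, off) {
    ids <- sprintf("FLD%04d", off + seq_len(nrow(gmat)))
    rownames(gmat) <- ids
    field_rows[[length(field_rows) + 1L]] <<- gmat
    field_meta[[length(field_meta) + 1L]] <<- data.frame(
      sample_id = ids, source = "field", duplicate_group = NA_character_,
      elicited_name = nm, released_name = NA_character_,
      household_id = sprintf("HH%04d", off + seq_len(nrow(gmat))),
      lat = NA_real_, lon = NA_real_, genet = genet,
      stringsAsFactors = FALSE)
    field_class <<- c(field_class, rep(cls, nrow(gmat)))
    genet_of <<- c(genet_of, genet)
    off + nrow(gmat)
  }
  off <- 0L
  if (params$n_field_clones > 0) {
    src <- sample(n_cult, params$n_field_clones, replace = TRUE,
                  prob = stats::rgamma(n_cult, shape = 0.7))  # skewed popularity
    for (b in seq_len(params$n_field_clones)) {
      cpy <- make_clonal_copies(G_genet, genet_ids[src[b]], copies = 1L,
                                eps = params$het_miscall_rate,
                                mu = params$missing_rate,
                                seed = params$seed + 2000L + b)
      off <- add_field(cpy$genotypes, genet_ids[src[b]], "clone_of_library",
                       sample(names_map[[src[b]]], 1L), off)
    }
  }
  if (params$n_unrepresented_clones > 0 && n_un > 0) {
    src <- n_cult + rep_len(seq_len(n_un), params$n_unrepresented_clones)
    for (b in seq_along(src)) {
      cpy <- make_clonal_copies(G_genet, genet_ids[src[b]], copies = 1L,
                                eps = params$het_miscall_rate,
                                mu = params$missing_rate,
                                seed = params$seed + 6000L + b)
      off <- add_field(cpy$genotypes, genet_ids[src[b]], "clone_unrepresented",
                       sample(names_map[[src[b]]], 1L), off)
    }
  }
  n_adm <- params$n_f1 + params$n_backcross + params$n_multi
  if (n_adm > 0) {
    des <- admixture_design(K, 0L, params$n_f1, params$n_backcross,
                            params$n_multi, seed = params$seed + 7L)
    simA <- simulate_genotypes(F_true, des$Q, seed = params$seed + 8L)
    Ga <- simA$genotypes
    cls <- c(rep("f1", params$n_f1), rep("backcross", params$n_backcross),
             rep("multi", params$n_multi))
    for (b in seq_len(nrow(Ga))) {
      g1 <- Ga[b, , drop = FALSE]
      rownames(g1) <- "tmp"
      off <- add_field(g1, NA_character_, cls[b],
                       sprintf("Hybrid%03d", b), off)
    }
    Q_adm <- des$Q
  } else Q_adm <- NULL

  ## --- assemble --------------------------------------------------------
  G_all <- rbind(do.call(rbind, lib_rows), do.call(rbind, field_rows))
  G_all <- genotype_matrix(G_all, locus_ids = colnames(F_true))
  meta <- do.call(rbind, c(lib_meta, field_meta))
  # true ancestry of every emitted sample
  Q_true <- matrix(0, nrow(G_all), K,
                   dimnames = list(rownames(G_all), rownames(F_true)))
  gm <- meta$genet[match(rownames(G_all), meta$sample_id)]
  has_genet <- !is.na(gm)
  Q_true[has_genet, ] <- Qg[gm[has_genet], ]
  if (!is.null(Q_adm)) {
    adm_ids <- meta$sample_id[meta$source == "field"][field_class %in%
                                                        c("f1", "backcross", "multi")]
    Q_true[adm_ids, ] <- Q_adm
  }
  truth <- list(F_true = F_true, Q_true = Q_true,
                genet_of = stats::setNames(gm, rownames(G_all)),
                class = stats::setNames(
                  c(rep("library", sum(meta$source == "library")), field_class),
                  rownames(G_all)),
                cultivar_founder = stats::setNames(genet_founder, genet_ids),
                released_name = stats::setNames(released_names, genet_ids),
                names_map = names_map, params = unclass(params))
  out <- list(genotypes = G_all, meta = meta[, setdiff(names(meta), "genet")],
              meta_full = meta, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(genotypes = file.path(dir, "genotypes.tsv"),
                  metadata = file.path(dir, "metadata.csv"),
                  truth = file.path(dir, "truth.json"))
    write_genotype_table(G_all, paths$genotypes)
    write_sample_metadata(out$meta, paths$metadata)
    jsonlite::write_json(
      list(F_true = F_true, Q_true = Q_true,
           genet_of = as.list(truth$genet_of), class = as.list(truth$class),
           cultivar_founder = as.list(truth$cultivar_founder),
           names_map = truth$names_map, params = unclass(params)),
      paths$truth, digits = NA, auto_unbox = TRUE, pretty = FALSE, na = "null")
    out$paths <- paths
  }
  class(out) <- "sim_scenario"
  out
}
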