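#' Pairwise identity-by-state distance
#'
#' For samples a and b the distance is the mean, over jointly non-missing
#' loci, of `|g_a - g_b| / 2`, i.e. 1 minus the allele-sharing IBS
#' similarity.  Distances are computed on the raw (pre-imputation) calls by
#' design: imputation would artificially shrink the distance between
#' re-genotyped duplicates, biasing the identity-threshold calibration.
#'
#' @param G genotype matrix with at least two samples.
#' @return list of class `ibs_dist` with `sample_ids`, `d` (symmetric n x n
#'   matrix in `[0, 1]`, zero diagonal) and `n_shared` (loci used per pair).
#' @export
ibs_distance <- function(G) {
  validate_genotypes(G)
  if (nrow(G) < 2) stop("need at least two samples")
  cross <- .ibs_cross(G, G)
  if (any(cross$n_shared[upper.tri(cross$n_shared)] == 0)) {
    idx <- which(cross$n_shared == 0 & upper.tri(cross$n_shared), arr.ind = TRUE)[1, ]
    stop("samples ", rownames(G)[idx[1]], " and ", rownames(G)[idx[2]],
         " share no jointly genotyped locus")
  }
  d <- cross$num / (2 * cross$n_shared)
  diag(d) <- 0
  d <- (d + t(d)) / 2  # enforce exact symmetry against fp noise
  structure(list(sample_ids = rownames(G), d = d, n_shared = cross$n_shared),
            class = "ibs_dist")
}

# Manhattan dosage mismatch counts between the rows of Ga and the rows of Gb,
# on pairwise-complete loci, via indicator-matrix products:
# |a-b| = (a-b)^2 - 2*[{a,b} = {0,2}].
.ibs_cross <- function(Ga, Gb) {
  Ma <- !is.na(Ga); Mb <- !is.na(Gb)
  Xa <- Ga; Xa[!Ma] <- 0L; Xb <- Gb; Xb[!Mb] <- 0L
  storage.mode(Xa) <- "double"; storage.mode(Xb) <- "double"
  Ma <- Ma * 1; Mb <- Mb * 1
  sq <- (Xa^2) %*% t(Mb) - 2 * Xa %*% t(Xb) + Ma %*% t(Xb^2)
  I2a <- (Xa == 2) * 1; I2b <- (Xb == 2) * 1
  I0a <- Ma * (Xa == 0); I0b <- Mb * (Xb == 0)
  num <- sq - 2 * (I0a %*% t(I2b) + I2a %*% t(I0b))
  list(num = num, n_shared = Ma %*% t(Mb))
}

#' Identity-by-state distances between two genotype sets
#'
#' Cross-distance used when matching field accessions against a collapsed
#' reference library.  Same definition as [ibs_distance()].
#'
#' @param Ga,Gb genotype matrices sharing a locus set (intersected by id).
#' @return list with `d` (`nrow(Ga)` x `nrow(Gb)`) and `n_shared`.
#' @export
ibs_cross_distance <- function(Ga, Gb) {
  validate_genotypes(Ga); validate_genotypes(Gb)
  shared <- intersect(colnames(Ga), colnames(Gb))
  if (!length(shared)) stop("genotype sets share no locus")
  cross <- .ibs_cross(Ga[, shared, drop = FALSE], Gb[, shared, drop = FALSE])
  if (any(cross$n_shared == 0)) stop("a sample pair shares no genotyped locus")
  d <- cross$num / (2 * cross$n_shared)
  dimnames(d) <- list(rownames(Ga), rownames(Gb))
  list(d = d, n_shared = cross$n_shared)
}

#' Ward minimum-variance dendrogram from an IBS distance matrix
#'
#' Agglomerates with the Lance-Williams update on squared distances
#' (`stats::hclust(method = "ward.D2")`): merge heights are non-decreasing
#' and the input distances are used as-is even though IBS distances are not
#' guaranteed Euclidean.
#'
#' @param D [ibs_distance()] result (or a square symmetric matrix).
#' @return `hclust` object labelled with sample ids.
#' @export
ward_tree <- function(D) {
  d <- if (inherits(D, "ibs_dist")) D$d else D
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  stats::hclust(stats::as.dist(d), method = "ward.D2")
}

#' Export a dendrogram as Newick
#' @param tree `hclust` from [ward_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Calibrate the clonal-identity distance threshold from library duplicates
#'
#' Re-genotyped DNAs of the same library clone differ only by genotyping
#' error (chiefly heterozygotes miscalled as homozygotes at low read depth),
#' so the distribution of duplicate-pair distances measures the error floor.
#' The threshold is `safety_factor` times the largest duplicate-pair
#' distance, rounded up to two decimals; pairs of samples closer than this
#' are declared the same clone.
#'
#' @param D [ibs_distance()] over all samples (or the library subset).
#' @param meta metadata data frame with `sample_id`, `source`,
#'   `duplicate_group` (see [read_sample_metadata()]).
#' @param safety_factor multiplier on the maximum duplicate distance.
#' @return list of class `identity_threshold` with `value`,
#'   `duplicate_distances`, `rule`, `safety_factor`.
#' @export
calibrate_threshold <- function(D, meta, safety_factor = 1.25) {
  stopifnot(inherits(D, "ibs_dist"))
  lib <- meta[!is.na(meta$duplicate_group) & meta$source == "library", , drop = FALSE]
  groups <- split(lib$sample_id, lib$duplicate_group)
  groups <- lapply(groups, intersect, D$sample_ids)
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups))
    stop("no duplicate pairs found in metadata; set the identity threshold manually")
  idx <- match(unlist(groups, use.names = FALSE), D$sample_ids)
  dup_d <- unlist(lapply(groups, function(g) {
    i <- match(g, D$sample_ids)
    D$d[i, i][upper.tri(diag(length(i)))]
  }), use.names = FALSE)
  value <- ceiling(safety_factor * max(dup_d) * 100) / 100
  # smallest distance between samples of *different* duplicate groups
  grp_of <- rep(names(groups), lengths(groups))
  between <- D$d[idx, idx]
  same <- outer(grp_of, grp_of, "==")
  between_min <- suppressWarnings(min(between[!same & upper.tri(same)]))
  if (is.finite(between_min) && value >= between_min)
    warning(sprintf(paste0("calibrated threshold %.2f is not below the smallest ",
                           "between-clone library distance %.4f; distinct clones ",
                           "may be merged"), value, between_min))
  if (value == 0)
    warning("degenerate calibration: duplicate distances are all zero")
  structure(list(value = value, duplicate_distances = dup_d,
                 rule = sprintf("ceil2(%g * max duplicate distance)", safety_factor),
                 safety_factor = safety_factor),
            class = "identity_threshold")
}

#' Manually specified identity threshold
#' @param value distance below which two samples are the same clone.
#' @return `identity_threshold` object.
#' @export
identity_threshold <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, value >= 0)
  structure(list(value = value, duplicate_distances = numeric(0),
                 rule = "manual", safety_factor = NA_real_),
            class = "identity_threshold")
}

#' Partition samples into clone groups at the identity threshold
#'
#' Two grouping rules are offered.  `components` (default) takes connected
#' components of the graph whose edges join pairs with `d < t`; `tree_cut`
#' cuts the Ward dendrogram at height `t`.  The rules can diverge on chains
#' (a-b and b-c close, a-c not): components merges all three, a dendrogram
#' cut may not.  The group representative is the member with the fewest
#' missing calls (ties broken lexicographically by sample id).
#'
#' @param D [ibs_distance()] result.
#' @param t [identity_threshold()] / [calibrate_threshold()] result, or a number.
#' @param rule `"components"` or `"tree_cut"`.
#' @param G optional genotype matrix used to count missing calls for the
#'   representative choice.
#' @return data frame of class `clone_assignment` with columns `sample_id`,
#'   `clone_group` (integer id), `representative` (logical).
#' @export
clone_groups <- function(D, t, rule = c("components", "tree_cut"), G = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(D, "ibs_dist"))
  tv <- if (inherits(t, "identity_threshold")) t$value else t
  n <- length(D$sample_ids)
  if (rule == "components") {
    adj <- D$d < tv
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
  } else {
    memb <- if (n >= 2) stats::cutree(ward_tree(D), h = tv) else 1L
  }
  # renumber groups by first appearance for determinism
  memb <- match(memb, unique(memb))
  rep_flag <- logical(n)
  n_miss <- if (is.null(G)) rep(0L, n) else rowSums(is.na(G))[D$sample_ids]
  for (gid in unique(memb)) {
    members <- which(memb == gid)
    ord <- members[order(n_miss[members], D$sample_ids[members])]
    rep_flag[ord[1]] <- TRUE
  }
  structure(data.frame(sample_id = D$sample_ids, clone_group = memb,
                       representative = rep_flag, stringsAsFactors = FALSE),
            class = c("clone_assignment", "data.frame"))
}

#' Collapse a duplicated reference library into unique cultivars
#'
#' Groups library samples into clones at the identity threshold and keeps
#' one representative genotype per clone; all member names are recorded as
#' synonyms.  Conflicting released-variety names inside one group are kept
#' and flagged rather than discarded.
#'
#' @param G_lib genotype matrix of library samples only.
#' @param t identity threshold.
#' @param meta optional metadata (for names and status).
#' @param rule grouping rule, as in [clone_groups()].
#' @return list of class `clone_library`: `genotypes` (one row per cultivar),
#'   `cultivars` data frame (`cultivar_id`, `representative`, `members`,
#'   `released_name`, `synonyms`, `status`, `name_conflict`).
#' @export
collapse_library <- function(G_lib, t, meta = NULL, rule = "components") {
  D <- ibs_distance(G_lib)
  asg <- clone_groups(D, t, rule = rule, G = G_lib)
  groups <- split(asg$sample_id, asg$clone_group)
  reps <- asg$sample_id[asg$representative]
  reps <- reps[order(asg$clone_group[asg$representative])]
  info <- lapply(seq_along(groups), function(gid) {
    members <- groups[[gid]]
    rel <- syn <- character(0)
    if (!is.null(meta)) {
      mm <- meta[match(members, meta$sample_id), , drop = FALSE]
      rel <- unique(stats::na.omit(mm$released_name))
      syn <- unique(stats::na.omit(c(mm$released_name, mm$elicited_name)))
    }
    data.frame(cultivar_id = sprintf("CV%03d", gid),
               representative = reps[gid],
               members = paste(members, collapse = ";"),
               released_name = if (length(rel)) paste(rel, collapse = ";") else NA_character_,
               synonyms = paste(syn, collapse = ";"),
               status = if (length(rel)) "released" else "landrace",
               name_conflict = length(rel) > 1,
               stringsAsFactors = FALSE)
  })
  cultivars <- do.call(rbind, info)
  structure(list(genotypes = G_lib[reps, , drop = FALSE],
                 cultivars = cultivars, threshold = t),
            class = "clone_library")
}

#' Match field accessions to a collapsed reference library
#'
#' Each field accession is assigned the nearest library cultivar if and only
#' if that IBS distance is below the identity threshold; ties go to the
#' lowest distance, then to library order.  Accessions with no library
#' representative within the threshold are labelled `NA` (unknown variety).
#'
#' @param G_field genotype matrix of field accessions.
#' @param library `clone_library` from [collapse_library()].
#' @param t identity threshold (defaults to the one stored in `library`).
#' @return data frame with `sample_id`, `matched_cultivar` (`NA` if none),
#'   `matched_distance`, `matched_representative`.
#' @export
match_to_library <- function(G_field, library, t = library$threshold) {
  stopifnot(inherits(library, "clone_library"))
  tv <- if (inherits(t, "identity_threshold")) t$value else t
  cross <- ibs_cross_distance(G_field, library$genotypes)
  best <- apply(cross$d, 1, which.min)
  best_d <- cross$d[cbind(seq_len(nrow(cross$d)), best)]
  hit <- best_d < tv
  data.frame(sample_id = rownames(G_field),
             matched_cultivar = ifelse(hit, library$cultivars$cultivar_id[best], NA),
             matched_distance = best_d,
             matched_representative = ifelse(hit, library$cultivars$representative[best], NA),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a distance matrix as square TSV
#' @param D [ibs_distance()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  m <- D$d
  dimnames(m) <- list(D$sample_ids, D$sample_ids)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
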