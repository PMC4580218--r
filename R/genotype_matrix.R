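#' Construct and validate a genotype dosage matrix
#'
#' The package's central container is a plain integer matrix of alt-allele
#' dosages (0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate) with samples in rows and loci in columns.  Missing calls are
#' `NA`; `is.na(G)` is the missing mask.  Row names are sample ids and column
#' names are locus ids, both required and unique.
#'
#' @param dosage numeric/integer matrix with values in \{0, 1, 2\} or `NA`.
#' @param sample_ids optional character vector of row names (taken from
#'   `rownames(dosage)` when omitted).
#' @param locus_ids optional character vector of column names.
#' @return validated integer matrix with dimnames.
#' @export
genotype_matrix <- function(dosage, sample_ids = NULL, locus_ids = NULL) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  if (!is.null(sample_ids)) rownames(dosage) <- sample_ids
  if (!is.null(locus_ids)) colnames(dosage) <- locus_ids
  storage.mode(dosage) <- "integer"
  validate_genotypes(dosage)
  dosage
}

#' Validate genotype matrix invariants
#'
#' Checks that dimnames exist and are unique and that every non-missing
#' entry is 0, 1 or 2.  Called at the entry points of all analysis
#' functions; invalid input is an error, never silently coerced.
#'
#' @param G genotype matrix as built by [genotype_matrix()].
#' @return `G`, invisibly.
#' @export
validate_genotypes <- function(G) {
  if (!is.matrix(G)) stop("genotype input must be a matrix")
  if ((nrow(G) > 0 && is.null(rownames(G))) ||
      (ncol(G) > 0 && is.null(colnames(G))))
    stop("genotype matrix must carry sample ids (rownames) and locus ids (colnames)")
  if (anyDuplicated(rownames(G)))
    stop("duplicate sample id(s): ",
         paste(unique(rownames(G)[duplicated(rownames(G))]), collapse = ", "))
  if (anyDuplicated(colnames(G)))
    stop("duplicate locus id(s): ",
         paste(unique(colnames(G)[duplicated(colnames(G))]), collapse = ", "))
  v <- G[!is.na(G)]
  if (length(v) && !all(v == 0L | v == 1L | v == 2L))
    stop("genotype dosages must be 0, 1 or 2 (or NA for missing)")
  invisible(G)
}

#' Missing mask of a genotype matrix
#' @param G genotype matrix.
#' @return logical matrix, `TRUE` where the call is missing.
#' @export
missing_mask <- function(G) is.na(G)
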