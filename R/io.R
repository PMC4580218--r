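#' Read a genotype table
#'
#' Two tab-separated dialects are supported.
#'
#' * `dosage_tsv`: row 1 is `sample_id` followed by locus ids; one row per
#'   sample; cells are `0`, `1`, `2` or `NA`.
#' * `hapmap_like`: one row per locus with columns `rs`, `alleles` (e.g.
#'   `"A/G"`, ref/alt), `chrom`, `pos`, then one column per sample holding a
#'   two-letter diploid genotype (`"AA"`, `"AG"`, ...); `"NN"` (or `NA`) is
#'   missing.  Dosage is the count of the alternate (second) allele.
#'
#' @param path file path.
#' @param dialect `"dosage_tsv"` (default) or `"hapmap_like"`.
#' @param strict if `TRUE` (default) any unrecognized code is an error; if
#'   `FALSE` unrecognized codes become missing.
#' @return genotype matrix (see [genotype_matrix()]).
#' @export
read_genotype_table <- function(path, dialect = c("dosage_tsv", "hapmap_like"),
                                strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1]))
    stop("ragged rows in ", path, " (row ",
         which(ncols != ncols[1])[1], " has ", ncols[which(ncols != ncols[1])[1]],
         " fields, expected ", ncols[1], ")")
  header <- fields[[1]]
  body <- fields[-1]

  if (dialect == "dosage_tsv") {
    locus_ids <- header[-1]
    sample_ids <- vapply(body, `[[`, character(1), 1L)
    cells <- if (length(body)) {
      matrix(unlist(lapply(body, `[`, -1L)), nrow = length(body), byrow = TRUE)
    } else {
      matrix(character(0), nrow = 0, ncol = length(locus_ids))
    }
    dos <- .decode_dosage_cells(cells, strict)
  } else {
    if (length(header) < 5L)
      stop("hapmap_like file needs columns rs, alleles, chrom, pos plus samples")
    sample_ids <- header[-(1:4)]
    locus_ids <- vapply(body, `[[`, character(1), 1L)
    alleles <- strsplit(vapply(body, `[[`, character(1), 2L), "/", fixed = TRUE)
    bad <- lengths(alleles) != 2L
    if (any(bad)) stop("malformed alleles field at locus ", locus_ids[which(bad)[1]])
    dos <- matrix(NA_integer_, nrow = length(sample_ids), ncol = length(body))
    for (j in seq_along(body)) {
      alt <- alleles[[j]][2]
      gt <- body[[j]][-(1:4)]
      d <- vapply(strsplit(gt, ""), function(ch) {
        if (length(ch) != 2L || any(ch == "N")) return(NA_integer_)
        sum(ch == alt)
      }, integer(1))
      known <- gt %in% c("NN", "NA", "") |
        vapply(strsplit(gt, ""), function(ch)
          length(ch) == 2L && all(ch %in% alleles[[j]]), logical(1))
      if (strict && !all(known))
        stop("unrecognized genotype code '", gt[!known][1], "' at locus ",
             locus_ids[j])
      d[!known] <- NA_integer_
      dos[, j] <- d
    }
  }
  genotype_matrix(dos, sample_ids = sample_ids, locus_ids = locus_ids)
}

.decode_dosage_cells <- function(cells, strict) {
  dos <- matrix(NA_integer_, nrow = nrow(cells), ncol = ncol(cells))
  if (!length(cells)) return(dos)
  ok0 <- cells == "0"; ok1 <- cells == "1"; ok2 <- cells == "2"
  miss <- cells == "NA" | cells == ""
  bad <- !(ok0 | ok1 | ok2 | miss)
  if (any(bad)) {
    if (strict) stop("unrecognized dosage code '", cells[bad][1],
                     "' (strict mode; use strict = FALSE to treat as missing)")
    miss <- miss | bad
  }
  dos[ok0 & !miss] <- 0L; dos[ok1 & !miss] <- 1L; dos[ok2 & !miss] <- 2L
  dos
}

#' Write a genotype table in the dosage_tsv dialect
#'
#' Lossless inverse of [read_genotype_table()]: missing calls are written as
#' `NA`.  Output is deterministic (byte-identical across repeated writes).
#'
#' @param G genotype matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(G, path) {
  validate_genotypes(G)
  ch <- matrix(as.character(G), nrow = nrow(G))
  ch[is.na(ch)] <- "NA"
  body <- vapply(seq_len(nrow(G)), function(i)
    paste(c(rownames(G)[i], ch[i, ]), collapse = "\t"), character(1))
  rows <- c(paste(c("sample_id", colnames(G)), collapse = "\t"), body)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(rows, con)
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with header; required column `sample_id`, optional columns `source`
#' (`"field"` or `"library"`), `duplicate_group` (shared by re-genotyped DNAs
#' of the same library clone), `elicited_name` (farmer-given), `released_name`,
#' `household_id`, `lat`, `lon`.  Empty cells become `NA`.
#'
#' @param path CSV path.
#' @return data frame with one row per sample; character columns except
#'   `lat`/`lon` (numeric).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = c("", "NA"))
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyNA(df$sample_id)) stop("missing sample_id in metadata row ",
                                which(is.na(df$sample_id))[1])
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1])
  if ("source" %in% names(df)) {
    bad <- !is.na(df$source) & !df$source %in% c("field", "library")
    if (any(bad)) stop("unknown source value '", df$source[bad][1],
                       "' (expected 'field' or 'library')")
    if ("duplicate_group" %in% names(df)) {
      offside <- !is.na(df$duplicate_group) & df$source != "library"
      if (any(offside))
        stop("duplicate_group set for non-library sample ",
             df$sample_id[offside][1])
    }
  }
  for (nm in intersect(c("lat", "lon"), names(df))) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Write sample metadata CSV
#' @param meta data frame as returned by [read_sample_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, na = "")
  invisible(path)
}
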