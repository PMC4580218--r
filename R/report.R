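#' Classify samples by ancestry composition
#'
#' Mutually exclusive, exhaustive classes from the ancestry matrix:
#' `pure` when the largest ancestry fraction exceeds `pure_threshold`
#' (strictly), `half_hybrid` when it is at least `half_threshold` but does
#' not exceed `pure_threshold` (boundary values 0.50 and 0.90 both fall in
#' this class), `multi` otherwise.
#'
#' @param Q n x K ancestry matrix (rows on the simplex).
#' @param pure_threshold purity cut (default 0.90, exclusive).
#' @param half_threshold major-ancestry cut (default 0.50, inclusive).
#' @return data frame with `sample_id`, `class`, `major_ancestry` (column
#'   index of the largest fraction), `major_fraction`.
#' @export
classify_ancestry <- function(Q, pure_threshold = 0.90, half_threshold = 0.50) {
  Q <- as.matrix(Q)
  mx <- apply(Q, 1, max)
  major <- apply(Q, 1, which.max)
  cls <- ifelse(mx > pure_threshold, "pure",
                ifelse(mx >= half_threshold, "half_hybrid", "multi"))
  data.frame(sample_id = if (is.null(rownames(Q))) as.character(seq_len(nrow(Q)))
                         else rownames(Q),
             class = factor(cls, levels = c("pure", "half_hybrid", "multi")),
             major_ancestry = major, major_fraction = mx,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the per-accession variety report
#'
#' Joins the clone-group assignment, the library match and the ancestry
#' classification for the field accessions.
#'
#' @param assignment `clone_assignment` over field samples ([clone_groups()]).
#' @param matches [match_to_library()] result.
#' @param classes [classify_ancestry()] result for the same samples.
#' @param meta optional metadata (adds `elicited_name`).
#' @return data frame of class `variety_report`, one row per field accession.
#' @export
variety_report <- function(assignment, matches, classes, meta = NULL) {
  out <- merge(assignment[, c("sample_id", "clone_group")],
               matches[, c("sample_id", "matched_cultivar", "matched_distance")],
               by = "sample_id", all.x = TRUE)
  out <- merge(out, classes, by = "sample_id", all.x = TRUE)
  if (!is.null(meta) && "elicited_name" %in% names(meta))
    out$elicited_name <- meta$elicited_name[match(out$sample_id, meta$sample_id)]
  out <- out[order(out$clone_group, out$sample_id), ]
  rownames(out) <- NULL
  class(out) <- c("variety_report", "data.frame")
  out
}

#' Cross-tabulate genetic clusters against farmer-elicited names
#'
#' Measures the mismatch between genetic identity and the local naming
#' system: synonymy (one genetic cluster carrying several names) and
#' homonymy (one name applied to several distinct clusters).  Names rarer
#' than `min_name_count` across the sample are dropped first.
#'
#' @param report `variety_report` (needs `clone_group`, `elicited_name`).
#' @param min_name_count minimum occurrences for a name to be tabulated.
#' @return list of class `name_correspondence`: `table` (cluster x name
#'   counts), `synonyms_per_cluster` (named integer vector), `homonyms_per_name`
#'   (distinct clusters per name), `n_tabulated`.
#' @export
name_correspondence <- function(report, min_name_count = 10L) {
  ok <- !is.na(report$elicited_name)
  if (!any(ok)) stop("no accession carries an elicited name")
  df <- report[ok, , drop = FALSE]
  keep_names <- names(which(table(df$elicited_name) >= min_name_count))
  df <- df[df$elicited_name %in% keep_names, , drop = FALSE]
  tab <- table(cluster = df$clone_group, name = df$elicited_name)
  structure(list(table = tab,
                 synonyms_per_cluster = apply(tab > 0, 1, sum),
                 homonyms_per_name = apply(tab > 0, 2, sum),
                 n_tabulated = sum(tab)),
            class = "name_correspondence")
}

#' Summary table of the variety-identification effort
#'
#' One row per matched variety (descending accession count, roman numerals
#' assigned in that order), then one row per half-hybrid major-ancestry
#' group, then a single multi-ancestry row.  Pure rows count only accessions
#' classified `pure`; the hybrid rows count `half_hybrid` accessions by
#' their major ancestry, so the classes never overlap.
#'
#' @param report `variety_report`.
#' @param library `clone_library` (for released/landrace status and names).
#' @return data frame with `variety`, `n_accessions`, `status`, `names`.
#' @export
summarize_varieties <- function(report, library = NULL) {
  pure <- report[report$class == "pure", , drop = FALSE]
  rows <- list()
  if (nrow(pure)) {
    by_cult <- split(pure, ifelse(is.na(pure$matched_cultivar), "none",
                                  pure$matched_cultivar))
    counts <- vapply(by_cult, nrow, integer(1))
    ord <- names(sort(counts, decreasing = TRUE))
    for (i in seq_along(ord)) {
      cult <- ord[i]
      sub <- by_cult[[cult]]
      if (cult == "none") {
        status <- "not_in_library"; nms <- .common_names(sub)
      } else if (!is.null(library)) {
        rec <- library$cultivars[library$cultivars$cultivar_id == cult, ]
        status <- rec$status
        nms <- if (nzchar(rec$synonyms)) rec$synonyms else .common_names(sub)
      } else {
        status <- "matched"; nms <- .common_names(sub)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variety = paste("Variety", .roman(i)),
        n_accessions = nrow(sub), status = status, names = nms,
        stringsAsFactors = FALSE)
    }
  }
  half <- report[report$class == "half_hybrid", , drop = FALSE]
  if (nrow(half)) {
    for (k in sort(unique(half$major_ancestry))) {
      sub <- half[half$major_ancestry == k, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        variety = sprintf("50%% ancestry from group %d", k),
        n_accessions = nrow(sub),
        status = "hybrid", names = .common_names(sub),
        stringsAsFactors = FALSE)
    }
  }
  multi <- report[report$class == "multi", , drop = FALSE]
  if (nrow(multi))
    rows[[length(rows) + 1L]] <- data.frame(
      variety = "Multi-ancestry clones", n_accessions = nrow(multi),
      status = "hybrid", names = .common_names(multi),
      stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.common_names <- function(df, top = 3L) {
  if (!"elicited_name" %in% names(df)) return(NA_character_)
  nm <- df$elicited_name[!is.na(df$elicited_name)]
  if (!length(nm)) return(NA_character_)
  paste(names(sort(table(nm), decreasing = TRUE))[seq_len(min(top, length(unique(nm))))],
        collapse = ";")
}

.roman <- function(i) as.character(utils::as.roman(i))
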