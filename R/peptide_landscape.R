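#' Peptides detected only in tumour assays
#'
#' A peptide is tumour-only if it was detected in at least one tumour assay
#' and in zero cell-line assays; detection is strictly presence/absence (a
#' single cell-line detection excludes the peptide regardless of how often
#' it was seen in tumours).
#'
#' @param table a [peptide_evidence()] data.frame.
#' @param annotation an [assay_annotation()] covering the table's assays.
#' @return character vector of peptide sequences (sorted).
#' @export
tumour_only_peptides <- function(table, annotation) {
  stopifnot(inherits(table, "peptide_evidence"))
  orphans <- setdiff(unique(table$assay_id), annotation$assay_id)
  if (length(orphans))
    stop("assays missing from the annotation: ", paste(orphans, collapse = ", "))
  if (nrow(table) == 0) return(character())
  type <- annotation$sample_type[match(table$assay_id, annotation$assay_id)]
  det <- table[table$detected, , drop = FALSE]
  dtype <- type[table$detected]
  in_tumour <- unique(det$peptide_sequence[dtype == "tumour"])
  in_cell <- unique(det$peptide_sequence[dtype == "cell_line"])
  sort(setdiff(in_tumour, in_cell))
}

#' Keep peptides mapping to exactly one protein
#'
#' @param peptides character vector of peptide sequences.
#' @param table a [peptide_evidence()] data.frame giving the mapped protein
#'   set of each peptide.
#' @return the subset of `peptides` whose mapped protein set has
#'   cardinality 1 (sorted).
#' @export
unique_mapping_filter <- function(peptides, table) {
  stopifnot(inherits(table, "peptide_evidence"))
  if (!length(peptides)) return(character())
  maps <- .peptide_protein_sets(table)
  keep <- vapply(peptides, function(p) {
    s <- maps[[p]]
    !is.null(s) && length(s) == 1L
  }, logical(1))
  sort(peptides[keep])
}

# peptide -> union of mapped protein ids over all its rows
.peptide_protein_sets <- function(table) {
  sets <- .split_proteins(table$proteins)
  pep <- rep(table$peptide_sequence, lengths(sets))
  lapply(split(unlist(sets), pep), unique)
}

#' Tumour-specific proteins
#'
#' Proteins carrying at least one uniquely mapping tumour-only peptide and
#' having *no peptide evidence of any kind* (unique, shared or ambiguous)
#' in any cell-line assay.
#'
#' @param unique_peptides uniquely mapping tumour-only peptides, as from
#'   [unique_mapping_filter()].
#' @param table a [peptide_evidence()] data.frame.
#' @param annotation an [assay_annotation()].
#' @return character vector of protein ids (sorted).
#' @export
tumour_specific_proteins <- function(unique_peptides, table, annotation) {
  stopifnot(inherits(table, "peptide_evidence"))
  if (!length(unique_peptides)) return(character())
  maps <- .peptide_protein_sets(table)
  candidates <- unique(unlist(maps[unique_peptides]))
  type <- annotation$sample_type[match(table$assay_id, annotation$assay_id)]
  cell_rows <- table$detected & type == "cell_line"
  cell_evidenced <- unique(unlist(.split_proteins(table$proteins[cell_rows])))
  sort(setdiff(candidates, cell_evidenced))
}

#' Proteins detected in the majority of samples of each group
#'
#' Per group, returns the proteins detected in at least half of that
#' group's samples (inclusive boundary: 2 of 4 counts). Detection means at
#' least one observed value (matrix mode) or at least one detected peptide
#' (evidence-table mode).
#'
#' @param x an [intensity_matrix()] or a [peptide_evidence()] data.frame.
#' @param annotation an [assay_annotation()].
#' @param group_by annotation column defining the groups.
#' @param threshold majority fraction, inclusive (default 0.5).
#' @return named list, group -> character vector of protein ids.
#' @export
majority_detection <- function(x, annotation, group_by = "lineage",
                               threshold = 0.5) {
  if (!group_by %in% names(annotation))
    stop("unknown grouping column '", group_by, "'")
  if (inherits(x, "intensity_matrix")) {
    ann <- .match_annotation(x, annotation)
    v <- intensity_values(x)
    det <- !is.na(v)  # proteins x assays
    groups <- split(seq_len(ncol(v)), ann[[group_by]])
    out <- lapply(groups, function(cols) {
      frac <- rowMeans(det[, cols, drop = FALSE])
      sort(rownames(v)[frac >= threshold])
    })
  } else if (inherits(x, "peptide_evidence")) {
    det <- x[x$detected, , drop = FALSE]
    grp <- annotation[[group_by]][match(det$assay_id, annotation$assay_id)]
    if (anyNA(grp))
      stop("assays missing from the annotation: ",
           paste(unique(det$assay_id[is.na(grp)]), collapse = ", "))
    samp <- annotation$sample_id[match(det$assay_id, annotation$assay_id)]
    group_sizes <- tapply(annotation$sample_id, annotation[[group_by]],
                          function(s) length(unique(s)))
    sets <- .split_proteins(det$proteins)
    long <- data.frame(protein = unlist(sets),
                       sample = rep(samp, lengths(sets)),
                       group = rep(grp, lengths(sets)),
                       stringsAsFactors = FALSE)
    long <- unique(long)
    out <- lapply(stats::setNames(nm = names(group_sizes)), function(g) {
      sub <- long[long$group == g, , drop = FALSE]
      if (!nrow(sub)) return(character())
      counts <- table(sub$protein)
      sort(names(counts)[counts / group_sizes[[g]] >= threshold])
    })
  } else stop("x must be an intensity_matrix or a peptide_evidence table")
  out
}

#' Exclusive intersection counts of per-group protein sets
#'
#' UpSet semantics: each element is counted in exactly one combination, the
#' set of all groups that contain it; the counts therefore sum to the size
#' of the union.
#'
#' @param sets named list of character vectors.
#' @return data.frame with `combination` (group names joined by `"&"`) and
#'   `count`, ordered by decreasing count.
#' @export
intersection_counts <- function(sets) {
  if (!length(sets)) stop("at least one group set is required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named by group")
  elements <- unique(unlist(sets))
  if (!length(elements))
    return(data.frame(combination = character(), count = integer(),
                      stringsAsFactors = FALSE))
  member <- vapply(sets, function(s) elements %in% s, logical(length(elements)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  combo <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(combo)
  out <- data.frame(combination = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$combination), , drop = FALSE]
}
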