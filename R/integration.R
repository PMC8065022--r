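#' Merge separately processed cell-line and tumour matrices by razor protein
#'
#' The two sides are normalized independently (batch correction is only
#' possible within each side) and then merged on the leading razor protein
#' accession in two passes: exact accession match first, then with isoform
#' suffixes (`"-<n>"`) stripped for ids that did not match exactly. Proteins
#' found on one side only are kept with missing values on the absent side;
#' no quantification value is altered.
#'
#' If two protein groups on one side collapse to the same razor id after
#' stripping, the group with the larger total observed intensity is kept
#' (logged in the provenance table).
#'
#' @param cell_matrix,tumour_matrix [intensity_matrix()]es at stage
#'   `batch_corrected`.
#' @param cell_gene_map,tumour_gene_map data.frames mapping
#'   `protein_group_id` to `leading_razor_protein` (as from
#'   [read_protein_groups()]); `NULL` means the row ids are already razor
#'   accessions.
#' @return list of class `merged_landscape`: `matrix` (union proteins x all
#'   assays, stage `batch_corrected`), `intersection_ids`, `union_ids`,
#'   `provenance` (protein, razor id, side(s), match pass).
#' @export
merge_by_razor <- function(cell_matrix, tumour_matrix,
                           cell_gene_map = NULL, tumour_gene_map = NULL) {
  .check_stage(cell_matrix, "batch_corrected", "merge_by_razor")
  .check_stage(tumour_matrix, "batch_corrected", "merge_by_razor")
  if (nrow(intensity_values(cell_matrix)) == 0 &&
      nrow(intensity_values(tumour_matrix)) == 0)
    stop("both inputs are empty")
  shared_assays <- intersect(assay_ids(cell_matrix), assay_ids(tumour_matrix))
  if (length(shared_assays))
    stop("assays appear on both sides: ", paste(shared_assays, collapse = ", "))

  side <- function(x, map) {
    v <- intensity_values(x)
    razor <- if (is.null(map)) rownames(v) else
      map$leading_razor_protein[match(rownames(v), map$protein_group_id)]
    if (anyNA(razor)) stop("gene map does not cover every protein group")
    # within-side duplicates (after isoform stripping): keep the protein
    # group with the larger total intensity
    stripped <- sub("-[0-9]+$", "", razor)
    if (anyDuplicated(stripped)) {
      tot <- rowSums(abs(v), na.rm = TRUE)
      keep <- !logical(length(razor))
      for (r in unique(stripped[duplicated(stripped)])) {
        idx <- which(stripped == r)
        keep[idx[-which.max(tot[idx])]] <- FALSE
      }
      v <- v[keep, , drop = FALSE]
      razor <- razor[keep]
    }
    list(values = v, razor = razor)
  }
  a <- side(cell_matrix, cell_gene_map)
  b <- side(tumour_matrix, tumour_gene_map)

  strip <- function(ids) sub("-[0-9]+$", "", ids)
  # pass 1: exact; pass 2: isoform-stripped for the remainder
  match_pass <- rep(NA_integer_, length(a$razor))
  b_key <- b$razor
  m1 <- match(a$razor, b_key)
  match_pass[!is.na(m1)] <- 1L
  a_rem <- which(is.na(m1))
  b_unmatched <- setdiff(seq_along(b_key), m1[!is.na(m1)])
  m2 <- match(strip(a$razor[a_rem]), strip(b_key)[b_unmatched])
  m1[a_rem] <- b_unmatched[m2]
  match_pass[a_rem][!is.na(m2)] <- 2L

  union_ids <- character(); rows_a <- integer(); rows_b <- integer()
  prov_side <- character(); prov_pass <- integer()
  for (i in seq_along(a$razor)) {
    union_ids <- c(union_ids, a$razor[i]); rows_a <- c(rows_a, i)
    rows_b <- c(rows_b, if (is.na(m1[i])) NA_integer_ else m1[i])
    prov_side <- c(prov_side, if (is.na(m1[i])) "cell_line" else "both")
    prov_pass <- c(prov_pass, match_pass[i])
  }
  for (j in setdiff(seq_along(b$razor), m1[!is.na(m1)])) {
    union_ids <- c(union_ids, b$razor[j]); rows_a <- c(rows_a, NA_integer_)
    rows_b <- c(rows_b, j); prov_side <- c(prov_side, "tumour")
    prov_pass <- c(prov_pass, NA_integer_)
  }

  na_col <- function(n, cols) matrix(NA_real_, n, length(cols),
                                     dimnames = list(NULL, cols))
  left <- na_col(length(union_ids), colnames(a$values))
  right <- na_col(length(union_ids), colnames(b$values))
  ok_a <- !is.na(rows_a); ok_b <- !is.na(rows_b)
  left[ok_a, ] <- a$values[rows_a[ok_a], , drop = FALSE]
  right[ok_b, ] <- b$values[rows_b[ok_b], , drop = FALSE]
  merged <- cbind(left, right)
  rownames(merged) <- union_ids

  structure(list(
    matrix = intensity_matrix(merged, "batch_corrected"),
    union_ids = union_ids,
    intersection_ids = union_ids[prov_side == "both"],
    provenance = data.frame(protein_id = union_ids, side = prov_side,
                            match_pass = prov_pass, stringsAsFactors = FALSE)),
    class = "merged_landscape")
}

#' @export
print.merged_landscape <- function(x, ...) {
  cat(sprintf("merged_landscape: union %d proteins, intersection %d\n",
              length(x$union_ids), length(x$intersection_ids)))
  invisible(x)
}

#' Per-sample and per-group detected-protein counts
#'
#' Counts, for each assay and for each group of assays, the proteins with
#' at least one observed value, plus the per-group average over assays.
#'
#' @param landscape a `merged_landscape` (or an [intensity_matrix()]).
#' @param annotation an [assay_annotation()].
#' @param group_by annotation column defining the groups (default
#'   `"sample_type"`).
#' @return list with `per_assay` (assay, group, n_proteins) and `per_group`
#'   (group, n_assays, mean_proteins_per_assay, n_proteins_detected).
#' @export
coverage_report <- function(landscape, annotation, group_by = "sample_type") {
  x <- if (inherits(landscape, "merged_landscape")) landscape$matrix else landscape
  ann <- .match_annotation(x, annotation)
  if (!group_by %in% names(ann))
    stop("unknown grouping column '", group_by, "'")
  v <- intensity_values(x)
  per_assay <- data.frame(assay_id = colnames(v),
                          group = ann[[group_by]],
                          n_proteins = colSums(!is.na(v)),
                          stringsAsFactors = FALSE, row.names = NULL)
  groups <- unique(per_assay$group)
  per_group <- do.call(rbind, lapply(groups, function(g) {
    cols <- per_assay$group == g
    data.frame(group = g, n_assays = sum(cols),
               mean_proteins_per_assay = mean(per_assay$n_proteins[cols]),
               n_proteins_detected = sum(rowSums(
                 !is.na(v[, cols, drop = FALSE])) > 0),
               stringsAsFactors = FALSE)
  }))
  list(per_assay = per_assay, per_group = per_group)
}
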