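#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated protein-group quantification table with per-assay
#' iBAQ columns (named `"iBAQ <assay>"`), drops decoy ("Reverse") and
#' contaminant-flagged rows (the upstream convention marks them with `"+"`),
#' converts zero intensities to missing, and returns the raw-iBAQ intensity
#' matrix together with the protein-group / leading-razor-protein / gene map.
#'
#' Zero iBAQ is treated as missing rather than as a measured zero: the
#' upstream search engine reports 0 for proteins without quantifiable
#' evidence in a run.
#'
#' @param path path to a tab-separated proteinGroups-like file.
#' @param id_col column holding the protein-group identifier.
#' @param razor_col column holding the leading razor protein accession.
#' @param gene_col column holding the gene name (optional in the file).
#' @param reverse_col,contaminant_col columns carrying the `"+"` decoy /
#'   contaminant markers; either may be absent from the file.
#' @param ibaq_prefix prefix of the per-assay quantification columns.
#' @return list with `matrix` (an [intensity_matrix()] at stage `raw_ibaq`)
#'   and `gene_map` (data.frame: `protein_group_id`, `leading_razor_protein`,
#'   `gene_id`).
#' @export
read_protein_groups <- function(path,
                                id_col = "Protein IDs",
                                razor_col = "Leading razor protein",
                                gene_col = "Gene names",
                                reverse_col = "Reverse",
                                contaminant_col = "Potential contaminant",
                                ibaq_prefix = "iBAQ ") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_col %in% names(df))
    stop("protein-group id column '", id_col, "' not found in ", path)
  ibaq_cols <- grep(paste0("^", ibaq_prefix), names(df), value = TRUE)
  # plain "iBAQ" (summed over assays) is not a per-assay column
  ibaq_cols <- ibaq_cols[nzchar(sub(paste0("^", ibaq_prefix), "", ibaq_cols))]
  if (!length(ibaq_cols))
    stop("no per-assay iBAQ columns (prefix '", ibaq_prefix, "') found in ", path)
  keep <- rep(TRUE, nrow(df))
  for (flag in c(reverse_col, contaminant_col))
    if (flag %in% names(df))
      keep <- keep & !(trimws(as.character(df[[flag]])) %in% "+")
  df <- df[keep, , drop = FALSE]
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate protein-group ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, ibaq_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[vals == 0] <- NA_real_
  rownames(vals) <- ids
  colnames(vals) <- sub(paste0("^", ibaq_prefix), "", ibaq_cols)
  gene_map <- data.frame(
    protein_group_id = ids,
    leading_razor_protein = if (razor_col %in% names(df))
      as.character(df[[razor_col]]) else ids,
    gene_id = if (gene_col %in% names(df))
      as.character(df[[gene_col]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  list(matrix = intensity_matrix(vals, "raw_ibaq"), gene_map = gene_map)
}

#' Read an SDRF-like sample annotation table
#'
#' @param path tab-separated file with columns `assay_id`, `study_id`,
#'   `sample_id`, `sample_type`, and optionally `lineage`,
#'   `replicate_group`, `enzyme`.
#' @return an [assay_annotation()] data.frame.
#' @export
read_sdrf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assay_annotation(df)
}

#' Write an SDRF-like sample annotation table
#' @param annotation an [assay_annotation()]
#' @param path output path (TSV)
#' @export
write_sdrf <- function(annotation, path) {
  df <- as.data.frame(annotation)
  df$lineage_known <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix TSV
#'
#' The expression-matrix dialect has the gene or protein identifier in the
#' first column and one column per sample; empty cells or `NA` are missing.
#'
#' @param path file path.
#' @param stage stage tag to attach on read (see [intensity_matrix()]).
#' @return `read_expression_matrix`: an [intensity_matrix()];
#'   `write_expression_matrix` returns the path invisibly.
#' @export
read_expression_matrix <- function(path, stage = "raw_ibaq") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  intensity_matrix(vals, stage)
}

#' @rdname read_expression_matrix
#' @param x an [intensity_matrix()] or a plain matrix with dimnames
#' @param id_name header of the identifier column
#' @export
write_expression_matrix <- function(x, path, id_name = "id") {
  vals <- if (inherits(x, "intensity_matrix")) intensity_values(x) else x
  df <- data.frame(id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a peptide evidence table
#'
#' The peptides-like dialect has one row per (peptide, assay) with columns
#' `peptide_sequence`, `proteins` (semicolon-joined accessions of every
#' protein the sequence maps to), `assay_id` and `detected` (0/1).
#'
#' @param path file path
#' @return data.frame of class `peptide_evidence`
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  peptide_evidence(df)
}

#' @rdname read_peptide_table
#' @param table a `peptide_evidence` data.frame
#' @export
write_peptide_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a validated peptide evidence table
#'
#' @param df data.frame with columns `peptide_sequence`, `proteins`
#'   (semicolon-joined protein ids), `assay_id`, `detected` (logical or 0/1)
#' @return data.frame of class `peptide_evidence`
#' @export
peptide_evidence <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("peptide_sequence", "proteins", "assay_id", "detected")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("peptide table is missing columns: ", paste(miss, collapse = ", "))
  df$peptide_sequence <- toupper(as.character(df$peptide_sequence))
  if (any(!nzchar(df$peptide_sequence)))
    stop("empty peptide_sequence")
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", df$peptide_sequence)))
    stop("peptide_sequence contains characters outside the amino-acid alphabet")
  df$proteins <- as.character(df$proteins)
  if (any(!nzchar(df$proteins)))
    stop("every peptide must map to at least one protein")
  df$detected <- as.logical(as.integer(as.logical(df$detected)))
  class(df) <- c("peptide_evidence", "data.frame")
  df
}

# split semicolon-joined protein ids into a list of character vectors
.split_proteins <- function(proteins) strsplit(proteins, ";", fixed = TRUE)

#' Read / write an anchor absolute-abundance table
#'
#' Anchor proteins have independently measured absolute abundances (copies
#' per cell) used to validate the normalization. The TSV has the protein id
#' in the first column and one copies-per-cell column per sample.
#'
#' @param path file path
#' @return numeric matrix, anchor proteins x samples (copies per cell)
#' @export
read_anchor_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(df[[1]])
  if (any(v <= 0, na.rm = TRUE))
    stop("anchor copies-per-cell values must be positive")
  v
}

#' @rdname read_anchor_table
#' @param anchors numeric matrix of copies per cell with dimnames
#' @export
write_anchor_table <- function(anchors, path) {
  write_expression_matrix(anchors, path, id_name = "protein_id")
}

#' Restrict a matrix to assays digested with one enzyme
#'
#' Quantitative cross-study comparison is only meaningful within a single
#' digestion protocol, so the quantitative pipeline is restricted to (by
#' default) tryptic assays; protein rows are unchanged.
#'
#' @param x an [intensity_matrix()]
#' @param annotation an [assay_annotation()] covering the matrix assays
#' @param enzyme enzyme to retain (default `"trypsin"`)
#' @return [intensity_matrix()] with only the matching assays
#' @export
restrict_to_enzyme <- function(x, annotation, enzyme = "trypsin") {
  ann <- .match_annotation(x, annotation)
  keep <- ann$enzyme == enzyme
  if (!any(keep))
    stop("no assays digested with '", enzyme, "' remain")
  intensity_matrix(intensity_values(x)[, keep, drop = FALSE], x$stage)
}
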