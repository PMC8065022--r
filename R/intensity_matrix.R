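#' Protein quantification matrix with explicit missingness and stage tracking
#'
#' An `intensity_matrix` wraps a numeric proteins x assays matrix in which
#' `NA` marks a missing (undetected) value, together with a processing-stage
#' tag. The stage records where the matrix sits in the normalization pipeline
#' and stage transitions are enforced to follow pipeline order:
#' `raw_ibaq -> ppb -> log2_ppb -> imputed -> batch_corrected`.
#'
#' At the `raw_ibaq` and `ppb` stages all observed values must be
#' non-negative; at log2 stages values are unrestricted reals.
#'
#' @param values numeric matrix, proteins in rows, assays in columns; both
#'   dimensions must carry unique names (protein ids / assay ids). `NA`
#'   entries are missing values.
#' @param stage one of `"raw_ibaq"`, `"ppb"`, `"log2_ppb"`, `"imputed"`,
#'   `"batch_corrected"`.
#' @return an object of class `intensity_matrix`.
#' @examples
#' m <- matrix(c(1, 2, NA, 4), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("A1", "A2")))
#' im <- intensity_matrix(m, "raw_ibaq")
#' missing_mask(im)
#' @export
intensity_matrix <- function(values, stage = c("raw_ibaq", "ppb", "log2_ppb",
                                               "imputed", "batch_corrected")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("'values' must have protein ids as rownames and assay ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate assay ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (stage %in% c("raw_ibaq", "ppb") && any(values < 0, na.rm = TRUE))
    stop("negative values are not allowed at the '", stage, "' stage")
  structure(list(values = values, stage = stage), class = "intensity_matrix")
}

.stage_order <- c(raw_ibaq = 1L, ppb = 2L, log2_ppb = 3L,
                  imputed = 4L, batch_corrected = 5L)

#' @export
print.intensity_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("intensity_matrix [stage: %s]\n", x$stage))
  cat(sprintf("  %d proteins x %d assays, %.1f%% missing\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Extract the value matrix of an intensity_matrix
#' @param x an `intensity_matrix`
#' @return numeric matrix with `NA` for missing entries
#' @export
intensity_values <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  x$values
}

#' Logical mask of missing entries
#' @param x an `intensity_matrix`
#' @return logical matrix, `TRUE` where the value is missing
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  is.na(x$values)
}

#' Protein and assay identifiers
#' @param x an `intensity_matrix`
#' @return character vector of ids in matrix order
#' @export
protein_ids <- function(x) rownames(intensity_values(x))

#' @rdname protein_ids
#' @export
assay_ids <- function(x) colnames(intensity_values(x))

# Assert that `x` is at one of the stages in `allowed`; used by every pipeline
# stage so that e.g. log2_transform cannot run on an already-log matrix.
.check_stage <- function(x, allowed, op) {
  if (!inherits(x, "intensity_matrix"))
    stop(op, "() expects an intensity_matrix")
  if (!x$stage %in% allowed)
    stop(op, "() requires stage ", paste(sQuote(allowed), collapse = " or "),
         " but the input is at stage '", x$stage, "'")
  invisible(TRUE)
}

#' Per-assay sample annotation
#'
#' Builds and validates the assay-level metadata table that accompanies an
#' [intensity_matrix()]. The `study_id` column is the batch covariate used by
#' [remove_batch_effects()]. `sample_type` and `enzyme` are controlled
#' vocabularies; `lineage` values outside the known tissue-origin vocabulary
#' are kept but flagged in the `lineage_known` column.
#'
#' @param df data.frame with columns `assay_id`, `study_id`, `sample_id`,
#'   `sample_type` (cell_line / tumour / normal), `lineage`,
#'   `replicate_group`, `enzyme` (trypsin / lysc / chymotrypsin / gluc).
#'   Missing optional columns (`replicate_group`, `enzyme`, `lineage`) are
#'   filled with defaults.
#' @return validated data.frame of class `assay_annotation`.
#' @export
assay_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("assay_id", "study_id", "sample_id", "sample_type")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("annotation is missing required columns: ", paste(miss, collapse = ", "))
  if (!"lineage" %in% names(df)) df$lineage <- "unknown"
  if (!"replicate_group" %in% names(df)) df$replicate_group <- df$sample_id
  if (!"enzyme" %in% names(df)) df$enzyme <- "trypsin"
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$assay_id))
    stop("duplicate assay_id in annotation: ",
         paste(unique(df$assay_id[duplicated(df$assay_id)]), collapse = ", "))
  if (any(!nzchar(df$study_id)) || anyNA(df$study_id))
    stop("study_id must be non-empty for every assay")
  bad <- setdiff(unique(df$sample_type), c("cell_line", "tumour", "normal"))
  if (length(bad))
    stop("invalid sample_type value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$enzyme), c("trypsin", "lysc", "chymotrypsin", "gluc"))
  if (length(bad))
    stop("invalid enzyme value(s): ", paste(bad, collapse = ", "))
  df$lineage_known <- df$lineage %in% lineage_vocabulary()
  class(df) <- c("assay_annotation", "data.frame")
  df
}

#' Known tissue-origin lineages
#'
#' The controlled vocabulary of tissue origins used across the landscape.
#' @return character vector of lineage names
#' @export
lineage_vocabulary <- function() {
  c("blood", "bone", "brain", "breast", "cervix", "colorectal", "kidney",
    "liver", "lung", "lymph_node", "ovarian", "prostate", "skin")
}

# Check that every assay of matrix `x` has exactly one annotation row and
# return the annotation reordered to match the assay order of `x`.
.match_annotation <- function(x, annotation) {
  ids <- assay_ids(x)
  orphans <- setdiff(ids, annotation$assay_id)
  if (length(orphans))
    stop("assays present in the data but absent from the annotation: ",
         paste(orphans, collapse = ", "))
  annotation[match(ids, annotation$assay_id), , drop = FALSE]
}
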