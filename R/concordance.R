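#' Pairwise-complete correlation between assays
#'
#' For every pair of assays the coefficient is computed on the protein rows
#' observed in both (pairwise complete observations). Pairs with fewer than
#' `min_overlap` complete rows, or with a constant vector within the
#' complete subset, are reported as `NA`.
#'
#' @param x an [intensity_matrix()] (any log-scale stage) or numeric matrix
#'   with `NA` for missing values; columns are assays.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_overlap minimum number of complete pairs for a defined
#'   coefficient (default 10).
#' @return object of class `pairwise_correlation`: `r` (symmetric matrix,
#'   unit diagonal), `n_complete` (pair counts), `method`, `min_overlap`.
#' @export
pairwise_correlation <- function(x, method = c("pearson", "spearman"),
                                 min_overlap = 10) {
  method <- match.arg(method)
  v <- if (inherits(x, "intensity_matrix")) intensity_values(x) else x
  if (ncol(v) < 2) stop("at least 2 assays are required")
  n_complete <- crossprod(!is.na(v))
  r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs",
                                   method = method))
  r[n_complete < min_overlap] <- NA_real_
  diag(r) <- 1
  structure(list(r = r, n_complete = n_complete, method = method,
                 min_overlap = min_overlap),
            class = "pairwise_correlation")
}

#' @export
print.pairwise_correlation <- function(x, ...) {
  cat(sprintf("pairwise_correlation (%s): %d assays, %d undefined pairs\n",
              x$method, ncol(x$r), sum(is.na(x$r[upper.tri(x$r)]))))
  invisible(x)
}

#' @export
as.data.frame.pairwise_correlation <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  data.frame(entity_a = colnames(x$r)[idx[, 1]],
             entity_b = colnames(x$r)[idx[, 2]],
             coefficient = x$r[idx],
             n_complete = x$n_complete[idx],
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering of a correlation matrix
#'
#' Agglomerative clustering of the assays using Euclidean distance between
#' the rows of the correlation matrix.
#'
#' @param ct a [pairwise_correlation()] result (must be complete).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return an `hclust` object.
#' @export
hierarchical_cluster <- function(ct, linkage = "complete") {
  stopifnot(inherits(ct, "pairwise_correlation"))
  if (anyNA(ct$r))
    stop("correlation matrix contains undefined pairs; ",
         "exclude those assays or lower min_overlap before clustering")
  stats::hclust(stats::dist(ct$r, method = "euclidean"), method = linkage)
}

#' Correlation distributions within and between sample types
#'
#' Splits the off-diagonal pairwise coefficients into within-cell-line,
#' within-tumour and cell-line-vs-tumour distributions (self-pairs
#' excluded) and reports their medians.
#'
#' @param ct a [pairwise_correlation()] result.
#' @param annotation an [assay_annotation()] covering the assays.
#' @return list with `distributions` (named list of coefficient vectors)
#'   and `medians` (named numeric vector).
#' @export
within_between_summary <- function(ct, annotation) {
  stopifnot(inherits(ct, "pairwise_correlation"))
  ids <- colnames(ct$r)
  type <- annotation$sample_type[match(ids, annotation$assay_id)]
  if (anyNA(type))
    stop("assays missing from the annotation: ",
         paste(ids[is.na(type)], collapse = ", "))
  idx <- which(upper.tri(ct$r), arr.ind = TRUE)
  vals <- ct$r[idx]
  ta <- type[idx[, 1]]; tb <- type[idx[, 2]]
  pick <- function(cond) vals[cond & !is.na(vals)]
  dists <- list(
    within_cell_lines = pick(ta == "cell_line" & tb == "cell_line"),
    within_tumours = pick(ta == "tumour" & tb == "tumour"),
    cell_line_vs_tumour = pick((ta == "cell_line" & tb == "tumour") |
                                 (ta == "tumour" & tb == "cell_line")))
  empties <- names(dists)[lengths(dists) == 0]
  if (length(empties))
    warning("no pairs in: ", paste(empties, collapse = ", "))
  list(distributions = dists,
       medians = vapply(dists, function(d)
         if (length(d)) stats::median(d) else NA_real_, numeric(1)))
}

#' Coefficient of variation per protein per group
#'
#' CV is computed on the linear intensity scale: proteins in a log2 stage
#' should be passed with `from_log2 = TRUE` so values are back-transformed
#' (`2^x`) first. Per protein and group with at least 2 observed values:
#' `100 * sd / mean`; groups of one observation and zero-mean proteins are
#' excluded.
#'
#' @param x an [intensity_matrix()] or numeric matrix.
#' @param annotation an [assay_annotation()].
#' @param group_by annotation column defining the groups.
#' @param from_log2 back-transform values with `2^x` before computing.
#' @return data.frame: `protein_id`, `group`, `n`, `mean`, `sd`,
#'   `cv_percent`.
#' @export
cv_by_group <- function(x, annotation, group_by = "sample_type",
                        from_log2 = FALSE) {
  v <- if (inherits(x, "intensity_matrix")) intensity_values(x) else x
  if (from_log2) v <- 2^v
  ann_grp <- annotation[[group_by]][match(colnames(v), annotation$assay_id)]
  if (anyNA(ann_grp))
    stop("assays missing from the annotation: ",
         paste(colnames(v)[is.na(ann_grp)], collapse = ", "))
  out <- list()
  for (g in unique(ann_grp)) {
    sub <- v[, ann_grp == g, drop = FALSE]
    n <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1, stats::sd, na.rm = TRUE)
    keep <- n >= 2 & mu != 0 & !is.na(mu)
    if (!any(keep)) next
    out[[g]] <- data.frame(protein_id = rownames(v)[keep], group = g,
                           n = n[keep], mean = mu[keep], sd = sdv[keep],
                           cv_percent = 100 * sdv[keep] / mu[keep],
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Paired protein-mRNA container aligned on gene identifiers
#'
#' Aligns a protein matrix (assays in columns) with an mRNA matrix (samples
#' in columns) on their shared gene identifiers. If the column names
#' differ, `sample_of_assay` maps each protein assay to its mRNA sample
#' (replicate assays of one sample share that sample's mRNA profile).
#'
#' @param protein numeric matrix or [intensity_matrix()], genes x assays
#'   (log2 scale expected for downstream use).
#' @param rna numeric matrix, genes x samples (FPKM-like, non-negative).
#' @param sample_of_assay optional named character vector, assay id ->
#'   mRNA sample (column of `rna`).
#' @return list of class `paired_omics`: `protein`, `rna` (both genes x
#'   assays, identical dimnames), `gene_ids`.
#' @export
paired_omics <- function(protein, rna, sample_of_assay = NULL) {
  p <- if (inherits(protein, "intensity_matrix")) intensity_values(protein) else protein
  if (anyDuplicated(rownames(p)) || anyDuplicated(rownames(rna)))
    stop("duplicate gene ids are not allowed")
  genes <- intersect(rownames(p), rownames(rna))
  if (!length(genes)) stop("no shared gene identifiers")
  p <- p[genes, , drop = FALSE]
  if (is.null(sample_of_assay)) {
    shared <- intersect(colnames(p), colnames(rna))
    if (!length(shared)) stop("no shared samples; provide sample_of_assay")
    p <- p[, shared, drop = FALSE]
    r <- rna[genes, shared, drop = FALSE]
  } else {
    mapped <- sample_of_assay[colnames(p)]
    if (anyNA(mapped) || any(!mapped %in% colnames(rna)))
      stop("sample_of_assay does not cover every assay")
    r <- rna[genes, mapped, drop = FALSE]
    colnames(r) <- colnames(p)
  }
  structure(list(protein = p, rna = r, gene_ids = genes),
            class = "paired_omics")
}

# Spearman coefficient + large-sample t-approximation p-value
.spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(c(rs = NA_real_, p = NA_real_, n = n))
  rs <- stats::cor(x[ok], y[ok], method = "spearman")
  if (abs(rs) >= 1) return(c(rs = rs, p = 0, n = n))
  tstat <- rs * sqrt((n - 2) / (1 - rs^2))
  c(rs = rs, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Within-sample mRNA-protein correlation
#'
#' For each proteomics assay, the Spearman correlation between protein and
#' mRNA abundance across genes, with a large-sample t-approximation
#' p-value.
#'
#' @param paired a [paired_omics()] object.
#' @param min_overlap minimum genes observed in both layers (default 10).
#' @return data.frame: `assay_id`, `n_complete`, `coefficient`, `p_value`.
#' @export
within_sample_rna_protein <- function(paired, min_overlap = 10) {
  stopifnot(inherits(paired, "paired_omics"))
  res <- t(vapply(seq_len(ncol(paired$protein)), function(j)
    .spearman_test(paired$protein[, j], paired$rna[, j]), numeric(3)))
  out <- data.frame(assay_id = colnames(paired$protein),
                    n_complete = as.integer(res[, "n"]),
                    coefficient = res[, "rs"], p_value = res[, "p"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$coefficient[out$n_complete < min_overlap] <- NA_real_
  out$p_value[out$n_complete < min_overlap] <- NA_real_
  out
}

#' Across-sample (gene-wise) mRNA-protein correlation with BH control
#'
#' Per gene, the Spearman correlation between protein and mRNA abundance
#' across samples; p-values are Benjamini-Hochberg adjusted across all
#' testable genes (constant genes are excluded from the adjustment).
#'
#' @param paired a [paired_omics()] object.
#' @param min_overlap minimum samples per gene (default 10).
#' @param alpha adjusted-p significance threshold (default 0.01).
#' @return data.frame: `gene_id`, `n_complete`, `coefficient`, `p_value`,
#'   `adjusted_p`, `significant`.
#' @export
across_sample_rna_protein <- function(paired, min_overlap = 10, alpha = 0.01) {
  stopifnot(inherits(paired, "paired_omics"))
  res <- t(vapply(seq_len(nrow(paired$protein)), function(g)
    .spearman_test(paired$protein[g, ], paired$rna[g, ]), numeric(3)))
  out <- data.frame(gene_id = paired$gene_ids,
                    n_complete = as.integer(res[, "n"]),
                    coefficient = res[, "rs"], p_value = res[, "p"],
                    stringsAsFactors = FALSE, row.names = NULL)
  low <- out$n_complete < min_overlap
  out$coefficient[low] <- NA_real_
  out$p_value[low] <- NA_real_
  out$adjusted_p <- NA_real_
  testable <- !is.na(out$p_value)
  out$adjusted_p[testable] <- stats::p.adjust(out$p_value[testable],
                                              method = "BH")
  out$significant <- !is.na(out$adjusted_p) & out$adjusted_p < alpha
  out
}

#' Two-way ANOVA of within-sample correlations on lineage and study
#'
#' Fits a fixed-effects model of the per-assay mRNA-protein correlation on
#' lineage and study of origin (main effects only), after dropping
#' lineages below the minimum group size, and runs Tukey's honestly
#' significant difference post-hoc test on the lineage pairs. If only one
#' study is represented, the model reduces to a one-way ANOVA on lineage.
#'
#' @param rs_table data.frame with columns `coefficient` (or `rs`),
#'   `lineage`, `study`.
#' @param min_group_size smallest lineage kept (default 4, i.e. more than
#'   three assays).
#' @return list: `anova` (ANOVA table), `tukey` (lineage pairwise
#'   comparisons), `fit` (the `aov` object), `lineages_kept`.
#' @export
lineage_anova <- function(rs_table, min_group_size = 4) {
  df <- as.data.frame(rs_table)
  if ("rs" %in% names(df) && !"coefficient" %in% names(df))
    names(df)[names(df) == "rs"] <- "coefficient"
  need <- c("coefficient", "lineage", "study")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[!is.na(df$coefficient), , drop = FALSE]
  sizes <- table(df$lineage)
  keep <- names(sizes)[sizes >= min_group_size]
  df <- df[df$lineage %in% keep, , drop = FALSE]
  df$lineage <- factor(df$lineage)
  df$study <- factor(df$study)
  if (nlevels(df$lineage) < 2)
    stop("fewer than 2 lineages remain after the size filter")
  if (nlevels(df$study) < 2) {
    message("single study represented; fitting a one-way ANOVA on lineage")
    fit <- stats::aov(coefficient ~ lineage, data = df)
  } else {
    fit <- stats::aov(coefficient ~ lineage + study, data = df)
  }
  tuk <- stats::TukeyHSD(fit, which = "lineage")
  list(anova = summary(fit), tukey = tuk$lineage, fit = fit,
       lineages_kept = levels(df$lineage))
}
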