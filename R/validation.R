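#' Per-study intensity distribution summaries
#'
#' Summarises the distribution of log-scale intensities per study (kernel
#' density, median, IQR) and reports the between-study location spread,
#' `max |median_i - median_j|`, the quantity that global batch effects
#' inflate and batch correction should shrink.
#'
#' @param x an [intensity_matrix()] at a log-scale stage (or any matrix of
#'   log-scale values).
#' @param annotation an [assay_annotation()].
#' @return list: `per_study` (data.frame with `study_id`, `n_values`,
#'   `median`, `iqr`), `densities` (named list of [stats::density()]
#'   objects), `location_spread`.
#' @export
density_profiles <- function(x, annotation) {
  v <- if (inherits(x, "intensity_matrix")) intensity_values(x) else x
  study <- annotation$study_id[match(colnames(v), annotation$assay_id)]
  if (anyNA(study))
    stop("assays missing from the annotation: ",
         paste(colnames(v)[is.na(study)], collapse = ", "))
  studies <- unique(study)
  per <- lapply(studies, function(s) {
    vals <- as.numeric(v[, study == s, drop = FALSE])
    vals <- vals[!is.na(vals)]
    list(summary = data.frame(study_id = s, n_values = length(vals),
                              median = stats::median(vals),
                              iqr = stats::IQR(vals),
                              stringsAsFactors = FALSE),
         density = if (length(vals) > 1) stats::density(vals) else NULL)
  })
  summaries <- do.call(rbind, lapply(per, `[[`, "summary"))
  meds <- summaries$median
  spread <- if (length(meds) > 1) max(dist(meds)) else 0
  list(per_study = summaries,
       densities = stats::setNames(lapply(per, `[[`, "density"), studies),
       location_spread = spread)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a clustering and a reference
#' labeling: 1 for identical partitions, approximately 0 for random ones.
#'
#' @param a,b vectors of cluster/group labels, same length.
#' @return numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

# PCA of assay profiles (assays as observations, proteins as features),
# centered, optionally scaled; returns coordinates and variance fractions
.assay_pca <- function(v, scale. = FALSE) {
  p <- stats::prcomp(t(v), center = TRUE, scale. = scale.)
  list(coords = p$x, variance_explained = p$sdev^2 / sum(p$sdev^2))
}

#' PCA-based batch assessment before and after correction
#'
#' Projects assays into principal-component space (proteins as features,
#' centered), clusters them by k-means in the top-2 component plane (k =
#' number of label groups, fixed seed, multiple restarts) and scores the
#' clustering against the study labels and against the lineage labels with
#' the adjusted Rand index, for the matrix before and after batch
#' correction. Successful correction moves the dominant structure from
#' study to lineage: ARI(study) falls and ARI(lineage) rises.
#'
#' @param matrix_before,matrix_after complete (imputed) matrices with the
#'   same assays, [intensity_matrix()] or plain.
#' @param annotation an [assay_annotation()].
#' @param scale. unit-variance scaling before PCA (default `FALSE`).
#' @param seed seed for the k-means restarts.
#' @param nstart k-means restarts (default 20).
#' @return list of class `batch_assessment` with elements `before` and
#'   `after`, each holding `coords`, `variance_explained`, `ari_study`,
#'   `ari_lineage`.
#' @export
pca_batch_assessment <- function(matrix_before, matrix_after, annotation,
                                 scale. = FALSE, seed = 1L, nstart = 20) {
  get_vals <- function(x) if (inherits(x, "intensity_matrix"))
    intensity_values(x) else x
  vb <- get_vals(matrix_before); va <- get_vals(matrix_after)
  if (!identical(colnames(vb), colnames(va)))
    stop("before/after matrices must cover the same assays in the same order")
  if (anyNA(vb) || anyNA(va))
    stop("pca_batch_assessment requires complete (imputed) matrices")
  ids <- colnames(vb)
  study <- annotation$study_id[match(ids, annotation$assay_id)]
  lineage <- annotation$lineage[match(ids, annotation$assay_id)]
  if (anyNA(study))
    stop("assays missing from the annotation: ",
         paste(ids[is.na(study)], collapse = ", "))
  assess <- function(v) {
    pca <- .assay_pca(v, scale. = scale.)
    top2 <- pca$coords[, 1:2, drop = FALSE]
    score <- function(labels) {
      k <- length(unique(labels))
      if (ncol(v) < k) stop("fewer assays than label groups")
      set.seed(seed)
      km <- stats::kmeans(top2, centers = k, nstart = nstart)
      adjusted_rand_index(km$cluster, labels)
    }
    list(coords = pca$coords, variance_explained = pca$variance_explained,
         ari_study = score(study), ari_lineage = score(lineage))
  }
  structure(list(before = assess(vb), after = assess(va)),
            class = "batch_assessment")
}

#' @export
print.batch_assessment <- function(x, ...) {
  cat(sprintf("batch_assessment\n  before: ARI(study) %.3f, ARI(lineage) %.3f\n",
              x$before$ari_study, x$before$ari_lineage))
  cat(sprintf("  after:  ARI(study) %.3f, ARI(lineage) %.3f\n",
              x$after$ari_study, x$after$ari_lineage))
  invisible(x)
}

#' Anchor-protein validation of quantification variants
#'
#' For each quantification variant (e.g. raw iBAQ, ppb, each imputed and
#' batch-corrected matrix) and each assay, the Spearman correlation between
#' the quantification values and the anchors' absolute abundances (copies
#' per cell). Spearman is invariant to monotone rescaling, so a faithful
#' normalization must not degrade the correlation.
#'
#' @param variants named list of [intensity_matrix()] objects (or plain
#'   matrices); rows are proteins.
#' @param anchors numeric matrix, anchor proteins x samples (copies per
#'   cell), as from [read_anchor_table()].
#' @param sample_of_assay optional named vector mapping assay ids to anchor
#'   sample columns; by default assay ids are matched to anchor columns
#'   directly.
#' @param min_anchors minimum shared anchors for a defined coefficient
#'   (default 3).
#' @return list: `per_assay` (data.frame `variant`, `assay_id`,
#'   `n_anchors`, `coefficient`), `medians` (named per-variant median).
#' @export
anchor_validation <- function(variants, anchors, sample_of_assay = NULL,
                              min_anchors = 3) {
  if (!length(variants) || is.null(names(variants)))
    stop("variants must be a named list of matrices")
  rows <- list()
  for (vn in names(variants)) {
    v <- variants[[vn]]
    if (inherits(v, "intensity_matrix")) v <- intensity_values(v)
    for (a in colnames(v)) {
      s <- if (is.null(sample_of_assay)) a else sample_of_assay[[a]]
      if (is.null(s) || is.na(s) || !s %in% colnames(anchors)) next
      shared <- intersect(rownames(v), rownames(anchors))
      q <- v[shared, a]
      cpc <- anchors[shared, s]
      ok <- !is.na(q) & !is.na(cpc)
      coef <- if (sum(ok) >= min_anchors)
        suppressWarnings(stats::cor(q[ok], cpc[ok], method = "spearman"))
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, assay_id = a, n_anchors = sum(ok),
        coefficient = coef, stringsAsFactors = FALSE)
    }
  }
  per_assay <- do.call(rbind, rows)
  medians <- vapply(split(per_assay$coefficient, per_assay$variant),
                    function(x) stats::median(x, na.rm = TRUE), numeric(1))
  list(per_assay = per_assay, medians = medians)
}

#' Benchmark imputation methods against synthetic ground truth
#'
#' Masks are known in synthetic data, so each method's root-mean-square
#' error can be computed over the masked entries only.
#'
#' @param x an [intensity_matrix()] at stage `log2_ppb` with missing
#'   entries.
#' @param truth_log2 numeric matrix of true values on the same scale and
#'   with the same dimnames as `x` (e.g. the generator's `true_log2`
#'   shifted to the ppb scale, or any matrix whose masked-entry values are
#'   the reconstruction target).
#' @param methods character vector among `"svd"`, `"lod"`, `"lls"`.
#' @param svd_rank,svd_tol,lls_k method parameters.
#' @return named numeric vector of per-method RMSE over masked entries.
#' @export
imputation_benchmark <- function(x, truth_log2,
                                 methods = c("svd", "lod", "lls"),
                                 svd_rank = NULL, svd_tol = 1e-6, lls_k = 5) {
  .check_stage(x, c("log2_ppb", "ppb"), "imputation_benchmark")
  v <- intensity_values(x)
  if (!identical(dimnames(v), dimnames(truth_log2)))
    stop("truth matrix must have the same dimnames as the input")
  miss <- is.na(v)
  if (!any(miss)) stop("no masked entries to benchmark")
  vapply(stats::setNames(nm = methods), function(m) {
    imp <- switch(m,
                  svd = impute_svd(x, rank = svd_rank, tol = svd_tol),
                  lod = impute_lod(x),
                  lls = impute_lls(x, k = lls_k),
                  stop("unknown method '", m, "'"))
    est <- intensity_values(imp)[miss]
    sqrt(mean((est - truth_log2[miss])^2))
  }, numeric(1))
}
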