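#' Normalization pipeline configuration
#'
#' @param presence_threshold minimum fraction of assays in which a protein
#'   must be observed to survive [presence_filter()]; inclusive, default 0.5.
#' @param impute_method `"svd"`, `"lod"` or `"lls"`.
#' @param svd_rank number of singular components for [impute_svd()];
#'   `NULL` = `min(5, min(dim) - 1)`.
#' @param svd_tol relative-change convergence tolerance on the imputed
#'   entries (Frobenius norm).
#' @param svd_max_iter maximum refinement iterations.
#' @param lls_k neighbour count for [impute_lls()].
#' @param batch_covariate annotation column used as the batch factor.
#' @return list of class `normalization_config`.
#' @export
normalization_config <- function(presence_threshold = 0.5,
                                 impute_method = c("svd", "lod", "lls"),
                                 svd_rank = NULL,
                                 svd_tol = 1e-6,
                                 svd_max_iter = 500,
                                 lls_k = 5,
                                 batch_covariate = "study_id") {
  impute_method <- match.arg(impute_method)
  if (presence_threshold <= 0 || presence_threshold > 1)
    stop("presence_threshold must be in (0, 1]")
  if (svd_tol <= 0) stop("svd_tol must be > 0")
  structure(list(presence_threshold = presence_threshold,
                 impute_method = impute_method, svd_rank = svd_rank,
                 svd_tol = svd_tol, svd_max_iter = as.integer(svd_max_iter),
                 lls_k = as.integer(lls_k), batch_covariate = batch_covariate),
            class = "normalization_config")
}

#' Scale each assay to parts per billion (ppb)
#'
#' Within each assay (MS run), every observed iBAQ intensity is divided by
#' the assay's total observed intensity and multiplied by 100,000,000, so
#' each assay's observed values sum to 1e8 and assays become comparable in
#' composition. Missing entries stay missing and are excluded from the
#' denominator (the only computable reading when values are absent).
#'
#' @param x an [intensity_matrix()] at stage `raw_ibaq`.
#' @return an [intensity_matrix()] at stage `ppb`.
#' @examples
#' m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("P", 1:3), "A1"))
#' intensity_values(ppb_normalize(intensity_matrix(m, "raw_ibaq")))
#' @export
ppb_normalize <- function(x) {
  .check_stage(x, "raw_ibaq", "ppb_normalize")
  v <- intensity_values(x)
  totals <- colSums(v, na.rm = TRUE)
  empty <- colSums(!is.na(v)) == 0
  if (any(empty))
    stop("assay(s) with zero observed values: ",
         paste(colnames(v)[empty], collapse = ", "))
  out <- sweep(v, 2, totals, "/") * 1e8
  intensity_matrix(out, "ppb")
}

#' Log2-transform a ppb matrix
#'
#' @param x an [intensity_matrix()] at stage `ppb`.
#' @return an [intensity_matrix()] at stage `log2_ppb`; missing preserved.
#' @export
log2_transform <- function(x) {
  .check_stage(x, "ppb", "log2_transform")
  v <- intensity_values(x)
  if (any(v <= 0, na.rm = TRUE))
    stop("log2_transform requires strictly positive observed values")
  intensity_matrix(log2(v), "log2_ppb")
}

#' Drop proteins observed in too few assays
#'
#' Retains proteins present (observed) in at least `threshold` of all assays;
#' the boundary is inclusive, so with the default 0.5 a protein observed in
#' exactly half of the assays is kept. Row order is preserved.
#'
#' @param x an [intensity_matrix()] at any stage.
#' @param threshold minimum observed fraction, in (0, 1].
#' @return filtered [intensity_matrix()] at the same stage.
#' @export
presence_filter <- function(x, threshold = 0.5) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  v <- intensity_values(x)
  frac <- rowMeans(!is.na(v))
  keep <- frac >= threshold
  if (!any(keep)) warning("presence_filter removed every protein")
  intensity_matrix(v[keep, , drop = FALSE], x$stage)
}

#' Impute missing values by iterative low-rank SVD reconstruction
#'
#' Missing entries are initialized with per-protein observed means, then
#' refined by repeatedly (i) computing the rank-`rank` truncated SVD of the
#' completed matrix, (ii) overwriting only the missing entries with the
#' reconstruction, until the relative Frobenius-norm change of the imputed
#' entries drops below `tol` or `max_iter` is reached. Observed entries are
#' never modified.
#'
#' @param x an [intensity_matrix()] at stage `log2_ppb` (or `ppb`).
#' @param rank number of singular components; must be `< min(dim)`.
#'   Default `min(5, min(dim(x)) - 1)`.
#' @param tol relative-change convergence tolerance.
#' @param max_iter maximum number of refinement iterations.
#' @return an [intensity_matrix()] at stage `imputed`.
#' @export
impute_svd <- function(x, rank = NULL, tol = 1e-6, max_iter = 500) {
  .check_stage(x, c("log2_ppb", "ppb"), "impute_svd")
  v <- intensity_values(x)
  if (is.null(rank)) rank <- min(5L, min(dim(v)) - 1L)
  if (rank < 1 || rank >= min(dim(v)))
    stop("rank must satisfy 1 <= rank < min(dim)")
  miss <- is.na(v)
  .check_imputable(v)
  if (!any(miss)) return(intensity_matrix(v, "imputed"))
  filled <- v
  row_means <- rowMeans(v, na.rm = TRUE)
  filled[miss] <- row_means[row(v)[miss]]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- svd(filled, nu = rank, nv = rank)
    recon <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
    new_imp <- recon[miss]
    delta <- sqrt(sum((new_imp - filled[miss])^2)) /
      max(sqrt(sum(filled[miss]^2)), .Machine$double.eps)
    filled[miss] <- new_imp
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("impute_svd did not converge within ", max_iter, " iterations")
  intensity_matrix(filled, "imputed")
}

.check_imputable <- function(v) {
  bad_p <- rowSums(!is.na(v)) == 0
  bad_a <- colSums(!is.na(v)) == 0
  if (any(bad_p))
    stop("protein(s) with no observed value: ",
         paste(utils::head(rownames(v)[bad_p], 5), collapse = ", "))
  if (any(bad_a))
    stop("assay(s) with no observed value: ",
         paste(colnames(v)[bad_a], collapse = ", "))
  invisible(TRUE)
}

#' Impute missing values at the per-assay limit of detection
#'
#' Every missing entry is set to the minimum observed value of its assay,
#' the detection-limit proxy.
#'
#' @param x an [intensity_matrix()] at stage `log2_ppb` (or `ppb`).
#' @return an [intensity_matrix()] at stage `imputed`.
#' @export
impute_lod <- function(x) {
  .check_stage(x, c("log2_ppb", "ppb"), "impute_lod")
  v <- intensity_values(x)
  empty <- colSums(!is.na(v)) == 0
  if (any(empty))
    stop("assay(s) fully missing: ", paste(colnames(v)[empty], collapse = ", "))
  mins <- apply(v, 2, min, na.rm = TRUE)
  miss <- is.na(v)
  v[miss] <- mins[col(v)[miss]]
  intensity_matrix(v, "imputed")
}

#' Impute missing values by local least squares regression
#'
#' Each incomplete protein is regressed on its `k` most correlated complete
#' proteins over the columns where the target is observed; its missing
#' entries are predicted from the fitted model.
#'
#' @param x an [intensity_matrix()] at stage `log2_ppb` (or `ppb`).
#' @param k neighbour count.
#' @return an [intensity_matrix()] at stage `imputed`.
#' @export
impute_lls <- function(x, k = 5) {
  .check_stage(x, c("log2_ppb", "ppb"), "impute_lls")
  v <- intensity_values(x)
  .check_imputable(v)
  miss <- is.na(v)
  if (!any(miss)) return(intensity_matrix(v, "imputed"))
  complete <- which(rowSums(miss) == 0)
  if (length(complete) < k)
    stop("impute_lls needs at least k = ", k, " complete proteins; found ",
         length(complete))
  out <- v
  for (i in which(rowSums(miss) > 0)) {
    obs <- !miss[i, ]
    y <- v[i, obs]
    cand <- v[complete, , drop = FALSE]
    cors <- suppressWarnings(
      abs(stats::cor(y, t(cand[, obs, drop = FALSE]))))
    cors[is.na(cors)] <- -Inf
    nb <- complete[order(cors, decreasing = TRUE)[seq_len(k)]]
    X <- cbind(1, t(v[nb, obs, drop = FALSE]))
    fit <- stats::lm.fit(X, y)
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    Xm <- cbind(1, t(v[nb, !obs, drop = FALSE]))
    out[i, !obs] <- drop(Xm %*% beta)
  }
  intensity_matrix(out, "imputed")
}

#' Remove study-of-origin batch effects by a per-protein linear model
#'
#' For every protein, abundance is modelled by ordinary least squares on
#' batch membership encoded with sum-to-zero contrasts, and the fitted
#' batch component is subtracted. Each protein keeps its grand level (the
#' unweighted mean of its batch means, identical to the grand mean in
#' balanced designs) and within-batch deviations from batch means are
#' untouched, so only the systematic between-study shifts are removed.
#'
#' @param x an [intensity_matrix()] at stage `imputed` (complete matrix).
#' @param annotation an [assay_annotation()] covering the matrix assays.
#' @param batch_covariate annotation column holding the batch factor
#'   (default `"study_id"`).
#' @return an [intensity_matrix()] at stage `batch_corrected`.
#' @export
remove_batch_effects <- function(x, annotation, batch_covariate = "study_id") {
  .check_stage(x, c("imputed", "log2_ppb"), "remove_batch_effects")
  v <- intensity_values(x)
  if (anyNA(v))
    stop("remove_batch_effects requires a complete (imputed) matrix")
  ann <- .match_annotation(x, annotation)
  if (!batch_covariate %in% names(ann))
    stop("annotation has no column '", batch_covariate, "'")
  batch <- factor(ann[[batch_covariate]])
  if (nlevels(batch) < 2) {
    warning("single batch: returning the input unchanged")
    return(intensity_matrix(v, "batch_corrected"))
  }
  # sum-to-zero encoding: X has nlevels-1 columns; per-protein OLS reduces
  # to batch means, the subtracted component is batchmean - mean(batchmeans)
  X <- stats::model.matrix(~ b, data = data.frame(b = batch),
                           contrasts.arg = list(b = "contr.sum"))
  XtXi <- solve(crossprod(X))
  beta <- v %*% X %*% XtXi                 # proteins x (1 + L-1)
  beta[, 1] <- 0                           # keep the intercept (grand level)
  corrected <- v - beta %*% t(X)
  dimnames(corrected) <- dimnames(v)
  intensity_matrix(corrected, "batch_corrected")
}

#' Run the full two-step normalization pipeline
#'
#' Applies, in order: ppb scaling, log2 transform, presence filtering,
#' missing-value imputation (SVD, LOD or LLS) and linear-model batch-effect
#' removal. A per-stage processing log (stage, parameters, resulting
#' dimensions) is attached as the `"processing_log"` attribute.
#'
#' @param x an [intensity_matrix()] at stage `raw_ibaq`.
#' @param annotation an [assay_annotation()].
#' @param config a [normalization_config()].
#' @return an [intensity_matrix()] at stage `batch_corrected`.
#' @export
run_normalization <- function(x, annotation, config = normalization_config()) {
  stopifnot(inherits(config, "normalization_config"))
  log_lines <- character()
  note <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))
  m <- ppb_normalize(x)
  note("ppb_normalize: %d x %d", nrow(m$values), ncol(m$values))
  m <- log2_transform(m)
  note("log2_transform: %d x %d", nrow(m$values), ncol(m$values))
  m <- presence_filter(m, config$presence_threshold)
  note("presence_filter(threshold=%g): %d x %d", config$presence_threshold,
       nrow(m$values), ncol(m$values))
  m <- switch(config$impute_method,
              svd = impute_svd(m, rank = config$svd_rank, tol = config$svd_tol,
                               max_iter = config$svd_max_iter),
              lod = impute_lod(m),
              lls = impute_lls(m, k = config$lls_k))
  note("impute_%s: %d x %d", config$impute_method, nrow(m$values), ncol(m$values))
  m <- remove_batch_effects(m, annotation, config$batch_covariate)
  note("remove_batch_effects(batch=%s): %d x %d", config$batch_covariate,
       nrow(m$values), ncol(m$values))
  attr(m, "processing_log") <- log_lines
  m
}
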