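# Independent brute-force oracles. These deliberately re-derive each
# statistic from its textbook definition, sharing no code with the package.

# Iterative-SVD imputation, written directly from the algorithm statement:
# initialize missing with row means, reconstruct at rank k, overwrite
# missing, repeat.
oracle_svd_impute <- function(v, rank, tol = 1e-6, max_iter = 500) {
  miss <- is.na(v)
  filled <- v
  for (i in seq_len(nrow(v))) {
    mu <- mean(v[i, ], na.rm = TRUE)
    filled[i, is.na(v[i, ])] <- mu
  }
  for (it in seq_len(max_iter)) {
    s <- svd(filled)
    d <- s$d
    d[-seq_len(rank)] <- 0
    recon <- s$u %*% diag(d, nrow = length(d)) %*% t(s$v)
    old <- filled[miss]
    filled[miss] <- recon[miss]
    if (sqrt(sum((filled[miss] - old)^2)) /
        max(sqrt(sum(old^2)), .Machine$double.eps) < tol) break
  }
  filled
}

# Pairwise-complete correlation, materializing each pair's complete subset
# and applying the textbook formula via cor() on that subset.
oracle_pairwise_cor <- function(v, method = "pearson", min_overlap = 10) {
  p <- ncol(v)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ok <- !is.na(v[, i]) & !is.na(v[, j])
    if (sum(ok) >= min_overlap && sd(v[ok, i]) > 0 && sd(v[ok, j]) > 0)
      r[i, j] <- cor(v[ok, i], v[ok, j], method = method)
  }
  diag(r) <- 1
  r
}

# Per-protein OLS batch removal: residuals of lm(y ~ batch) with
# sum-to-zero contrasts, plus the fitted intercept.
oracle_batch_remove <- function(v, batch) {
  batch <- factor(batch)
  out <- v
  for (i in seq_len(nrow(v))) {
    df <- data.frame(y = v[i, ], b = batch)
    fit <- lm(y ~ b, data = df, contrasts = list(b = "contr.sum"))
    out[i, ] <- residuals(fit) + coef(fit)[1]
  }
  out
}

# Brute-force GSEA running sum, walked position by position.
oracle_es <- function(scores, set_genes, weight = 1) {
  genes <- names(scores)
  n <- length(genes)
  hit <- genes %in% set_genes
  k <- sum(hit)
  w <- abs(scores)^weight
  sw <- sum(w[hit])
  if (sw == 0) { w[] <- 1; sw <- k }
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) w[i] / sw else -1 / (n - k)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# random matrix with missing values, reproducible
random_missing_matrix <- function(n, p, miss_frac, seed) {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("P%03d", 1:n), sprintf("A%03d", 1:p)))
  n_miss <- round(miss_frac * n * p)
  if (n_miss > 0) v[sample(length(v), n_miss)] <- NA
  # keep every row and column with at least one observed value
  v
}

# tiny valid annotation builder
make_annotation <- function(assays, study, type = "cell_line",
                            lineage = "breast") {
  assay_annotation(data.frame(
    assay_id = assays, study_id = study, sample_id = assays,
    sample_type = type, lineage = lineage, stringsAsFactors = FALSE))
}
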