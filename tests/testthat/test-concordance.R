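test_that("pairwise correlation handles perfect linear relations", {
  x <- rnorm(20)
  v <- cbind(A1 = x, A2 = 2 * x + 1, A3 = -x)
  rownames(v) <- sprintf("P%d", 1:20)
  ct <- pairwise_correlation(v, "pearson", min_overlap = 5)
  expect_equal(ct$r["A1", "A2"], 1)
  expect_equal(ct$r["A1", "A3"], -1)
  expect_true(all(diag(ct$r) == 1))
  expect_equal(ct$r, t(ct$r))
})

test_that("pairwise correlation equals the brute-force per-pair oracle", {
  for (seed in 1:6) {
    v <- random_missing_matrix(12, 5, 0.2, seed + 100)
    for (method in c("pearson", "spearman")) {
      got <- pairwise_correlation(v, method, min_overlap = 3)$r
      want <- oracle_pairwise_cor(v, method, min_overlap = 3)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("pairs below min_overlap or with constant subsets are undefined", {
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("P%d", 1:10), sprintf("A%d", 1:4)))
  v[3:10, 2] <- NA              # only 2 complete pairs with anything
  ct <- pairwise_correlation(v, "pearson", min_overlap = 5)
  expect_true(all(is.na(ct$r["A2", c("A1", "A3", "A4")])))
  expect_equal(ct$n_complete["A2", "A1"], 2)
  v[, 3] <- 1                   # constant column
  ct2 <- pairwise_correlation(v, "pearson", min_overlap = 5)
  expect_true(is.na(ct2$r["A3", "A1"]))
  expect_error(pairwise_correlation(v[, 1, drop = FALSE]), "2 assays")
})

test_that("hierarchical clustering merges identical assays first and splits blocks", {
  set.seed(8)
  base1 <- rnorm(30); base2 <- rnorm(30)
  v <- cbind(A = base1, B = base1 + rnorm(30, 0, 0.01),
             C = base2, D = base2 + rnorm(30, 0, 0.01))
  rownames(v) <- sprintf("P%d", 1:30)
  ct <- pairwise_correlation(v, "pearson", min_overlap = 5)
  hc <- hierarchical_cluster(ct)
  groups <- cutree(hc, k = 2)
  expect_equal(groups[["A"]], groups[["B"]])
  expect_equal(groups[["C"]], groups[["D"]])
  expect_false(groups[["A"]] == groups[["C"]])
  ct$r[1, 2] <- ct$r[2, 1] <- NA
  expect_error(hierarchical_cluster(ct), "undefined")
})

test_that("within/between summary splits pairs by sample type", {
  v <- matrix(rnorm(60), 15, 4,
              dimnames = list(sprintf("P%d", 1:15), sprintf("A%d", 1:4)))
  ann <- make_annotation(colnames(v), "s1",
                         type = c("cell_line", "cell_line", "tumour", "tumour"))
  ct <- pairwise_correlation(v, "pearson", min_overlap = 5)
  wb <- within_between_summary(ct, ann)
  expect_length(wb$distributions$within_cell_lines, 1)
  expect_length(wb$distributions$within_tumours, 1)
  expect_length(wb$distributions$cell_line_vs_tumour, 4)
  # all-identical assays give all medians 1
  vi <- matrix(rep(rnorm(15), 4), 15, 4,
               dimnames = dimnames(v))
  wbi <- within_between_summary(pairwise_correlation(vi, min_overlap = 5), ann)
  expect_true(all(wbi$medians == 1))
})

test_that("lineage-aligned types give higher within-type than cross-type medians", {
  # cell lines come from two lineages and tumours from two others, so
  # within-type pairs can share a lineage profile while cross-type pairs
  # never do: median(within) must exceed median(between)
  cfg <- generator_config(n_proteins = 150, batch_offset_sd = 0,
                          lineage_sd = 2, noise_sd = 0.2,
                          samples_per_lineage = c(breast = 4, lung = 4,
                                                  colorectal = 4, ovarian = 4),
                          sample_type = rep(c("cell_line", "tumour"), each = 8),
                          seed = 18)
  sim <- generate_multistudy(cfg)
  l2 <- log2(intensity_values(sim$matrix))
  ct <- pairwise_correlation(l2, "pearson", min_overlap = 10)
  wb <- within_between_summary(ct, sim$annotation)
  expect_gt(wb$medians[["within_cell_lines"]],
            wb$medians[["cell_line_vs_tumour"]])
  expect_gt(wb$medians[["within_tumours"]],
            wb$medians[["cell_line_vs_tumour"]])
})

test_that("cv_by_group matches hand arithmetic and the lognormal closed form", {
  v <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("Pvar", "Pconst"), c("A1", "A2", "A3")))
  ann <- make_annotation(colnames(v), "s1")
  cv <- cv_by_group(v, ann)
  expect_equal(cv$cv_percent[cv$protein_id == "Pvar"], 50)   # sd 1, mean 2
  expect_equal(cv$cv_percent[cv$protein_id == "Pconst"], 0)
  # lognormal: CV% = 100 * sqrt(exp(sigma_ln^2) - 1)
  set.seed(20)
  sigma_log2 <- 0.5
  sigma_ln <- sigma_log2 * log(2)
  big <- matrix(2^rnorm(300 * 40, 10, sigma_log2), 300, 40,
                dimnames = list(sprintf("P%d", 1:300), sprintf("A%d", 1:40)))
  annb <- make_annotation(colnames(big), "s1")
  cvb <- cv_by_group(big, annb)
  want <- 100 * sqrt(exp(sigma_ln^2) - 1)
  expect_lt(abs(median(cvb$cv_percent) - want) / want, 0.1)
})

test_that("groups of one observation are excluded from CV", {
  v <- matrix(rnorm(4, 100, 5), 2, 2,
              dimnames = list(c("P1", "P2"), c("A1", "A2")))
  ann <- make_annotation(colnames(v), "s1", type = c("cell_line", "tumour"))
  expect_null(cv_by_group(v, ann))
})

test_that("within-sample correlation is exact for monotone and reversed ranks", {
  genes <- sprintf("G%d", 1:50)
  p <- matrix(rnorm(100), 50, 2, dimnames = list(genes, c("A1", "A2")))
  rna <- cbind(A1 = exp(p[, 1]), A2 = max(p[, 2]) - p[, 2] + 1)
  rownames(rna) <- genes
  po <- paired_omics(p, rna)
  rs <- within_sample_rna_protein(po)
  expect_equal(rs$coefficient[rs$assay_id == "A1"], 1)
  expect_equal(rs$coefficient[rs$assay_id == "A2"], -1)
  expect_equal(rs$p_value[rs$assay_id == "A1"], 0)
})

test_that("assay-coupled generator recovers the within-sample target", {
  cfg <- generator_config(n_proteins = 2000, assay_rs_target = 0.58,
                          samples_per_lineage = c(breast = 3, lung = 3),
                          seed = 21)
  sim <- generate_multistudy(cfg)
  rna <- generate_paired_rna(sim$truth, cfg, coupling = "assay")
  po <- paired_omics(sim$truth$true_log2, rna)
  rs <- within_sample_rna_protein(po)
  expect_lt(abs(median(rs$coefficient) - 0.58), 0.04)
})

test_that("BH adjustment matches the hand-executed step-up on 4 genes", {
  genes <- sprintf("G%d", 1:4)
  # craft per-gene p-values indirectly is brittle; test the BH contract on
  # the result table instead: adjusted_p = p * n / rank, cummin from bottom
  p <- matrix(rnorm(4 * 30), 4, 30, dimnames = list(genes, sprintf("S%d", 1:30)))
  rna <- abs(p + matrix(rnorm(4 * 30, 0, 2), 4, 30)) + 0.1
  po <- paired_omics(p, rna)
  res <- across_sample_rna_protein(po)
  ok <- !is.na(res$p_value)
  expect_equal(res$adjusted_p[ok],
               p.adjust(res$p_value[ok], method = "BH"))
  # monotone and idempotent
  expect_true(all(res$adjusted_p[ok] >= res$p_value[ok]))
  expect_equal(p.adjust(res$adjusted_p[ok], "BH") >= res$adjusted_p[ok],
               rep(TRUE, sum(ok)))
})

test_that("perfectly coupled layers give coefficient 1 and near-zero p", {
  genes <- sprintf("G%d", 1:20)
  p <- matrix(rnorm(20 * 15), 20, 15,
              dimnames = list(genes, sprintf("S%d", 1:15)))
  po <- paired_omics(p, exp(p / 2))
  res <- across_sample_rna_protein(po)
  expect_equal(res$coefficient, rep(1, 20))
  expect_true(all(res$adjusted_p < 1e-10))
  expect_true(all(res$significant))
})

test_that("constant genes are excluded from testing and adjustment", {
  genes <- c("Gconst", "Gvar")
  p <- rbind(Gconst = rep(1, 12), Gvar = rnorm(12))
  colnames(p) <- sprintf("S%d", 1:12)
  rna <- abs(p + 1)
  po <- paired_omics(p, rna)
  res <- across_sample_rna_protein(po)
  expect_true(is.na(res$coefficient[res$gene_id == "Gconst"]))
  expect_false(res$significant[res$gene_id == "Gconst"])
})

test_that("gene-coupled generator recovers the configured r_s median", {
  cfg <- generator_config(n_proteins = 800, rna_rs_location = 0.31,
                          rna_rs_spread = 0.15,
                          samples_per_lineage = c(breast = 30, lung = 30),
                          seed = 23)
  sim <- generate_multistudy(cfg)
  rna <- generate_paired_rna(sim$truth, cfg, coupling = "gene")
  po <- paired_omics(sim$truth$true_log2, rna)
  res <- across_sample_rna_protein(po)
  expect_lt(abs(median(res$coefficient, na.rm = TRUE) - 0.31), 0.05)
})

test_that("lineage ANOVA reduces to one-way F in a balanced one-study design", {
  set.seed(24)
  df <- data.frame(coefficient = c(rnorm(10, 0.5, 0.05), rnorm(10, 0.6, 0.05)),
                   lineage = rep(c("breast", "lung"), each = 10),
                   study = "s1")
  suppressMessages(res <- lineage_anova(df, min_group_size = 4))
  direct <- summary(aov(coefficient ~ lineage, data = df))
  expect_equal(res$anova[[1]]["lineage", "F value"],
               direct[[1]]["lineage", "F value"])
  expect_true("breast" %in% res$lineages_kept)
})

test_that("a planted lineage shift is detected by Tukey HSD", {
  set.seed(25)
  lin <- rep(c("breast", "lung", "colorectal"), each = 12)
  study <- rep(c("s1", "s2"), 18)
  mu <- ifelse(lin == "lung", 0.7, 0.5)
  df <- data.frame(coefficient = rnorm(36, mu, 0.02), lineage = lin,
                   study = study)
  res <- lineage_anova(df, min_group_size = 4)
  tuk <- as.data.frame(res$tukey)
  lung_rows <- grepl("lung", rownames(tuk))
  expect_true(all(tuk[lung_rows, "p adj"] < 0.05))
  expect_true(all(tuk[!lung_rows, "p adj"] > 0.05))
})

test_that("lineage ANOVA drops small lineages and errors on one level", {
  df <- data.frame(coefficient = rnorm(10), lineage = "breast", study = "s1")
  expect_error(suppressMessages(lineage_anova(df)), "fewer than 2")
  df2 <- data.frame(coefficient = rnorm(9),
                    lineage = c(rep("breast", 4), rep("lung", 4), "skin"),
                    study = rep(c("s1", "s2"), length.out = 9))
  res <- lineage_anova(df2, min_group_size = 4)
  expect_setequal(res$lineages_kept, c("breast", "lung"))
})
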