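#' Run the full landscape pipeline on synthetic data
#'
#' Orchestrates the end-to-end analysis in simulate mode: generate a
#' cell-line and a tumour multi-study dataset, normalize each side
#' separately (ppb, log2, presence filter, imputation, batch removal),
#' merge by razor protein, extract the tumour-specific peptide landscape,
#' compute concordance statistics (sample-sample correlations, CV, paired
#' mRNA-protein correlations with BH control), run preranked GSEA on the
#' gene-wise correlation ranking, and emit validation diagnostics. All
#' result tables are written as TSV into `out_dir` together with a
#' manifest recording the configuration, seed and per-stage dimensions.
#'
#' @param out_dir output directory (created if absent).
#' @param cell_config,tumour_config [generator_config()]s for the two
#'   sides; the tumour default flips `sample_type` and shifts the seed.
#' @param norm_config a [normalization_config()].
#' @param gene_sets optional named list of gene sets for GSEA; by default
#'   two synthetic sets are built from the ranked list (top block and a
#'   random set).
#' @param seed global seed; overrides the seeds in both generator configs.
#' @return (invisibly) a list with every in-memory result plus
#'   `manifest`, a character vector also written to
#'   `file.path(out_dir, "manifest.txt")`.
#' @export
run_pipeline <- function(out_dir,
                         cell_config = generator_config(
                           n_proteins = 300, mcar_rate = 0.05, seed = 1L),
                         tumour_config = generator_config(
                           n_proteins = 300, mcar_rate = 0.05,
                           sample_type = "tumour", seed = 2L),
                         norm_config = normalization_config(),
                         gene_sets = NULL,
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  note <- function(fmt, ...) manifest <<- c(manifest, sprintf(fmt, ...))
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note("wrote %s (%d rows)", basename(path), nrow(df))
  }
  cell_config$seed <- as.integer(seed)
  tumour_config$seed <- as.integer(seed) + 1000L
  note("pipeline seed: %d", seed)

  # --- simulate and normalize each side separately
  sides <- list(cell_line = generate_multistudy(cell_config),
                tumour = generate_multistudy(tumour_config))
  normed <- lapply(names(sides), function(nm) {
    s <- sides[[nm]]
    m <- run_normalization(s$matrix, s$annotation, norm_config)
    note("%s: raw %d x %d -> corrected %d x %d", nm,
         nrow(s$matrix$values), ncol(s$matrix$values),
         nrow(m$values), ncol(m$values))
    m
  })
  names(normed) <- names(sides)

  # tumour assay/sample ids are shared between the two generator runs, so
  # namespace them per side before merging
  rename_side <- function(m, ann, prefix) {
    v <- intensity_values(m)
    colnames(v) <- paste0(prefix, colnames(v))
    ann$assay_id <- paste0(prefix, ann$assay_id)
    ann$sample_id <- paste0(prefix, ann$sample_id)
    ann$study_id <- paste0(prefix, ann$study_id)
    list(matrix = intensity_matrix(v, m$stage), annotation = ann)
  }
  cl <- rename_side(normed$cell_line, sides$cell_line$annotation, "CL_")
  tu <- rename_side(normed$tumour, sides$tumour$annotation, "TU_")
  annotation <- assay_annotation(rbind(as.data.frame(cl$annotation)[
    names(as.data.frame(cl$annotation)) != "lineage_known"],
    as.data.frame(tu$annotation)[
      names(as.data.frame(tu$annotation)) != "lineage_known"]))

  landscape <- merge_by_razor(cl$matrix, tu$matrix)
  note("merged landscape: union %d, intersection %d",
       length(landscape$union_ids), length(landscape$intersection_ids))
  write_expression_matrix(landscape$matrix,
                          file.path(out_dir, "landscape_matrix.tsv"),
                          id_name = "protein_id")
  emit(landscape$provenance, "landscape_provenance")
  coverage <- coverage_report(landscape, annotation)
  emit(coverage$per_group, "coverage_per_group")

  # --- peptide landscape on a planted fixture
  pep_cfg <- cell_config
  pep_cfg$seed <- as.integer(seed) + 2000L
  fixture <- generate_peptide_fixture(pep_cfg)
  tonly <- tumour_only_peptides(fixture$table, fixture$annotation)
  uniq <- unique_mapping_filter(tonly, fixture$table)
  ts_prot <- tumour_specific_proteins(uniq, fixture$table, fixture$annotation)
  per_lineage <- majority_detection(fixture$table, fixture$annotation,
                                    group_by = "lineage")
  tum_lineages <- unique(fixture$annotation$lineage[
    fixture$annotation$sample_type == "tumour"])
  ts_sets <- lapply(per_lineage[tum_lineages], intersect, x = ts_prot)
  icounts <- intersection_counts(ts_sets[lengths(ts_sets) > 0])
  note("peptides: %d tumour-only, %d unique, %d tumour-specific proteins",
       length(tonly), length(uniq), length(ts_prot))
  emit(data.frame(peptide = uniq), "tumour_only_unique_peptides")
  emit(data.frame(protein = ts_prot), "tumour_specific_proteins")
  if (nrow(icounts)) emit(icounts, "lineage_intersections")

  # --- concordance
  corr <- pairwise_correlation(landscape$matrix, method = "pearson",
                               min_overlap = 10)
  emit(as.data.frame(corr), "pairwise_correlations")
  wb <- within_between_summary(corr, annotation)
  emit(data.frame(category = names(wb$medians), median = wb$medians),
       "within_between_medians")
  cv <- cv_by_group(landscape$matrix, annotation, from_log2 = TRUE)
  emit(cv, "cv_by_group")

  rna <- generate_paired_rna(sides$cell_line$truth, cell_config,
                             coupling = "gene")
  sample_map <- stats::setNames(
    sides$cell_line$annotation$sample_id,
    paste0("CL_", sides$cell_line$annotation$assay_id))
  paired <- paired_omics(cl$matrix$values, rna, sample_of_assay = sample_map)
  within_rs <- within_sample_rna_protein(paired)
  across_rs <- across_sample_rna_protein(paired)
  emit(within_rs, "rna_protein_within_sample")
  emit(across_rs, "rna_protein_across_sample")
  note("median within-sample r_s: %.3f",
       stats::median(within_rs$coefficient, na.rm = TRUE))
  note("median gene-wise r_s: %.3f",
       stats::median(across_rs$coefficient, na.rm = TRUE))

  # --- GSEA on the gene-wise correlation ranking
  ok <- !is.na(across_rs$coefficient)
  ranked <- ranked_gene_list(across_rs$gene_id[ok], across_rs$coefficient[ok])
  if (is.null(gene_sets)) {
    set.seed(seed + 3000L)
    gene_sets <- list(top_coupled = names(ranked)[seq_len(20)],
                      random_set = sample(names(ranked), 20))
  }
  gsea <- gsea_preranked(ranked, gene_sets, n_permutations = 1000,
                         seed = seed + 4000L)
  emit(gsea, "gsea_results")

  # --- validation diagnostics (cell-line side)
  raw_log2 <- intensity_matrix(log2(intensity_values(sides$cell_line$matrix)),
                               "log2_ppb")
  dens_before <- density_profiles(raw_log2, sides$cell_line$annotation)
  dens_after <- density_profiles(normed$cell_line, sides$cell_line$annotation)
  note("location spread before %.3f, after %.3f",
       dens_before$location_spread, dens_after$location_spread)
  anchors <- sides$cell_line$truth$anchor_abundance
  if (!is.null(anchors)) {
    amap <- stats::setNames(sides$cell_line$annotation$sample_id,
                            sides$cell_line$annotation$assay_id)
    av <- anchor_validation(
      list(raw = sides$cell_line$matrix, corrected = normed$cell_line),
      anchors, sample_of_assay = amap)
    emit(av$per_assay, "anchor_validation")
    note("anchor medians: raw %.3f, corrected %.3f",
         av$medians[["raw"]], av$medians[["corrected"]])
  }

  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(landscape = landscape, annotation = annotation,
                 coverage = coverage, tumour_specific = ts_prot,
                 correlations = corr, cv = cv, within_rs = within_rs,
                 across_rs = across_rs, gsea = gsea, manifest = manifest))
}
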