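#' Configuration for the multi-study synthetic data generator
#'
#' Collects every knob of the synthetic world: lineage-structured true
#' protein abundances over a wide dynamic range, study-level batch offsets
#' (additive in log2, i.e. multiplicative on intensities), measurement
#' noise, abundance-dependent (MNAR, logistic detection curve) and random
#' (MCAR) missingness, anchor proteins with known absolute abundance, and
#' the per-gene target mRNA-protein correlation distribution.
#'
#' Defaults describe the regime the pipeline targets: a ~5 orders of
#' magnitude dynamic range, study offsets of ~1 log2 unit, and a gene-wise
#' mRNA-protein Spearman distribution located at 0.31.
#'
#' @param n_proteins number of proteins (= genes) simulated.
#' @param n_studies number of studies; each assay belongs to one study and
#'   all assays of a study share its batch offset.
#' @param samples_per_lineage named integer vector, lineage -> sample count.
#' @param sample_type single value or one per sample: `"cell_line"`,
#'   `"tumour"` or `"normal"`.
#' @param batch_offset_sd sd (log2 units) of the global per-study offset.
#' @param batch_protein_sd sd of optional per-protein jitter around the
#'   study offset; 0 = purely global offsets.
#' @param lineage_sd sd (log2 units) of per-protein lineage effects; samples
#'   of one lineage share the resulting lineage mean profile.
#' @param sample_sd sd (log2 units) of per-sample biological deviation
#'   around the lineage mean profile; 0 makes same-lineage samples
#'   identical in truth.
#' @param noise_sd sd (log2 units) of per-assay measurement noise.
#' @param dynamic_range_log10 span of protein baseline abundances in orders
#'   of magnitude.
#' @param mnar_midpoint true log2 abundance at which detection probability
#'   is 0.5; `NA` disables MNAR masking.
#' @param mnar_slope slope of the logistic detection curve (per log2 unit).
#' @param mcar_rate probability that any entry is masked completely at
#'   random, in `[0, 1]`.
#' @param anchor_count number of anchor proteins carrying absolute
#'   copies-per-cell abundances.
#' @param anchor_noise_sd sd (log10 units) of rank noise added to anchor
#'   copies per cell; 0 keeps anchors a monotone transform of the truth.
#' @param rna_rs_location,rna_rs_spread location and spread of the Gaussian
#'   from which per-gene target mRNA-protein Spearman correlations are
#'   drawn (truncated to (-0.9, 0.95)).
#' @param assay_rs_target target within-assay (across genes) mRNA-protein
#'   Spearman used by [generate_paired_rna()] in `"assay"` coupling mode.
#' @param peptide_class_counts named integer vector of planted peptide
#'   classes for [generate_peptide_fixture()]: `tumour_only_unique`,
#'   `tumour_only_ambiguous`, `confounded`, `cell_line_only`, `shared`.
#' @param peptide_n_cell_assays,peptide_n_tumour_assays assay counts for the
#'   peptide fixture.
#' @param seed integer seed fixing the full output bit-for-bit.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 1000,
                             n_studies = 3,
                             samples_per_lineage = c(breast = 4, colorectal = 4,
                                                     lung = 4, skin = 4,
                                                     ovarian = 4, brain = 4),
                             sample_type = "cell_line",
                             batch_offset_sd = 1.0,
                             batch_protein_sd = 0,
                             lineage_sd = 1.0,
                             sample_sd = 0.5,
                             noise_sd = 0.3,
                             dynamic_range_log10 = 5,
                             mnar_midpoint = NA_real_,
                             mnar_slope = 1.0,
                             mcar_rate = 0,
                             anchor_count = 14,
                             anchor_noise_sd = 0,
                             rna_rs_location = 0.31,
                             rna_rs_spread = 0.15,
                             assay_rs_target = 0.58,
                             peptide_class_counts = c(tumour_only_unique = 5,
                                                      tumour_only_ambiguous = 2,
                                                      confounded = 2,
                                                      cell_line_only = 10,
                                                      shared = 10),
                             peptide_n_cell_assays = 4,
                             peptide_n_tumour_assays = 4,
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_studies = as.integer(n_studies),
              samples_per_lineage = samples_per_lineage,
              sample_type = sample_type,
              batch_offset_sd = batch_offset_sd,
              batch_protein_sd = batch_protein_sd,
              lineage_sd = lineage_sd,
              sample_sd = sample_sd,
              noise_sd = noise_sd,
              dynamic_range_log10 = dynamic_range_log10,
              mnar_midpoint = mnar_midpoint,
              mnar_slope = mnar_slope,
              mcar_rate = mcar_rate,
              anchor_count = as.integer(anchor_count),
              anchor_noise_sd = anchor_noise_sd,
              rna_rs_location = rna_rs_location,
              rna_rs_spread = rna_rs_spread,
              assay_rs_target = assay_rs_target,
              peptide_class_counts = peptide_class_counts,
              peptide_n_cell_assays = as.integer(peptide_n_cell_assays),
              peptide_n_tumour_assays = as.integer(peptide_n_tumour_assays),
              seed = as.integer(seed))
  n_samples <- sum(cfg$samples_per_lineage)
  if (cfg$n_proteins < 1) stop("n_proteins must be >= 1")
  if (cfg$n_studies < 1) stop("n_studies must be >= 1")
  if (is.null(names(cfg$samples_per_lineage)) ||
      any(!nzchar(names(cfg$samples_per_lineage))))
    stop("samples_per_lineage must be a named vector (lineage -> count)")
  if (any(cfg$samples_per_lineage < 1))
    stop("samples_per_lineage counts must be >= 1")
  if (n_samples < 2)
    stop("degenerate config: at least 2 samples are required")
  if (cfg$mcar_rate < 0 || cfg$mcar_rate > 1)
    stop("mcar_rate must be in [0, 1]")
  if (cfg$anchor_count > cfg$n_proteins)
    stop("anchor_count cannot exceed n_proteins")
  if (!length(cfg$sample_type) %in% c(1L, n_samples))
    stop("sample_type must have length 1 or one entry per sample")
  if (any(!cfg$sample_type %in% c("cell_line", "tumour", "normal")))
    stop("invalid sample_type value(s)")
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a multi-study proteomics dataset with known ground truth
#'
#' Simulates the aggregated-dataset regime: lineage-structured true log2
#' abundances, per-study additive log2 batch offsets, Gaussian measurement
#' noise, and MNAR (logistic on true abundance) plus MCAR masking. Observed
#' raw intensity is `2^(true_log2 + batch_offset + noise)` where not masked.
#'
#' @param config a [generator_config()].
#' @return list with `matrix` (an [intensity_matrix()] at stage `raw_ibaq`),
#'   `annotation` (an [assay_annotation()]) and `truth` (class
#'   `synthetic_truth`: `true_log2`, `batch_offsets` (proteins x studies),
#'   `missing_mechanism` ("observed"/"mnar"/"mcar" per entry),
#'   `gene_rs_targets`, `anchor_abundance` (anchors x samples, copies per
#'   cell), `config`).
#' @examples
#' sim <- generate_multistudy(generator_config(n_proteins = 50, seed = 7))
#' sim$matrix
#' @export
generate_multistudy <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_p <- config$n_proteins
  lineages <- rep(names(config$samples_per_lineage), config$samples_per_lineage)
  n_s <- length(lineages)
  sample_type <- rep(config$sample_type, length.out = n_s)
  prot_ids <- sprintf("P%04d", seq_len(n_p))
  sample_ids <- sprintf("S%03d", seq_len(n_s))
  assay_ids <- sprintf("A%03d", seq_len(n_s))
  # assign studies round-robin within each lineage so study and lineage are
  # not confounded and equal-sized lineages give every study the same
  # lineage composition
  study <- sprintf("study%d", unlist(lapply(
    unname(config$samples_per_lineage),
    function(k) rep_len(seq_len(config$n_studies), k))))

  baseline <- stats::runif(n_p, min = 8,
                           max = 8 + config$dynamic_range_log10 * log2(10))
  lin_names <- names(config$samples_per_lineage)
  lin_effect <- matrix(stats::rnorm(n_p * length(lin_names), 0, config$lineage_sd),
                       n_p, length(lin_names), dimnames = list(prot_ids, lin_names))
  true_log2 <- baseline + lin_effect[, lineages, drop = FALSE]
  if (config$sample_sd > 0)
    true_log2 <- true_log2 +
      matrix(stats::rnorm(n_p * n_s, 0, config$sample_sd), n_p, n_s)
  dimnames(true_log2) <- list(prot_ids, sample_ids)

  study_names <- sprintf("study%d", seq_len(config$n_studies))
  offs_global <- stats::rnorm(config$n_studies, 0, config$batch_offset_sd)
  batch_offsets <- matrix(rep(offs_global, each = n_p), n_p, config$n_studies,
                          dimnames = list(prot_ids, study_names))
  if (config$batch_protein_sd > 0)
    batch_offsets <- batch_offsets +
      matrix(stats::rnorm(n_p * config$n_studies, 0, config$batch_protein_sd),
             n_p, config$n_studies)

  noise <- if (config$noise_sd > 0)
    matrix(stats::rnorm(n_p * n_s, 0, config$noise_sd), n_p, n_s) else 0
  obs_log2 <- true_log2 + batch_offsets[, match(study, study_names), drop = FALSE] + noise
  values <- 2^obs_log2
  dimnames(values) <- list(prot_ids, assay_ids)

  mechanism <- matrix("observed", n_p, n_s, dimnames = list(prot_ids, assay_ids))
  if (is.finite(config$mnar_midpoint)) {
    p_detect <- stats::plogis(config$mnar_slope * (true_log2 - config$mnar_midpoint))
    mnar_mask <- matrix(stats::runif(n_p * n_s), n_p, n_s) > p_detect
    mechanism[mnar_mask] <- "mnar"
  }
  if (config$mcar_rate > 0) {
    mcar_mask <- matrix(stats::runif(n_p * n_s), n_p, n_s) < config$mcar_rate
    mechanism[mcar_mask & mechanism == "observed"] <- "mcar"
  }
  values[mechanism != "observed"] <- NA_real_

  rs <- stats::rnorm(n_p, config$rna_rs_location, config$rna_rs_spread)
  gene_rs_targets <- stats::setNames(pmin(pmax(rs, -0.9), 0.95), prot_ids)

  anchor_abundance <- NULL
  if (config$anchor_count > 0) {
    # anchors span the dynamic range: pick proteins at evenly spaced
    # abundance quantiles, then map truth monotonically onto 1e2..1e6 cpc
    qidx <- order(baseline)[round(seq(1, n_p, length.out = config$anchor_count))]
    anchor_ids <- prot_ids[sort(qidx)]
    t_sub <- true_log2[anchor_ids, , drop = FALSE]
    rng <- range(t_sub)
    span <- if (diff(rng) > 0) diff(rng) else 1
    log10_cpc <- 2 + 4 * (t_sub - rng[1]) / span
    if (config$anchor_noise_sd > 0)
      log10_cpc <- log10_cpc + matrix(stats::rnorm(length(t_sub), 0,
                                                   config$anchor_noise_sd),
                                      nrow(t_sub), ncol(t_sub))
    anchor_abundance <- 10^log10_cpc
    dimnames(anchor_abundance) <- list(anchor_ids, sample_ids)
  }

  annotation <- assay_annotation(data.frame(
    assay_id = assay_ids, study_id = study, sample_id = sample_ids,
    sample_type = sample_type, lineage = lineages,
    replicate_group = sample_ids, enzyme = "trypsin",
    stringsAsFactors = FALSE))

  truth <- structure(list(true_log2 = true_log2,
                          batch_offsets = batch_offsets,
                          missing_mechanism = mechanism,
                          gene_rs_targets = gene_rs_targets,
                          anchor_abundance = anchor_abundance,
                          sample_study = stats::setNames(study, sample_ids),
                          config = config),
                     class = "synthetic_truth")
  list(matrix = intensity_matrix(values, "raw_ibaq"),
       annotation = annotation, truth = truth)
}

# Spearman target -> Pearson correlation of the Gaussian copula;
# |rs| = 1 maps to exactly +/-1 so the degenerate case adds no noise at all
.copula_rho <- function(rs) {
  r <- 2 * sin(pi * rs / 6)
  r[rs >= 1] <- 1
  r[rs <= -1] <- -1
  r
}

# normal scores of a vector (no ties in the generator's continuous truth)
.normal_scores <- function(x) stats::qnorm((rank(x) - 0.5) / length(x))

#' Generate a paired mRNA (FPKM-like) matrix coupled to the protein truth
#'
#' Couples mRNA to true protein abundance through a Gaussian copula so the
#' target Spearman correlation can be set directly. Two coupling modes:
#'
#' * `"gene"` (default): per gene, the across-sample Spearman between mRNA
#'   and true protein abundance converges to `truth$gene_rs_targets` as the
#'   sample count grows.
#' * `"assay"`: per sample, the across-gene Spearman converges to
#'   `config$assay_rs_target`, emulating the within-sample mRNA-protein
#'   concordance regime.
#'
#' mRNA values are strictly positive (log-normal marginal), FPKM-like.
#'
#' @param truth a `synthetic_truth` from [generate_multistudy()].
#' @param config the [generator_config()] used to generate it.
#' @param coupling `"gene"` or `"assay"`.
#' @return numeric matrix, genes x samples, non-negative.
#' @export
generate_paired_rna <- function(truth, config, coupling = c("gene", "assay")) {
  if (!inherits(truth, "synthetic_truth"))
    stop("'truth' must be a synthetic_truth produced by generate_multistudy()")
  coupling <- match.arg(coupling)
  set.seed(config$seed + 1L)
  t_mat <- truth$true_log2
  n_g <- nrow(t_mat); n_s <- ncol(t_mat)
  latent <- matrix(NA_real_, n_g, n_s, dimnames = dimnames(t_mat))
  if (coupling == "gene") {
    rho <- .copula_rho(truth$gene_rs_targets[rownames(t_mat)])
    eps <- matrix(stats::rnorm(n_g * n_s), n_g, n_s)
    for (g in seq_len(n_g)) {
      z <- .normal_scores(t_mat[g, ])
      latent[g, ] <- rho[g] * z + sqrt(1 - rho[g]^2) * eps[g, ]
    }
  } else {
    rho <- .copula_rho(config$assay_rs_target)
    eps <- matrix(stats::rnorm(n_g * n_s), n_g, n_s)
    for (j in seq_len(n_s)) {
      z <- .normal_scores(t_mat[, j])
      latent[, j] <- rho * z + sqrt(1 - rho^2) * eps[, j]
    }
  }
  exp(2 + 1.5 * latent)  # log-normal FPKM-like marginal, strictly positive
}

# deterministic pseudo-random peptide sequences (tryptic-looking: end in K/R)
.random_peptides <- function(n, len = 9) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "P", "Q", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    body <- paste(sample(aa, len - 1, replace = TRUE), collapse = "")
    paste0(body, sample(c("K", "R"), 1))
  }, character(1))
}

#' Generate a peptide evidence fixture with planted peptide classes
#'
#' Emits a peptide detection table for cell-line and tumour assays with
#' known class labels: tumour-only unique peptides whose proteins carry no
#' cell-line evidence (the planted tumour-specific proteins), tumour-only
#' unique peptides whose proteins *also* have cell-line evidence
#' ("confounded", hence not tumour-specific), ambiguous (multi-protein)
#' tumour-only peptides, cell-line-only peptides and shared peptides. The
#' planted composition is recorded in the returned truth.
#'
#' @param config a [generator_config()]; class sizes come from
#'   `config$peptide_class_counts` and assay counts from
#'   `config$peptide_n_cell_assays` / `config$peptide_n_tumour_assays`.
#' @return list with `table` (a [peptide_evidence()] data.frame),
#'   `annotation` (an [assay_annotation()]) and `truth` (planted peptide
#'   sets and the tumour-specific protein set).
#' @export
generate_peptide_fixture <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$peptide_n_tumour_assays < 1)
    stop("the peptide fixture requires at least one tumour assay")
  set.seed(config$seed + 2L)
  cnt <- config$peptide_class_counts
  for (k in c("tumour_only_unique", "tumour_only_ambiguous", "confounded",
              "cell_line_only", "shared"))
    if (is.na(cnt[k])) cnt[k] <- 0

  n_cell <- config$peptide_n_cell_assays
  n_tum <- config$peptide_n_tumour_assays
  cell_assays <- sprintf("CL%02d", seq_len(max(n_cell, 0)))
  tum_assays <- sprintf("TU%02d", seq_len(n_tum))
  tum_lineages <- rep_len(c("colorectal", "ovarian", "prostate"), n_tum)
  annotation <- assay_annotation(data.frame(
    assay_id = c(cell_assays, tum_assays),
    study_id = c(rep("study_cl", length(cell_assays)), rep("study_tu", n_tum)),
    sample_id = c(cell_assays, tum_assays),
    sample_type = c(rep("cell_line", length(cell_assays)), rep("tumour", n_tum)),
    lineage = c(rep_len(c("breast", "lung"), length(cell_assays)), tum_lineages),
    stringsAsFactors = FALSE))

  total_pep <- cnt[["tumour_only_unique"]] + cnt[["tumour_only_ambiguous"]] +
    2 * cnt[["confounded"]] + cnt[["cell_line_only"]] + cnt[["shared"]]
  seqs <- unique(.random_peptides(total_pep * 3))
  if (length(seqs) < total_pep) stop("failed to generate enough distinct peptides")
  seqs <- seqs[seq_len(total_pep)]
  take <- function(n) {
    out <- seqs[seq_len(n)]; seqs <<- seqs[-seq_len(n)]; out
  }

  rows <- list()
  add_rows <- function(seqs, proteins, assays) {
    for (i in seq_along(seqs))
      for (a in assays[[i]])
        rows[[length(rows) + 1L]] <<- data.frame(
          peptide_sequence = seqs[i], proteins = proteins[i], assay_id = a,
          detected = TRUE, stringsAsFactors = FALSE)
  }
  pick_assays <- function(pool, n_rows)
    lapply(seq_len(n_rows), function(i)
      sample(pool, sample.int(length(pool), 1)))

  truth <- list()
  # tumour-specific proteins: one unique tumour-only peptide each, nothing else
  n_ts <- cnt[["tumour_only_unique"]]
  ts_prot <- if (n_ts > 0) sprintf("TSP%02d", seq_len(n_ts)) else character()
  ts_pep <- if (n_ts > 0) take(n_ts) else character()
  if (n_ts > 0) add_rows(ts_pep, ts_prot, pick_assays(tum_assays, n_ts))

  # confounded: unique tumour-only peptide + a shared peptide in cell lines
  n_cf <- cnt[["confounded"]]
  cf_prot <- if (n_cf > 0) sprintf("CFP%02d", seq_len(n_cf)) else character()
  cf_pep <- if (n_cf > 0) take(n_cf) else character()
  cf_shared <- if (n_cf > 0) take(n_cf) else character()
  if (n_cf > 0) {
    add_rows(cf_pep, cf_prot, pick_assays(tum_assays, n_cf))
    if (length(cell_assays))
      add_rows(cf_shared, cf_prot, pick_assays(cell_assays, n_cf))
  }

  # ambiguous tumour-only peptides map to two proteins
  n_amb <- cnt[["tumour_only_ambiguous"]]
  amb_pep <- if (n_amb > 0) take(n_amb) else character()
  if (n_amb > 0)
    add_rows(amb_pep, sprintf("AMB%02da;AMB%02db", seq_len(n_amb), seq_len(n_amb)),
             pick_assays(tum_assays, n_amb))

  n_cl <- cnt[["cell_line_only"]]
  cl_pep <- if (n_cl > 0 && length(cell_assays)) take(n_cl) else character()
  if (length(cl_pep))
    add_rows(cl_pep, sprintf("CLP%02d", seq_along(cl_pep)),
             pick_assays(cell_assays, length(cl_pep)))

  n_sh <- cnt[["shared"]]
  sh_pep <- if (n_sh > 0) take(n_sh) else character()
  if (n_sh > 0) {
    sh_prot <- sprintf("SHP%02d", seq_len(n_sh))
    add_rows(sh_pep, sh_prot, pick_assays(tum_assays, n_sh))
    if (length(cell_assays))
      add_rows(sh_pep, sh_prot, pick_assays(cell_assays, n_sh))
  }

  table <- peptide_evidence(do.call(rbind, rows))
  truth$tumour_only_peptides <- sort(c(ts_pep, cf_pep, amb_pep))
  truth$tumour_only_unique_peptides <- sort(c(ts_pep, cf_pep))
  truth$ambiguous_tumour_only_peptides <- sort(amb_pep)
  truth$tumour_specific_proteins <- sort(ts_prot)
  truth$confounded_proteins <- sort(cf_prot)
  truth$cell_line_only_peptides <- sort(cl_pep)
  truth$shared_peptides <- sort(sh_pep)
  list(table = table, annotation = annotation, truth = truth)
}
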