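#' Build a ranked gene list
#'
#' Orders genes by a ranking score (for the landscape: the gene-wise
#' mRNA-protein Spearman correlation) in decreasing order.
#'
#' @param genes character vector of gene ids (no duplicates).
#' @param scores numeric ranking scores, finite, same length.
#' @return named numeric vector of class `ranked_gene_list`, scores named
#'   by gene, sorted decreasing.
#' @export
ranked_gene_list <- function(genes, scores) {
  if (length(genes) != length(scores)) stop("genes and scores differ in length")
  if (anyDuplicated(genes)) stop("duplicate genes in the ranked list")
  if (any(!is.finite(scores))) stop("ranking scores must be finite")
  out <- sort(stats::setNames(as.numeric(scores), genes), decreasing = TRUE)
  class(out) <- "ranked_gene_list"
  out
}

#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: set name, description, then member
#' genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors
#' @param descriptions optional character vector of set descriptions
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

# Core ES computation from hit positions only (O(set size)).
# hit_idx: positions (1-based, sorted) of the set members in the ranked
# list; w: |score|^weight at those positions; n: list length.
# The running sum is piecewise linear between hits, so its extremum is
# attained either just after a hit increment or just before the next hit.
.es_from_hits <- function(hit_idx, w, n) {
  k <- length(hit_idx)
  sw <- sum(w)
  if (sw == 0) { w <- rep(1, k); sw <- k }  # all-zero scores: unweighted
  miss_dec <- 1 / (n - k)
  cum_hit <- cumsum(w) / sw
  # value just after the j-th hit:
  after <- cum_hit - (hit_idx - seq_len(k)) * miss_dec
  # value just before the j-th hit (all misses since previous hit applied):
  before <- after - w / sw
  extreme <- c(after, before, 0)
  es <- extreme[which.max(abs(extreme))]
  es
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list top to bottom, incrementing the running sum at
#' set members (hits) proportionally to `|score|^weight_exponent`
#' (normalized over the hits) and decrementing by `1/(N - set size)` at
#' non-members. The enrichment score (ES) is the extremum of the running
#' sum; positive ES means enrichment at the top of the list.
#'
#' @param ranked a [ranked_gene_list()].
#' @param gene_set character vector of member genes.
#' @param weight_exponent weighting of hit increments by score magnitude;
#'   0 gives the classic unweighted Kolmogorov-Smirnov statistic.
#' @return list: `es`, `running_sum` (length N profile), `hit_positions`,
#'   `leading_edge` (member genes at or before/after the extremum for
#'   positive/negative ES).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  genes <- names(ranked)
  n <- length(genes)
  hit <- genes %in% gene_set
  k <- sum(hit)
  if (k == 0) stop("gene set has no genes in the ranked list")
  if (k == n) stop("gene set covers the whole ranked list")
  w <- abs(as.numeric(ranked))^weight_exponent
  wh <- w[hit]
  sw <- sum(wh)
  if (sw == 0) { wh <- rep(1, k); sw <- k }
  inc <- numeric(n)
  inc[hit] <- wh / sw
  inc[!hit] <- -1 / (n - k)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  peak <- which.max(abs(running))
  hit_pos <- which(hit)
  leading <- if (es >= 0) genes[hit_pos[hit_pos <= peak]]
             else genes[hit_pos[hit_pos >= peak]]
  list(es = es, running_sum = running, hit_positions = hit_pos,
       leading_edge = leading)
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted Kolmogorov-Smirnov enrichment score of each gene
#' set against the ranked list, builds a null distribution by gene-set
#' permutation (random member sets of matched size drawn from the ranked
#' list), and reports the normalized enrichment score (ES divided by the
#' mean |null ES| of matching sign), a matched-sign nominal permutation
#' p-value, and a standard NES-ratio FDR q-value.
#'
#' @param ranked a [ranked_gene_list()].
#' @param gene_sets named list of character vectors.
#' @param n_permutations null-set permutations per set (default 1000).
#' @param weight_exponent see [enrichment_score()] (default 1).
#' @param seed integer seed; the analysis is deterministic given the seed.
#' @param min_size,max_size gene-set size bounds (after intersection with
#'   the ranked list); sets outside are skipped with a message.
#' @return data.frame: `gene_set`, `size`, `es`, `nes`, `nominal_p`,
#'   `fdr_q`, `leading_edge` (comma-joined gene ids).
#' @export
gsea_preranked <- function(ranked, gene_sets, n_permutations = 1000,
                           weight_exponent = 1, seed = 1L,
                           min_size = 2, max_size = 500) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  if (!length(gene_sets)) stop("at least one gene set is required")
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  set.seed(seed)
  genes <- names(ranked)
  n <- length(genes)
  w_all <- abs(as.numeric(ranked))^weight_exponent

  sizes <- vapply(gene_sets, function(s) sum(genes %in% s), integer(1))
  usable <- sizes >= min_size & sizes <= max_size & sizes < n
  if (any(!usable))
    message("skipping ", sum(!usable), " gene set(s) outside size bounds")
  gene_sets <- gene_sets[usable]
  sizes <- sizes[usable]
  if (!length(gene_sets)) stop("no usable gene sets after size filtering")

  obs <- lapply(gene_sets, function(s)
    enrichment_score(ranked, s, weight_exponent))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  # one null pool per distinct set size (shared across sets of that size)
  null_by_size <- lapply(unique(sizes), function(k) {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sort(sample.int(n, k))
      .es_from_hits(idx, w_all[idx], n)
    }, numeric(1))
  })
  names(null_by_size) <- as.character(unique(sizes))

  res <- data.frame(gene_set = names(gene_sets), size = sizes,
                    es = es_obs, nes = NA_real_, nominal_p = NA_real_,
                    fdr_q = NA_real_,
                    leading_edge = vapply(obs, function(o)
                      paste(o$leading_edge, collapse = ","), character(1)),
                    stringsAsFactors = FALSE, row.names = NULL)

  all_null_nes <- numeric()
  null_nes_list <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    null_es <- null_by_size[[as.character(res$size[i])]]
    pos <- null_es[null_es >= 0]; neg <- null_es[null_es < 0]
    mean_pos <- if (length(pos)) mean(pos) else NA_real_
    mean_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    es <- res$es[i]
    if (es >= 0) {
      res$nes[i] <- if (is.na(mean_pos) || mean_pos == 0) NA_real_ else es / mean_pos
      res$nominal_p[i] <- if (length(pos)) mean(pos >= es) else NA_real_
    } else {
      res$nes[i] <- if (is.na(mean_neg) || mean_neg == 0) NA_real_ else es / mean_neg
      res$nominal_p[i] <- if (length(neg)) mean(neg <= es) else NA_real_
    }
    null_nes <- c(if (!is.na(mean_pos) && mean_pos > 0) pos / mean_pos,
                  if (!is.na(mean_neg) && mean_neg > 0) neg / mean_neg)
    null_nes_list[[i]] <- null_nes
    all_null_nes <- c(all_null_nes, null_nes)
  }
  # FDR q: fraction of pooled null NES at least as extreme (matched sign)
  # over fraction of observed NES at least as extreme, clipped to [0, 1]
  for (i in seq_len(nrow(res))) {
    nes <- res$nes[i]
    if (is.na(nes)) next
    if (nes >= 0) {
      null_frac <- mean(all_null_nes[all_null_nes >= 0] >= nes)
      obs_frac <- mean(res$nes[res$nes >= 0] >= nes, na.rm = TRUE)
    } else {
      null_frac <- mean(all_null_nes[all_null_nes < 0] <= nes)
      obs_frac <- mean(res$nes[res$nes < 0] <= nes, na.rm = TRUE)
    }
    res$fdr_q[i] <- min(1, if (obs_frac > 0) null_frac / obs_frac else 1)
  }
  res[order(-res$nes), , drop = FALSE]
}
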