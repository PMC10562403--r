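#' Log-normalize a UMI expression matrix
#'
#' Per cell: `ln(1 + count / cell_total * 1e4)`. Cells with zero total map to
#' zeros.
#'
#' @param counts Non-negative cells x genes matrix.
#' @param scale_factor Depth scale (default 1e4).
#' @return Dense numeric matrix, same dimnames.
#' @export
normalize_expression <- function(counts, scale_factor = 1e4) {
  m <- as.matrix(counts)
  totals <- rowSums(m)
  log1p(m / ifelse(totals > 0, totals, 1) * scale_factor)
}

#' Rank-based gene-signature score per cell
#'
#' Non-parametric signature scoring in the UCell style: genes are ranked per
#' cell by decreasing count (average ranks for ties), ranks beyond `r_max`
#' are set to `r_max + 1`, and the Mann-Whitney U statistic of the signature
#' genes' ranks is rescaled to a score in [0, 1] (1 = signature genes are the
#' cell's top-expressed genes). Because it uses only ranks, the score is
#' invariant to any strictly monotone per-cell transform of the counts.
#'
#' @param counts Cells x genes matrix (raw or normalized; ranks only).
#' @param signature Character vector of signature gene ids (must be in the
#'   matrix's gene universe).
#' @param r_max Rank ceiling (default 1500).
#' @return Named numeric vector of scores, one per cell.
#' @export
rank_signature_score <- function(counts, signature, r_max = 1500L) {
  if (length(signature) == 0L) pt_stop("empty_signature", "empty signature")
  m <- as.matrix(counts)
  miss <- setdiff(signature, colnames(m))
  if (length(miss)) {
    pt_stop("empty_signature", "signature gene(s) absent from matrix: %s",
            paste(miss, collapse = ", "))
  }
  n <- length(signature)
  if (r_max < n) pt_stop("invalid_input", "r_max must be >= signature length")
  scores <- apply(m, 1L, function(x) {
    r <- rank(-x, ties.method = "average")
    r[r > r_max] <- r_max + 1
    u <- sum(r[signature]) - n * (n + 1) / 2
    1 - u / (n * r_max)
  })
  pmin(pmax(scores, 0), 1)
}

#' Assign cells to states by competing signature scores
#'
#' Each cell is scored against every signature with
#' [rank_signature_score()] and assigned the arg-max state; exact ties give
#' `NA` (unassigned).
#'
#' @param counts Cells x genes matrix.
#' @param signatures Named list of signature gene vectors (>= 2).
#' @param r_max Rank ceiling passed through.
#' @return A list with `state` (named character vector, `NA` = unassigned)
#'   and `scores` (cells x signatures matrix).
#' @export
assign_cell_state <- function(counts, signatures, r_max = 1500L) {
  if (length(signatures) < 2L) {
    pt_stop("invalid_input", "need at least 2 signatures")
  }
  sc <- vapply(signatures, function(sig)
    rank_signature_score(counts, sig, r_max), numeric(nrow(counts)))
  state <- apply(sc, 1L, function(v) {
    top <- which(v == max(v))
    if (length(top) > 1L) NA_character_ else colnames(sc)[top]
  })
  list(state = setNames(state, rownames(counts)), scores = sc)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene, a two-sided Wilcoxon rank-sum test on the log-normalized
#' expression (exact when both groups have fewer than 50 cells and no ties,
#' otherwise the normal approximation with tie and continuity corrections),
#' with Benjamini-Hochberg adjustment across genes. The reported fold change
#' is `ln((mean_A + 1) / (mean_B + 1))` on depth-normalized (not logged)
#' means.
#'
#' @param counts Cells x genes UMI matrix.
#' @param cells_a,cells_b Cell ids of the two groups (>= 3 each).
#' @param scale_factor Depth scale for normalization (default 1e4).
#' @return Data frame with columns `gene`, `lfc`, `statistic` (rank-sum W),
#'   `p`, `q`, ordered as in the input matrix.
#' @export
wilcoxon_de <- function(counts, cells_a, cells_b, scale_factor = 1e4) {
  if (length(cells_a) < 3L || length(cells_b) < 3L) {
    pt_stop("group_too_small", "both groups need at least 3 cells")
  }
  m <- as.matrix(counts)
  norm <- normalize_expression(m, scale_factor)
  depth <- expm1(norm)  # depth-normalized, not logged
  a <- norm[cells_a, , drop = FALSE]
  b <- norm[cells_b, , drop = FALSE]
  res <- vapply(seq_len(ncol(m)), function(j) {
    wt <- suppressWarnings(wilcox.test(a[, j], b[, j]))
    p <- wt$p.value
    # all pooled values tied: the rank-sum variance is zero and the normal
    # approximation degenerates; there is no evidence against the null
    if (is.na(p)) p <- 1
    c(wt$statistic, min(p, 1))
  }, numeric(2))
  data.frame(gene = colnames(m),
             lfc = log((colMeans(depth[cells_a, , drop = FALSE]) + 1) /
                         (colMeans(depth[cells_b, , drop = FALSE]) + 1)),
             statistic = res[1L, ],
             p = res[2L, ],
             q = p.adjust(res[2L, ], method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold changes of each perturbation against the reference
#'
#' Entry (label, gene) = (mean depth-normalized expression in the label's
#' cells + 1) / (mean in the reference cells + 1). Restricting `gene_list`
#' to the targeted genes themselves yields the cross-regulation view
#' (how each knockout shifts the other targets' transcripts).
#'
#' @param counts Cells x genes UMI matrix.
#' @param labels Data frame with `cell_id`, `label`.
#' @param gene_list Genes to report (default: all).
#' @param reference Reference label (default `"NT"`).
#' @param scale_factor Depth scale (default 1e4).
#' @return Labels x genes numeric matrix of fold changes; the reference row
#'   is all ones.
#' @export
fold_change_matrix <- function(counts, labels, gene_list = NULL,
                               reference = "NT", scale_factor = 1e4) {
  if (!reference %in% labels$label) {
    pt_stop("missing_reference", "reference label '%s' absent", reference)
  }
  m <- as.matrix(counts)
  gene_list <- gene_list %||% colnames(m)
  depth <- expm1(normalize_expression(m, scale_factor))[, gene_list,
                                                        drop = FALSE]
  labs <- sort(unique(labels$label))
  ref_mean <- colMeans(depth[labels$cell_id[labels$label == reference], ,
                             drop = FALSE])
  out <- t(vapply(labs, function(l) {
    (colMeans(depth[labels$cell_id[labels$label == l], , drop = FALSE]) + 1) /
      (ref_mean + 1)
  }, numeric(length(gene_list))))
  dimnames(out) <- list(labs, gene_list)
  out
}

#' Differential-expression selection rule
#'
#' @param padj_max Adjusted-p ceiling (default 0.1).
#' @param basemean_min Minimum baseMean, exclusive (default 5).
#' @param lfc_offset,lfc_coef The baseMean-dependent absolute log2
#'   fold-change threshold `lfc_coef / sqrt(baseMean) + lfc_offset`
#'   (defaults 0.3 and 5): weakly expressed genes must clear a larger fold
#'   change, reflecting their noisier estimates.
#' @param mode `"basemean_dependent"` (default) or `"fixed"`.
#' @param lfc_fixed Fixed |log2FC| threshold for `mode = "fixed"` (default 1).
#' @return A list of class `de_rule`.
#' @export
de_selection_rule <- function(padj_max = 0.1, basemean_min = 5,
                              lfc_offset = 0.3, lfc_coef = 5,
                              mode = c("basemean_dependent", "fixed"),
                              lfc_fixed = 1) {
  mode <- match.arg(mode)
  stopifnot(lfc_offset >= 0, lfc_coef >= 0)
  structure(list(padj_max = padj_max, basemean_min = basemean_min,
                 lfc_offset = lfc_offset, lfc_coef = lfc_coef,
                 mode = mode, lfc_fixed = lfc_fixed),
            class = "de_rule")
}

#' Select differentially expressed genes from a DE table
#'
#' A gene is selected iff `padj < padj_max`, `baseMean > basemean_min` and
#' `|log2FoldChange|` exceeds the rule's threshold (baseMean-dependent by
#' default). Genes with missing `padj` are never selected.
#'
#' @param records Data frame with columns `gene`, `baseMean`,
#'   `log2FoldChange`, `padj` (e.g. an exported DESeq2 result table).
#' @param rule A [de_selection_rule()].
#' @return Character vector of selected gene ids.
#' @export
select_de_genes <- function(records, rule = de_selection_rule()) {
  thr <- if (rule$mode == "basemean_dependent") {
    rule$lfc_coef / sqrt(records$baseMean) + rule$lfc_offset
  } else {
    rule$lfc_fixed
  }
  keep <- !is.na(records$padj) & records$padj < rule$padj_max &
    records$baseMean > rule$basemean_min &
    abs(records$log2FoldChange) > thr
  records$gene[keep]
}

#' Row z-scoring plus k-means clustering for heatmaps
#'
#' Rows (genes) are standardized to mean 0 and sd 1 across the columns
#' (conditions); constant rows map to all-zero. K-means then partitions the
#' rows with `nstart` random restarts under a fixed seed, so the clustering
#' is reproducible.
#'
#' @param mat Genes x conditions numeric matrix.
#' @param k Number of clusters (<= number of rows).
#' @param seed Seed for the k-means restarts (default 1).
#' @param nstart Number of restarts (default 25).
#' @return A list with `cluster` (named integer vector) and `zmat` (the
#'   z-scored matrix).
#' @export
cluster_zscore_kmeans <- function(mat, k, seed = 1L, nstart = 25L) {
  m <- as.matrix(mat)
  if (k > nrow(m)) pt_stop("k_too_large", "k = %d exceeds %d rows", k, nrow(m))
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  km <- kmeans(z, centers = k, nstart = nstart, iter.max = 100L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(cluster = setNames(km$cluster, rownames(m)), zmat = z)
}
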