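#' Per-guide log2 fold change between sorted bins
#'
#' Counts in each bin are scaled to counts-per-million, then
#' `lfc = log2((cpm_high + pc) / (cpm_low + pc))`; the mean abundance is the
#' average of the two cpm values. Used to quantify guide enrichment in e.g.
#' CD86-high versus CD86-low sorted populations.
#'
#' @param table Data frame with columns `gRNA`, `gene`, `is_nt`,
#'   `count_high`, `count_low`.
#' @param pseudocount Added to both cpm values (default 1).
#' @param normalization `"cpm"` (default) or `"median_ratio"` (DESeq-style
#'   size factors on the two bins).
#' @return The input with added columns `cpm_high`, `cpm_low`, `lfc`,
#'   `mean_abundance`.
#' @export
guide_log2fc <- function(table, pseudocount = 1,
                         normalization = c("cpm", "median_ratio")) {
  normalization <- match.arg(normalization)
  th <- sum(table$count_high); tl <- sum(table$count_low)
  if (th == 0 || tl == 0) pt_stop("empty_bin", "a sorting bin has zero reads")
  if (normalization == "cpm") {
    ch <- table$count_high / th * 1e6
    cl <- table$count_low / tl * 1e6
  } else {
    # median-of-ratios size factors over guides present in both bins
    both <- table$count_high > 0 & table$count_low > 0
    geo <- sqrt(table$count_high[both] * table$count_low[both])
    sfh <- median(table$count_high[both] / geo)
    sfl <- median(table$count_low[both] / geo)
    ch <- table$count_high / sfh
    cl <- table$count_low / sfl
  }
  table$cpm_high <- ch
  table$cpm_low <- cl
  table$lfc <- log2((ch + pseudocount) / (cl + pseudocount))
  table$mean_abundance <- (ch + cl) / 2
  table
}

#' Z-score gene ranking against non-targeting guides
#'
#' Guide log2 fold changes are standardized against the non-targeting
#' distribution (`z = (lfc - mean_NT) / sd_NT`); per gene the guide z-scores
#' are combined by the Stouffer rule (`sum(z) / sqrt(m)` over its m guides),
#' giving a gene z whose two-sided normal p-value is BH-adjusted across
#' genes. Rank 1 is the gene most enriched in the high bin. Adding a
#' constant to every guide's lfc leaves all z-scores unchanged.
#'
#' @param effects Output of [guide_log2fc()] (columns `gene`, `is_nt`,
#'   `lfc`).
#' @return Data frame with columns `gene`, `n_guides`, `z`, `p`, `q`,
#'   `rank`, sorted by rank.
#' @export
gene_zscore_rank <- function(effects) {
  nt <- effects$lfc[as.logical(effects$is_nt)]
  if (length(nt) < 2L) {
    pt_stop("no_nt_guides", "need >= 2 non-targeting guides for z-ranking")
  }
  mu <- mean(nt); sdev <- sd(nt)
  if (sdev == 0) pt_stop("no_nt_guides", "non-targeting lfc values are constant")
  targ <- effects[!as.logical(effects$is_nt), , drop = FALSE]
  z_guide <- (targ$lfc - mu) / sdev
  zs <- tapply(z_guide, targ$gene, function(v) sum(v) / sqrt(length(v)))
  out <- data.frame(gene = names(zs),
                    n_guides = as.integer(table(targ$gene)[names(zs)]),
                    z = as.numeric(zs),
                    stringsAsFactors = FALSE)
  out$p <- 2 * pnorm(-abs(out$z))
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(-out$z, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric overlap test for two gene lists
#'
#' Probability of observing at least `x` genes shared between a list of `K`
#' and a list of `n` genes drawn from a universe of `N`, i.e.
#' `P(X >= x)` for X hypergeometric. Computed in log space (stable for
#' genome-sized universes).
#'
#' @param N Universe size (e.g. genes in the reference transcriptome).
#' @param K,n The two list sizes.
#' @param x Observed overlap.
#' @return The upper-tail p-value.
#' @export
hypergeometric_overlap <- function(N, K, n, x) {
  if (K > N || n > N || x > min(K, n) || x < 0) {
    pt_stop("invalid_input",
            "need x <= min(K, n) and K, n <= N (got N=%s K=%s n=%s x=%s)",
            N, K, n, x)
  }
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Chi-squared test with adjusted standardized residuals
#'
#' For an observed perturbations x clusters table, computes the Pearson
#' chi-squared statistic against independence and the adjusted standardized
#' residual of every cell,
#' `r_ij = (O_ij - E_ij) / sqrt(E_ij (1 - row_i/N) (1 - col_j/N))`,
#' which is approximately standard normal under independence and flags which
#' perturbation/cluster pairs drive the association.
#'
#' @param O Non-negative integer matrix (perturbations x clusters).
#' @return A list with `chi2`, `df`, `p`, `expected` and `residuals` (the
#'   adjusted standardized residual matrix).
#' @export
chisq_residuals <- function(O) {
  O <- as.matrix(O)
  if (any(O < 0)) pt_stop("invalid_input", "negative counts")
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  if (any(rs == 0) || any(cs == 0)) {
    pt_stop("zero_margin", "table has an empty row or column")
  }
  E <- outer(rs, cs) / N
  chi2 <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  res <- (O - E) / sqrt(E * outer(1 - rs / N, 1 - cs / N))
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       expected = E, residuals = res)
}
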