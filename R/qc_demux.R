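#' Per-cell QC parameters
#'
#' Cells with unusually high total GDO UMI counts (top five percentiles by
#' default — a signature of multiplets and ambient-guide-rich droplets), few
#' cDNA UMIs, or few detected genes are removed before demultiplexing.
#'
#' @param gdo_total_quantile Quantile above which total GDO counts are
#'   removed (default 0.95).
#' @param min_cdna_umis Minimum cDNA UMIs per cell (default 5000).
#' @param min_genes Minimum detected genes per cell (default 200).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(gdo_total_quantile = 0.95, min_cdna_umis = 5000L,
                      min_genes = 200L) {
  stopifnot(gdo_total_quantile > 0, gdo_total_quantile < 1,
            min_cdna_umis >= 0, min_genes >= 0)
  structure(list(gdo_total_quantile = gdo_total_quantile,
                 min_cdna_umis = as.integer(min_cdna_umis),
                 min_genes = as.integer(min_genes)),
            class = "qc_params")
}

#' Apply per-cell QC filters
#'
#' All three filters are evaluated independently on the full input and the
#' retained set is their intersection, so the result does not depend on
#' filter order. The GDO quantile is computed by linear interpolation
#' (R's default, type 7); cells strictly above it are removed.
#'
#' @param profiles Data frame with columns `cell_id`, `total_gdo_umis`,
#'   `total_cdna_umis`, `n_genes_detected`.
#' @param params A [qc_params()].
#' @return A list with `retained` (character vector of cell ids, input order)
#'   and `report` (cells removed per filter and the thresholds used).
#' @export
apply_qc_filters <- function(profiles, params = qc_params()) {
  if (nrow(profiles) == 0L) pt_stop("empty_input", "no cell profiles supplied")
  gdo_cut <- quantile(profiles$total_gdo_umis, params$gdo_total_quantile,
                      names = FALSE, type = 7)
  ok_gdo <- profiles$total_gdo_umis <= gdo_cut
  ok_cdna <- profiles$total_cdna_umis >= params$min_cdna_umis
  ok_genes <- profiles$n_genes_detected >= params$min_genes
  keep <- ok_gdo & ok_cdna & ok_genes
  list(retained = profiles$cell_id[keep],
       report = list(n_input = nrow(profiles),
                     n_retained = sum(keep),
                     n_removed_gdo = sum(!ok_gdo),
                     n_removed_cdna = sum(!ok_cdna),
                     n_removed_genes = sum(!ok_genes),
                     gdo_cutoff = gdo_cut,
                     params = unclass(params)))
}

#' Centered log-ratio normalization
#'
#' Per cell (row), across features: `log(x + pseudocount)` minus the mean of
#' those logs, so each cell's transformed values sum to zero. This is the
#' standard transform for hashtag and antibody tag counts before thresholding.
#'
#' @param counts Non-negative cells x features matrix.
#' @param pseudocount Added before the log (default 1).
#' @return Dense numeric matrix, same dimnames.
#' @export
clr_normalize <- function(counts, pseudocount = 1) {
  x <- log(as.matrix(counts) + pseudocount)
  x - rowMeans(x)
}

#' Classify cells as hashtag negative / singlet / doublet
#'
#' For each hashtag the CLR values across cells are split into a low
#' (background) and a high (stained) cluster by deterministic 1-D two-means
#' (centers initialized at the min and max, Lloyd iterations to convergence);
#' the positive threshold is the midpoint of the two final centers. A cell is
#' a singlet if exactly one hashtag is positive, a doublet if two or more
#' are, and negative otherwise. Droplet doublets carrying two different
#' hashtags are thereby separated from genuinely multi-guide single cells.
#'
#' @param clr Cells x HTO matrix of CLR-normalized counts
#'   (see [clr_normalize()]).
#' @return Data frame with columns `cell_id`, `status`
#'   (`"negative"`/`"singlet"`/`"doublet"`), `hashtag` (the called hashtag for
#'   singlets, `NA` otherwise) and `positive_set` (comma-joined positive
#'   hashtags).
#' @export
classify_hashtags <- function(clr) {
  if (nrow(clr) < 2L || ncol(clr) < 2L) {
    pt_stop("degenerate_distribution",
            "need at least 2 cells and 2 hashtags to classify")
  }
  clr <- as.matrix(clr)
  pos <- matrix(FALSE, nrow(clr), ncol(clr), dimnames = dimnames(clr))
  for (j in seq_len(ncol(clr))) {
    v <- clr[, j]
    if (max(v) - min(v) < .Machine$double.eps^0.5) {
      warning(sprintf("hashtag %s has constant CLR values; no positives called",
                      colnames(clr)[j]))
      next
    }
    pos[, j] <- v > two_means_threshold(v)
  }
  npos <- rowSums(pos)
  status <- ifelse(npos == 0L, "negative",
                   ifelse(npos == 1L, "singlet", "doublet"))
  hashtag <- rep(NA_character_, nrow(clr))
  sing <- which(npos == 1L)
  if (length(sing)) {
    hashtag[sing] <- colnames(clr)[apply(pos[sing, , drop = FALSE], 1L, which)]
  }
  positive_set <- apply(pos, 1L, function(p)
    paste(colnames(clr)[p], collapse = ","))
  data.frame(cell_id = rownames(clr), status = status, hashtag = hashtag,
             positive_set = positive_set, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Deterministic 1-D two-means: centers start at min and max, Lloyd updates
# until fixed point; returns the midpoint of the final centers.
two_means_threshold <- function(v, max_iter = 100L) {
  c_lo <- min(v); c_hi <- max(v)
  for (i in seq_len(max_iter)) {
    hi <- abs(v - c_hi) < abs(v - c_lo)
    new_lo <- mean(v[!hi]); new_hi <- mean(v[hi])
    if (isTRUE(all.equal(c(c_lo, c_hi), c(new_lo, new_hi)))) break
    c_lo <- new_lo; c_hi <- new_hi
  }
  (c_lo + c_hi) / 2
}
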