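#' Relative-count normalization of tag counts
#'
#' Each cell's counts are divided by the cell's total over the modality's
#' features and multiplied by a common scale factor, making the values
#' invariant to per-cell sequencing depth. Cells with zero total map to
#' zeros.
#'
#' @param counts Non-negative cells x features matrix.
#' @param scale_factor Positive scale factor (default 1); use the same factor
#'   for every modality entering a combined score.
#' @return Dense numeric matrix, same dimnames.
#' @export
rc_normalize <- function(counts, scale_factor = 1) {
  stopifnot(scale_factor > 0)
  m <- as.matrix(counts)
  totals <- rowSums(m)
  out <- m / ifelse(totals > 0, totals, 1) * scale_factor
  out[totals == 0, ] <- 0
  out
}

#' Per-cell normalized dominant-hashtag value (HTO-Max)
#'
#' Hashtag singlets are grouped by their called hashtag; within each group
#' the dominant hashtag's raw count is divided by the group's center (mean by
#' default), and the groups are recombined into one per-cell value. Dividing
#' within hashtag groups removes per-antibody staining-efficiency differences
#' while preserving the cell-to-cell signal, which tracks the abundance of
#' the hashtag's epitope (MHC-I/CD45) on the cell surface.
#'
#' @param hto_counts Cells x HTO raw count matrix.
#' @param calls Hashtag calls from [classify_hashtags()]; only rows with
#'   `status == "singlet"` are used.
#' @param center `"mean"` (default) or `"median"` group centering.
#' @return Named numeric vector of HTO-Max values, one per singlet cell.
#' @export
compute_hto_max <- function(hto_counts, calls, center = c("mean", "median")) {
  center <- match.arg(center)
  fun <- if (center == "mean") mean else median
  singlets <- calls[calls$status == "singlet", , drop = FALSE]
  if (nrow(singlets) == 0L) pt_stop("empty_group", "no hashtag singlets")
  m <- as.matrix(hto_counts)
  dom <- m[cbind(match(singlets$cell_id, rownames(m)),
                 match(singlets$hashtag, colnames(m)))]
  out <- numeric(nrow(singlets))
  for (h in unique(singlets$hashtag)) {
    idx <- which(singlets$hashtag == h)
    ctr <- fun(dom[idx])
    if (ctr <= 0) {
      warning(sprintf("hashtag group %s has non-positive center; values set to 0", h))
      out[idx] <- 0
    } else {
      out[idx] <- dom[idx] / ctr
    }
  }
  setNames(out, singlets$cell_id)
}

#' Combined per-cell protein score
#'
#' The score summarizes a cell's co-stimulatory surface phenotype:
#' `S = RC(CD86) + HTO-Max - RC(PD-L1)`, i.e. relative-count-normalized CD86
#' plus the normalized dominant-hashtag value (tracking MHC-I/CD45) minus
#' relative-count-normalized PD-L1. Higher scores mean more co-stimulation
#' and less co-inhibition.
#'
#' @param rc_adt Relative-count-normalized ADT matrix from [rc_normalize()],
#'   containing the `cd86` and `pdl1` columns.
#' @param hto_max Named HTO-Max vector from [compute_hto_max()]; cells absent
#'   from it are dropped.
#' @param cd86,pdl1 Column names of the stimulatory and inhibitory ADT
#'   features (defaults `"CD86"`, `"PD-L1"`).
#' @return Data frame with columns `cell_id`, `rc_cd86`, `rc_pdl1`,
#'   `hto_max`, `score`.
#' @export
protein_score <- function(rc_adt, hto_max, cd86 = "CD86", pdl1 = "PD-L1") {
  miss <- setdiff(c(cd86, pdl1), colnames(rc_adt))
  if (length(miss)) {
    pt_stop("missing_modality", "ADT matrix lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  cells <- intersect(names(hto_max), rownames(rc_adt))
  if (length(cells) == 0L) {
    pt_stop("missing_modality", "no cells shared between ADT and HTO-Max")
  }
  data.frame(cell_id = cells,
             rc_cd86 = unname(rc_adt[cells, cd86]),
             rc_pdl1 = unname(rc_adt[cells, pdl1]),
             hto_max = unname(hto_max[cells]),
             score = unname(rc_adt[cells, cd86] + hto_max[cells] -
                              rc_adt[cells, pdl1]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize and rank perturbation combinations by protein score
#'
#' Per perturbation label, the median score over its cells is taken and
#' expressed relative to the median of the non-targeting reference (so the
#' reference sits at exactly 0); labels are ranked in descending order of
#' relative score (rank 1 = strongest co-stimulatory shift). Ties break by
#' descending cell count, then label.
#'
#' @param scores Data frame with `cell_id` and `score`
#'   (from [protein_score()]).
#' @param labels Data frame with `cell_id` and `label`; cells present in both
#'   inputs are summarized.
#' @param reference_label Reference label (default `"NT"`).
#' @return Data frame with columns `label`, `n_cells`, `median_score`,
#'   `relative_score`, `rank`, sorted by rank.
#' @export
summarize_and_rank <- function(scores, labels, reference_label = "NT") {
  df <- merge(scores[, c("cell_id", "score")],
              labels[, c("cell_id", "label")], by = "cell_id")
  if (!reference_label %in% df$label) {
    pt_stop("missing_reference", "reference label '%s' has no scored cells",
            reference_label)
  }
  med <- tapply(df$score, df$label, median)
  out <- data.frame(label = names(med),
                    n_cells = as.integer(table(df$label)[names(med)]),
                    median_score = as.numeric(med),
                    stringsAsFactors = FALSE)
  out$relative_score <- out$median_score - med[[reference_label]]
  out <- out[order(-out$relative_score, -out$n_cells, out$label), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
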