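#' Guide-assignment parameters
#'
#' A gRNA is called in a cell only when it passes two thresholds jointly:
#' at least `min_umis` GDO UMIs, and at least `min_fraction` of the cell's
#' total GDO UMIs. Both are inclusive. Rare gene-level combinations (fewer
#' than `min_cells_per_combo` cells — mainly triplets and higher-order
#' combinations) are discarded from downstream summaries.
#'
#' @param min_umis Minimum UMIs per called guide (default 5).
#' @param min_fraction Minimum fraction of the cell's GDO UMIs (default 0.20).
#' @param min_cells_per_combo Minimum cells per retained combination
#'   (default 10).
#' @param collapse_nt Drop non-targeting guides from mixed guide sets; cells
#'   carrying only non-targeting guides are labelled `"NT"` (default TRUE).
#' @param collapse_same_gene Collapse two guides hitting the same gene to a
#'   single-gene label (default TRUE).
#' @return A list of class `guide_params`.
#' @export
guide_params <- function(min_umis = 5L, min_fraction = 0.20,
                         min_cells_per_combo = 10L, collapse_nt = TRUE,
                         collapse_same_gene = TRUE) {
  stopifnot(min_umis >= 1, min_fraction > 0, min_fraction <= 1,
            min_cells_per_combo >= 1)
  structure(list(min_umis = as.integer(min_umis),
                 min_fraction = min_fraction,
                 min_cells_per_combo = as.integer(min_cells_per_combo),
                 collapse_nt = isTRUE(collapse_nt),
                 collapse_same_gene = isTRUE(collapse_same_gene)),
            class = "guide_params")
}

#' Call guides per cell from GDO counts
#'
#' @param gdo_counts Cells x guides count matrix (dense or sparse) with
#'   dimnames, or a named numeric vector for a single cell.
#' @param params A [guide_params()].
#' @return Long data frame with one row per called (cell, guide):
#'   columns `cell_id`, `guide`, `umis`, `fraction`. Cells without any
#'   passing guide do not appear (no-call).
#' @export
assign_guides <- function(gdo_counts, params = guide_params()) {
  if (is.null(dim(gdo_counts))) {
    gdo_counts <- matrix(gdo_counts, nrow = 1L,
                         dimnames = list("cell", names(gdo_counts)))
  }
  m <- as.matrix(gdo_counts)
  if (any(m < 0)) pt_stop("invalid_input", "negative GDO counts")
  totals <- rowSums(m)
  frac <- m / ifelse(totals > 0, totals, 1)
  pass <- m >= params$min_umis & frac >= params$min_fraction
  idx <- which(pass, arr.ind = TRUE)
  out <- data.frame(cell_id = rownames(m)[idx[, 1L]],
                    guide = colnames(m)[idx[, 2L]],
                    umis = m[idx],
                    fraction = frac[idx],
                    stringsAsFactors = FALSE)
  out[order(out$cell_id, -out$umis, out$guide), , drop = FALSE]
}

#' Gene-level perturbation label for one guide set
#'
#' @param guides Character vector of called guide feature ids.
#' @param guide_to_gene Named character vector mapping guide ids to target
#'   genes (`"NT"` for non-targeting), e.g. from [guide_to_gene_map()].
#' @param params A [guide_params()] (controls NT and same-gene collapsing).
#' @return Single label string: sorted distinct gene symbols joined with
#'   `"+"`, or `"NT"` for non-targeting-only cells; `NA` for an empty set.
#' @export
label_perturbation <- function(guides, guide_to_gene,
                               params = guide_params()) {
  if (length(guides) == 0L) return(NA_character_)
  unknown <- setdiff(guides, names(guide_to_gene))
  if (length(unknown)) {
    pt_stop("unknown_guide", "guide(s) not in map: %s",
            paste(unknown, collapse = ", "))
  }
  genes <- unname(guide_to_gene[guides])
  if (params$collapse_same_gene) genes <- unique(genes)
  if (params$collapse_nt) {
    targeting <- setdiff(genes, "NT")
    genes <- if (length(targeting)) targeting else "NT"
  }
  paste(sort(unique(genes)), collapse = "+")
}

#' Label all cells from their guide calls
#'
#' @param calls Output of [assign_guides()].
#' @param guide_to_gene Named guide-to-gene map.
#' @param params A [guide_params()].
#' @return Data frame with columns `cell_id`, `label`, `n_guides`.
#' @export
label_cells <- function(calls, guide_to_gene, params = guide_params()) {
  if (nrow(calls) == 0L) {
    return(data.frame(cell_id = character(0), label = character(0),
                      n_guides = integer(0), stringsAsFactors = FALSE))
  }
  by_cell <- split(calls$guide, calls$cell_id)
  data.frame(cell_id = names(by_cell),
             label = vapply(by_cell, label_perturbation, "",
                            guide_to_gene = guide_to_gene, params = params),
             n_guides = lengths(by_cell),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Drop rare perturbation combinations
#'
#' @param labels Data frame with columns `cell_id`, `label`.
#' @param params A [guide_params()]; combinations with fewer than
#'   `min_cells_per_combo` cells are removed.
#' @return A list with `retained` (the surviving rows of `labels`) and
#'   `dropped` (data frame of dropped labels and their cell counts).
#' @export
filter_combinations <- function(labels, params = guide_params()) {
  n <- table(labels$label)
  keep_labels <- names(n)[n >= params$min_cells_per_combo]
  dropped <- data.frame(label = names(n)[n < params$min_cells_per_combo],
                        n_cells = as.integer(n[n < params$min_cells_per_combo]),
                        stringsAsFactors = FALSE)
  list(retained = labels[labels$label %in% keep_labels, , drop = FALSE],
       dropped = dropped[order(-dropped$n_cells, dropped$label), ,
                         drop = FALSE])
}
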