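#' Write a tag count matrix as a 10x-style MTX triple
#'
#' Writes `matrix.mtx` (features x cells, MatrixMarket), `barcodes.tsv`
#' (cell ids) and `features.tsv` (feature id, display name, modality) into
#' `dir`. The on-disk orientation is features x cells per 10x convention;
#' the in-memory contract everywhere in this package is cells x features.
#'
#' @param counts Cells x features matrix (dense or sparse) with dimnames.
#' @param dir Output directory (created if needed).
#' @param modality Modality label stored in `features.tsv` (single string).
#' @param display_names Optional display names, defaulting to the feature ids.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, dir, modality = "ADT",
                               display_names = NULL) {
  if (is.null(rownames(counts)) && nrow(counts) > 0L ||
      is.null(colnames(counts)) && ncol(counts) > 0L) {
    pt_stop("format_error", "count matrix must carry cell and feature names")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- methods::as(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
                    "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts) %||% character(0),
             file.path(dir, "barcodes.tsv"))
  feats <- data.frame(
    feature_id = colnames(counts) %||% character(0),
    display_name = display_names %||% colnames(counts) %||% character(0),
    modality = if (ncol(counts)) modality else character(0))
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style MTX triple into a cells x features matrix
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` as written by [write_count_matrix()].
#' @return Sparse integer cells x features matrix with cell/feature dimnames;
#'   the modality read from `features.tsv` is attached as attribute
#'   `"modality"`.
#' @export
read_count_matrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  bfile <- file.path(dir, "barcodes.tsv")
  ffile <- file.path(dir, "features.tsv")
  for (f in c(mtx, bfile, ffile)) {
    if (!file.exists(f)) pt_stop("format_error", "missing file: %s", f)
  }
  header <- readLines(mtx, n = 1L)
  if (!startsWith(header, "%%MatrixMarket")) {
    pt_stop("format_error", "%s lacks a MatrixMarket header", mtx)
  }
  m <- Matrix::readMM(mtx)
  barcodes <- readLines(bfile)
  feats <- if (file.size(ffile) > 0L) {
    utils::read.delim(ffile, header = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(V1 = character(0), V2 = character(0), V3 = character(0))
  }
  if (nrow(m) != nrow(feats) || ncol(m) != length(barcodes)) {
    pt_stop("format_error",
            "matrix is %d x %d but features/barcodes have %d/%d entries",
            nrow(m), ncol(m), nrow(feats), length(barcodes))
  }
  out <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(out) <- list(barcodes, feats[[1L]])
  attr(out, "modality") <- if (nrow(feats)) feats[[3L]][1L] else NA_character_
  out
}
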