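#' Load a feature reference from CSV
#'
#' The feature reference describes every oligo tag the experiment can produce:
#' antibody-derived tags (ADT) for surface proteins, hashtag oligos (HTO) for
#' sample hashing, and guide-derived oligos (GDO) identifying gRNAs. The file
#' must have a header with columns `feature_id`, `display_name`, `modality`,
#' `barcode_seq`, `target_label`. The target label `"NT"` is reserved for
#' non-targeting control guides.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of class `feature_reference` with one row per
#'   feature, validated so that feature ids and barcode sequences are unique
#'   and all barcodes have a common length.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(feature_id = c("CD86", "HTO1"),
#'                      display_name = c("CD86", "hashtag-1"),
#'                      modality = c("ADT", "HTO"),
#'                      barcode_seq = c("ACGTACGTACGT", "TTGCATGCAAGG"),
#'                      target_label = c("CD86", "HTO1")),
#'           tf, row.names = FALSE)
#' ref <- load_feature_reference(tf)
#' table(ref$modality)
#' @export
load_feature_reference <- function(path) {
  if (!file.exists(path)) pt_stop("file_not_found", "no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  feature_reference(df)
}

#' Construct a feature reference from a data frame
#'
#' @param df Data frame with columns `feature_id`, `display_name`, `modality`,
#'   `barcode_seq`, `target_label`.
#' @return A validated `feature_reference` data frame.
#' @export
feature_reference <- function(df) {
  need <- c("feature_id", "display_name", "modality", "barcode_seq",
            "target_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    pt_stop("malformed_row", "feature reference missing column(s): %s",
            paste(miss, collapse = ", "))
  }
  df <- df[, need]
  if (nrow(df)) {
    if (anyNA(df) || any(df == "")) {
      pt_stop("malformed_row", "feature reference has empty fields")
    }
    if (anyDuplicated(df$feature_id)) {
      pt_stop("duplicate_feature_id", "duplicated feature_id: %s",
              paste(unique(df$feature_id[duplicated(df$feature_id)]),
                    collapse = ", "))
    }
    if (anyDuplicated(df$barcode_seq)) {
      pt_stop("duplicate_barcode", "duplicated barcode_seq: %s",
              paste(unique(df$barcode_seq[duplicated(df$barcode_seq)]),
                    collapse = ", "))
    }
    if (length(unique(nchar(df$barcode_seq))) > 1L) {
      pt_stop("malformed_row", "barcode sequences have differing lengths")
    }
    bad <- !df$modality %in% c("ADT", "HTO", "GDO")
    if (any(bad)) {
      pt_stop("malformed_row", "unknown modality: %s",
              paste(unique(df$modality[bad]), collapse = ", "))
    }
  }
  class(df) <- c("feature_reference", "data.frame")
  df
}

#' Guide-to-gene map from a feature reference
#'
#' @param ref A `feature_reference`.
#' @return Named character vector mapping GDO feature ids to their target
#'   gene symbols (`"NT"` for non-targeting guides).
#' @export
guide_to_gene_map <- function(ref) {
  g <- ref[ref$modality == "GDO", ]
  setNames(g$target_label, g$feature_id)
}
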