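#' Counting parameters
#'
#' Parameters for [count_tags()]. A (cell barcode, UMI) pair is kept only when
#' its majority feature holds strictly more than `purity_threshold` of the
#' pair's matched reads; this removes UMIs claimed by several features
#' (PCR chimeras, barcode collisions). GDO UMIs additionally need
#' `gdo_min_reads_per_umi` supporting reads, guarding against ambient guide
#' molecules that typically carry very few reads.
#'
#' @param purity_threshold Fraction in (0.5, 1]; default 0.75. Values above
#'   0.5 guarantee at most one feature can pass per UMI.
#' @param gdo_min_reads_per_umi Minimum total reads for a GDO UMI (default 5).
#'   ADT/HTO UMIs have no read floor.
#' @param max_hamming Maximum Hamming distance for tag and cell-barcode
#'   correction (default 1); corrections must be unique or the read is
#'   unmatched.
#' @param cbc_whitelist Optional character vector of allowed cell barcodes.
#' @return A list of class `counting_params`.
#' @export
counting_params <- function(purity_threshold = 0.75,
                            gdo_min_reads_per_umi = 5L,
                            max_hamming = 1L,
                            cbc_whitelist = NULL) {
  stopifnot(purity_threshold > 0.5, purity_threshold <= 1,
            gdo_min_reads_per_umi >= 1, max_hamming >= 0)
  structure(list(purity_threshold = purity_threshold,
                 gdo_min_reads_per_umi = as.integer(gdo_min_reads_per_umi),
                 max_hamming = as.integer(max_hamming),
                 cbc_whitelist = cbc_whitelist),
            class = "counting_params")
}

#' Read tag reads from a TSV file
#'
#' Expected columns: `cbc`, `umi`, `tag_seq` and optionally `n_reads`
#' (defaults to 1 per row when absent).
#'
#' @param path TSV path.
#' @return A data.frame with columns `cbc`, `umi`, `tag_seq`, `n_reads`.
#' @export
read_tag_reads_tsv <- function(path) {
  if (!file.exists(path)) pt_stop("file_not_found", "no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cbc", "umi", "tag_seq")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    pt_stop("malformed_row", "tag read TSV missing column(s): %s",
            paste(miss, collapse = ", "))
  }
  if (is.null(df$n_reads)) df$n_reads <- 1L
  df[, c("cbc", "umi", "tag_seq", "n_reads")]
}

#' Read tag reads from a FASTQ pair
#'
#' R1 carries the cell barcode followed by the UMI; R2 carries the tag
#' sequence (already quality-filtered upstream; it is trimmed here to the
#' requested length).
#'
#' @param r1,r2 Paths to the R1 and R2 FASTQ files (uncompressed or gzip).
#' @param cbc_len,umi_len Cell-barcode and UMI lengths within R1.
#' @param tag_len Length to which R2 is trimmed; defaults to the full read.
#' @return A data.frame with columns `cbc`, `umi`, `tag_seq`, `n_reads` (1).
#' @export
read_tag_reads_fastq <- function(r1, r2, cbc_len = 16L, umi_len = 12L,
                                 tag_len = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    pt_stop("missing_dependency", "Biostrings is required for FASTQ input")
  }
  s1 <- as.character(Biostrings::readDNAStringSet(r1, format = "fastq"))
  s2 <- as.character(Biostrings::readDNAStringSet(r2, format = "fastq"))
  if (length(s1) != length(s2)) {
    pt_stop("malformed_row", "R1 and R2 have different read counts")
  }
  if (!is.null(tag_len)) s2 <- substr(s2, 1L, tag_len)
  data.frame(cbc = substr(s1, 1L, cbc_len),
             umi = substr(s1, cbc_len + 1L, cbc_len + umi_len),
             tag_seq = unname(s2),
             n_reads = 1L,
             stringsAsFactors = FALSE)
}

#' Count tag UMIs per cell and feature
#'
#' Groups reads by (cell barcode, UMI), resolves tag sequences against the
#' feature reference (exact match, then unique Hamming-distance correction),
#' applies the purity rule and the GDO read floor, and tallies one UMI per
#' retained (cell, feature) pair into one count matrix per modality.
#'
#' A (CBC, UMI) group is retained only if its most-supported feature holds
#' strictly more than `purity_threshold` of the group's matched reads;
#' groups whose winning feature is a GDO also need at least
#' `gdo_min_reads_per_umi` total reads. Groups with no matchable read are
#' tallied as unmatched; groups whose cell barcode cannot be (uniquely)
#' corrected onto the whitelist are tallied separately.
#'
#' @param reads Data frame with columns `cbc`, `umi`, `tag_seq` and
#'   optionally `n_reads` (see [read_tag_reads_tsv()]).
#' @param ref A [feature_reference()].
#' @param params A [counting_params()].
#' @return A list with elements
#'   \describe{
#'     \item{matrices}{named list of sparse cells x features count matrices,
#'       one per modality present in `ref`; all share the same row (cell)
#'       ordering.}
#'     \item{discarded_umi_count}{number of (CBC, UMI) groups dropped by the
#'       purity rule or the GDO read floor.}
#'     \item{log}{tallies: total reads, distinct (CBC, UMI) groups, retained,
#'       discarded by purity, discarded by the GDO floor, unmatched groups,
#'       off-whitelist groups, and the parameter values used.}
#'   }
#' @export
count_tags <- function(reads, ref, params = counting_params()) {
  stopifnot(inherits(ref, "feature_reference"))
  if (is.null(reads$n_reads)) reads$n_reads <- 1L
  dt <- data.table::as.data.table(reads[, c("cbc", "umi", "tag_seq", "n_reads")])

  tag_len <- if (nrow(ref)) nchar(ref$barcode_seq[1L]) else 0L
  utags <- unique(dt$tag_seq)
  fidx <- match_barcodes(substr(utags, 1L, tag_len), ref$barcode_seq,
                         params$max_hamming)
  dt[, feature_id := ref$feature_id[fidx[match(tag_seq, utags)]]]

  # CBC whitelist correction, applied to the observed barcodes once.
  if (!is.null(params$cbc_whitelist)) {
    ucbc <- unique(dt$cbc)
    cidx <- match_barcodes(ucbc, params$cbc_whitelist, params$max_hamming)
    dt[, cbc_ok := params$cbc_whitelist[cidx[match(cbc, ucbc)]]]
  } else {
    dt[, cbc_ok := cbc]
  }

  n_groups_total <- data.table::uniqueN(dt, by = c("cbc", "umi"))

  # Groups with no matchable read at all.
  grp_any <- dt[, .(any_match = any(!is.na(feature_id)),
                    cbc_ok = cbc_ok[1L]), by = .(cbc, umi)]
  n_unmatched <- sum(!grp_any$any_match)
  n_off_whitelist <- sum(grp_any$any_match & is.na(grp_any$cbc_ok))

  m <- dt[!is.na(feature_id) & !is.na(cbc_ok)]
  retained <- data.table::data.table(cell = character(0),
                                     feature_id = character(0))
  n_purity_fail <- 0L
  n_gdo_floor_fail <- 0L
  if (nrow(m)) {
    per_feat <- m[, .(reads = sum(n_reads)), by = .(cbc, umi, cbc_ok, feature_id)]
    grp <- per_feat[order(-reads),
                    .(top_feature = feature_id[1L],
                      top_reads = reads[1L],
                      total_reads = sum(reads),
                      cell = cbc_ok[1L]),
                    by = .(cbc, umi)]
    mod <- setNames(ref$modality, ref$feature_id)
    grp[, pure := top_reads / total_reads > params$purity_threshold]
    grp[, floor_ok := mod[top_feature] != "GDO" |
                      total_reads >= params$gdo_min_reads_per_umi]
    n_purity_fail <- sum(!grp$pure)
    n_gdo_floor_fail <- sum(grp$pure & !grp$floor_ok)
    retained <- grp[pure & floor_ok, .(cell, feature_id = top_feature)]
  }

  cells <- sort(unique(retained$cell))
  matrices <- list()
  for (modality in unique(ref$modality)) {
    feats <- ref$feature_id[ref$modality == modality]
    sub <- retained[feature_id %in% feats]
    mat <- Matrix::sparseMatrix(
      i = match(sub$cell, cells),
      j = match(sub$feature_id, feats),
      x = rep(1L, nrow(sub)),
      dims = c(length(cells), length(feats)),
      dimnames = list(cells, feats))
    matrices[[modality]] <- methods::as(mat, "CsparseMatrix")
  }

  list(matrices = matrices,
       discarded_umi_count = n_purity_fail + n_gdo_floor_fail,
       log = list(n_reads = sum(reads$n_reads),
                  n_umi_groups = n_groups_total,
                  n_retained = nrow(retained),
                  n_discarded_purity = n_purity_fail,
                  n_discarded_gdo_floor = n_gdo_floor_fail,
                  n_unmatched_groups = n_unmatched,
                  n_off_whitelist_groups = n_off_whitelist,
                  params = params[c("purity_threshold", "gdo_min_reads_per_umi",
                                    "max_hamming")]))
}
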