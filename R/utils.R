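#' @importFrom stats median phyper pchisq pnorm p.adjust quantile rnbinom
#'   rpois runif qpois sd setNames kmeans wilcox.test rlnorm
#' @importFrom utils read.csv write.csv
#' @import data.table
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  "feature_id", "cbc", "cbc_ok", "umi", "tag_seq", "n_reads", "reads",
  "top_feature", "top_reads", "total_reads", "pure", "floor_ok", "cell",
  "modality", "other", "any_match"))

# Classed conditions so callers can distinguish failure modes programmatically.
pt_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "perturbtag_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

# Pairwise Hamming distances between equal-length strings. Small inputs only
# (observed unique tags x reference barcodes), so a dense char-matrix compare
# is fine and keeps the semantics exact (substitutions only).
hamming_dist <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    return(matrix(integer(0), nrow = length(x), ncol = length(y)))
  }
  stopifnot(all(nchar(x) == nchar(y[1L])))
  xm <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  ym <- do.call(rbind, strsplit(y, "", fixed = TRUE))
  d <- matrix(0L, nrow = length(x), ncol = length(y))
  for (j in seq_along(y)) {
    d[, j] <- as.integer(colSums(t(xm) != ym[j, ]))
  }
  d
}

# Resolve query sequences against a reference set: exact match first, then a
# unique match at Hamming distance <= max_hamming; ambiguous or distant
# queries resolve to NA.
match_barcodes <- function(queries, reference, max_hamming = 1L) {
  idx <- match(queries, reference)
  if (max_hamming > 0L && anyNA(idx)) {
    todo <- which(is.na(idx))
    ulen <- nchar(reference[1L])
    cand <- todo[nchar(queries[todo]) == ulen]
    if (length(cand)) {
      d <- hamming_dist(queries[cand], reference)
      ok <- d <= max_hamming
      nhit <- rowSums(ok)
      hit1 <- which(nhit == 1L)
      if (length(hit1)) {
        idx[cand[hit1]] <- apply(ok[hit1, , drop = FALSE], 1L, which)
      }
    }
  }
  idx
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

# n distinct random DNA strings (regenerates collisions).
random_dna_unique <- function(n, len) {
  out <- random_dna(n, len)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- random_dna(length(dup), len)
  }
  out
}
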