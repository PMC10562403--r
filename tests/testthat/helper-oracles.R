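# Independent oracles and fixture builders. Everything here is written as a
# literal restatement of the rules, deliberately avoiding the package's own
# code paths (no data.table grouping, no vectorized shortcuts).

small_feature_ref <- function() {
  feature_reference(data.frame(
    feature_id = c("CD86", "PD-L1", "HTO1", "HTO2", "HTO3",
                   "gA_1", "gA_2", "gB_1", "gNT_1"),
    display_name = c("CD86", "PD-L1", "hash1", "hash2", "hash3",
                     "gA_1", "gA_2", "gB_1", "gNT_1"),
    modality = c("ADT", "ADT", "HTO", "HTO", "HTO",
                 "GDO", "GDO", "GDO", "GDO"),
    barcode_seq = c("AAAACCCC", "CCCCAAAA", "GGGGTTTT", "TTTTGGGG",
                    "ACACACAC", "GTGTGTGT", "AATTCCGG", "CCGGAATT",
                    "AGAGAGAG"),
    target_label = c("CD86", "PD-L1", "HTO1", "HTO2", "HTO3",
                     "GeneA", "GeneA", "GeneB", "NT"),
    stringsAsFactors = FALSE))
}

hamming1_oracle <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Literal counter: resolve each read's tag (exact, else unique Hamming<=1),
# group reads by (cbc, umi) with split(), apply the purity and GDO-floor
# rules one group at a time, tally.
brute_force_count <- function(reads, ref, params = counting_params()) {
  if (is.null(reads$n_reads)) reads$n_reads <- 1L
  tag_len <- nchar(ref$barcode_seq[1])
  resolve <- function(seqs, pool) {
    u <- unique(seqs)
    idx <- vapply(u, function(s) {
      hit <- which(pool == s)
      if (length(hit) != 1) {
        d <- vapply(pool, hamming1_oracle, numeric(1), a = s)
        hit <- which(d <= params$max_hamming)
      }
      if (length(hit) == 1) hit else NA_integer_
    }, integer(1), USE.NAMES = FALSE)
    idx[match(seqs, u)]
  }
  reads$feature <- ref$feature_id[resolve(substr(reads$tag_seq, 1, tag_len),
                                          ref$barcode_seq)]
  if (!is.null(params$cbc_whitelist)) {
    reads$cell <- params$cbc_whitelist[resolve(reads$cbc, params$cbc_whitelist)]
  } else {
    reads$cell <- reads$cbc
  }
  modality_of <- setNames(ref$modality, ref$feature_id)
  groups <- split(reads, paste(reads$cbc, reads$umi))
  tally <- list()
  discarded <- 0L; unmatched <- 0L; off_wl <- 0L
  for (g in groups) {
    g2 <- g[!is.na(g$feature), , drop = FALSE]
    if (nrow(g2) == 0) { unmatched <- unmatched + 1L; next }
    if (is.na(g2$cell[1])) { off_wl <- off_wl + 1L; next }
    per <- tapply(g2$n_reads, g2$feature, sum)
    total <- sum(per)
    top <- names(per)[order(-per, names(per))][1]
    ok <- per[[top]] / total > params$purity_threshold
    if (ok && modality_of[[top]] == "GDO" &&
        total < params$gdo_min_reads_per_umi) ok <- FALSE
    if (!ok) { discarded <- discarded + 1L; next }
    key <- paste(g2$cell[1], top, sep = "\r")
    tally[[key]] <- (tally[[key]] %||% 0L) + 1L
  }
  cells <- if (length(tally)) {
    sort(unique(vapply(strsplit(names(tally), "\r"), `[`, "", 1)))
  } else {
    character(0)
  }
  mats <- list()
  for (modality in unique(ref$modality)) {
    feats <- ref$feature_id[ref$modality == modality]
    m <- matrix(0L, length(cells), length(feats),
                dimnames = list(cells, feats))
    for (key in names(tally)) {
      kv <- strsplit(key, "\r")[[1]]
      if (kv[2] %in% feats) m[kv[1], kv[2]] <- tally[[key]]
    }
    mats[[modality]] <- m
  }
  list(matrices = mats, discarded_umi_count = discarded,
       unmatched = unmatched, off_whitelist = off_wl,
       n_groups = length(groups))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Randomized counting instance with deliberate collisions: tiny barcode and
# UMI alphabets, occasional single-base tag errors and junk tags.
random_counting_instance <- function(seed, n_reads_max = 1e4) {
  set.seed(seed)
  ref <- small_feature_ref()
  n <- sample.int(n_reads_max, 1)
  cbcs <- paste0("CB", sprintf("%02d", 1:12))
  umis <- paste0("U", sprintf("%02d", 1:25))
  tag <- sample(ref$barcode_seq, n, replace = TRUE)
  mutate <- runif(n) < 0.15
  pos <- sample.int(8, n, replace = TRUE)
  substr(tag[mutate], pos[mutate], pos[mutate]) <-
    sample(c("A", "C", "G", "T"), sum(mutate), replace = TRUE)
  junk <- runif(n) < 0.05
  tag[junk] <- vapply(seq_len(sum(junk)), function(i)
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = ""),
    "")
  data.frame(cbc = sample(cbcs, n, replace = TRUE),
             umi = sample(umis, n, replace = TRUE),
             tag_seq = tag,
             n_reads = sample.int(12, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

expect_same_counts <- function(res, oracle) {
  for (modality in names(oracle$matrices)) {
    a <- as.matrix(res$matrices[[modality]])
    b <- oracle$matrices[[modality]]
    expect_identical(dim(a), dim(b))
    if (nrow(b)) {
      expect_identical(rownames(a), rownames(b))
      expect_true(all(a == b))
    }
  }
  expect_identical(res$discarded_umi_count, oracle$discarded_umi_count)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(nA+nB, nA) group labelings of the pooled sample.
exact_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  nA <- length(a)
  w_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  sets <- utils::combn(length(pooled), nA)
  w_all <- apply(sets, 2, function(ix) sum(r[ix]) - nA * (nA + 1) / 2)
  mu <- nA * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# Literal rank/U signature score.
brute_signature_score <- function(x, sig, r_max = 1500) {
  r <- rank(-x, ties.method = "average")
  r[r > r_max] <- r_max + 1
  n <- length(sig)
  u <- sum(r[sig]) - n * (n + 1) / 2
  min(max(1 - u / (n * r_max), 0), 1)
}

# Brute-force upper-tail overlap probability by enumerating every n-subset
# of the N-element universe against a fixed K-element list.
brute_overlap_p <- function(N, K, n, x) {
  sets <- utils::combn(N, n)
  mean(colSums(sets <= K) >= x)
}

# Small simulation shared across test files (kept small for speed).
tiny_sim <- function(seed = 1, ...) {
  simulate_dataset(sim_config(n_cells = 300L, ...), seed = seed)
}
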