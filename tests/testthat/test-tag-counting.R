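ref <- small_feature_ref()

read_row <- function(cbc, umi, feature, n) {
  data.frame(cbc = cbc, umi = umi,
             tag_seq = ref$barcode_seq[ref$feature_id == feature],
             n_reads = n, stringsAsFactors = FALSE)
}

test_that("purity rule keeps dominant-feature UMIs and drops split UMIs", {
  reads <- rbind(read_row("c1", "u1", "CD86", 9), read_row("c1", "u1", "PD-L1", 1),
                 read_row("c1", "u2", "CD86", 6), read_row("c1", "u2", "PD-L1", 4))
  res <- count_tags(reads, ref, counting_params(purity_threshold = 0.75))
  expect_equal(as.numeric(res$matrices$ADT["c1", "CD86"]), 1)
  expect_equal(res$discarded_umi_count, 1L)  # the 6:4 UMI
  expect_equal(res$log$n_retained, 1L)
})

test_that("the read floor applies to GDO UMIs only", {
  reads <- rbind(read_row("c2", "u3", "gA_1", 4),   # GDO below floor
                 read_row("c2", "u4", "CD86", 1),   # single-read ADT retained
                 read_row("c2", "u5", "gA_1", 5))   # GDO at floor retained
  res <- count_tags(reads, ref)
  expect_equal(as.numeric(res$matrices$GDO["c2", "gA_1"]), 1)
  expect_equal(as.numeric(res$matrices$ADT["c2", "CD86"]), 1)
  expect_equal(res$discarded_umi_count, 1L)
  expect_equal(res$log$n_discarded_gdo_floor, 1L)
})

test_that("tags are corrected at Hamming distance 1; unmatchable tags are logged", {
  mut <- ref$barcode_seq[ref$feature_id == "CD86"]
  substr(mut, 3, 3) <- "T"  # AAAACCCC -> AATACCCC, unique hit
  reads <- data.frame(cbc = c("c1", "c1"), umi = c("u1", "u2"),
                      tag_seq = c(mut, "GGGGGGGG"), n_reads = c(3L, 3L))
  res <- count_tags(reads, ref)
  expect_equal(as.numeric(res$matrices$ADT["c1", "CD86"]), 1)
  expect_equal(res$log$n_unmatched_groups, 1L)
  # with correction disabled the mutated tag is unmatched too
  res0 <- count_tags(reads, ref, counting_params(max_hamming = 0))
  expect_equal(res0$log$n_unmatched_groups, 2L)
})

test_that("cell barcodes are corrected onto the whitelist", {
  reads <- rbind(read_row("AAAA", "u1", "CD86", 3),
                 read_row("AAAT", "u2", "CD86", 3),  # 1 mismatch from AAAA
                 read_row("TTTT", "u3", "CD86", 3))  # off-whitelist
  res <- count_tags(reads, ref,
                    counting_params(cbc_whitelist = c("AAAA", "CCCC")))
  expect_equal(rownames(res$matrices$ADT), "AAAA")
  expect_equal(as.numeric(res$matrices$ADT["AAAA", "CD86"]), 2)
  expect_equal(res$log$n_off_whitelist_groups, 1L)
})

test_that("count_tags matches the literal brute-force counter on random instances", {
  for (seed in 1:25) {
    reads <- random_counting_instance(seed, n_reads_max = 2000)
    expect_same_counts(count_tags(reads, ref), brute_force_count(reads, ref))
  }
})

test_that("raising purity or the GDO floor never increases any count", {
  reads <- random_counting_instance(42, n_reads_max = 3000)
  base <- count_tags(reads, ref, counting_params(0.6, 2))
  stricter <- list(counting_params(0.9, 2), counting_params(0.6, 8),
                   counting_params(0.9, 8))
  for (p in stricter) {
    res <- count_tags(reads, ref, p)
    for (modality in names(base$matrices)) {
      a <- as.matrix(base$matrices[[modality]])
      b <- as.matrix(res$matrices[[modality]])
      shared <- intersect(rownames(a), rownames(b))
      expect_true(all(b[shared, ] <= a[shared, ]))
      lost <- setdiff(rownames(b), rownames(a))
      expect_length(lost, 0)
    }
  }
})

test_that("retained + discarded + unmatched + off-whitelist groups conserve the UMI total", {
  for (seed in c(3, 17)) {
    reads <- random_counting_instance(seed, n_reads_max = 2000)
    res <- count_tags(reads, ref,
                      counting_params(cbc_whitelist = paste0(
                        "CB", sprintf("%02d", 1:8))))
    with(res$log, expect_equal(
      n_retained + n_discarded_purity + n_discarded_gdo_floor +
        n_unmatched_groups + n_off_whitelist_groups,
      n_umi_groups))
  }
})

test_that("noise-free simulated reads reproduce the generator's UMI matrices exactly", {
  ds <- simulate_dataset(sim_config(n_cells = 40L, chimera_rate = 0),
                         seed = 5)
  reads <- simulate_tag_reads(ds, seed = 5)
  res <- count_tags(reads, ds$feature_ref)
  for (modality in c("adt", "hto", "gdo")) {
    truth <- as.matrix(ds[[modality]])
    got <- as.matrix(res$matrices[[toupper(modality)]])
    rows <- rownames(truth)[rowSums(truth) > 0]
    expect_true(all(rows %in% rownames(got)))
    expect_equal(unname(got[rows, colnames(truth)]), unname(truth[rows, ]),
                 ignore_attr = TRUE)
    expect_equal(sum(got), sum(truth))
  }
})

test_that("fixed 4-read GDO UMIs are all removed by the read floor", {
  ds <- simulate_dataset(
    sim_config(n_cells = 30L, chimera_rate = 0,
               reads_per_umi = list(ADT = c(1, 2), HTO = c(1, 2),
                                    GDO = c(4, 0))),
    seed = 9)
  res <- count_tags(simulate_tag_reads(ds, seed = 9), ds$feature_ref)
  expect_equal(sum(res$matrices$GDO), 0)
  expect_equal(res$log$n_discarded_gdo_floor, sum(ds$gdo))
})

test_that("balanced chimeric UMIs are discarded by the purity rule", {
  ds <- simulate_dataset(
    sim_config(n_cells = 20L, chimera_rate = 1, chimera_frac = 0.5),
    seed = 3)
  res <- count_tags(simulate_tag_reads(ds, seed = 3), ds$feature_ref)
  # every UMI carries two features at 50/50, so nothing clears purity 0.75
  expect_equal(res$log$n_retained, 0L)
})
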