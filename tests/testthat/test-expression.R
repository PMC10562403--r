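test_that("log-normalization hits the stated arithmetic and inverts to depth", {
  m <- rbind(c1 = c(g1 = 10, g2 = 9990),
             c2 = c(g1 = 0, g2 = 50),
             c3 = c(g1 = 0, g2 = 0))
  y <- normalize_expression(m)
  expect_equal(y["c1", "g1"], log(11))  # total 1e4, count 10
  expect_equal(y["c2", "g1"], 0)
  expect_equal(y["c3", ], c(g1 = 0, g2 = 0))
  nonzero <- rowSums(m) > 0
  expect_equal(unname(rowSums(expm1(y[nonzero, ]))), c(1e4, 1e4),
               tolerance = 1e-6)
})

test_that("signature scores hit their extremes at top-ranked and beyond-ceiling genes", {
  set.seed(2)
  x <- matrix(sample(1:2000), nrow = 1,
              dimnames = list("c1", paste0("g", 1:2000)))
  top <- colnames(x)[order(-x[1, ])][1:10]
  expect_equal(unname(rank_signature_score(x, top)), 1)
  bottom <- colnames(x)[order(x[1, ])][1]  # rank 2000 > r_max
  expect_equal(unname(rank_signature_score(x, bottom)), 0)
  expect_error(rank_signature_score(x, character(0)),
               class = "empty_signature")
})

test_that("signature scores equal the brute-force rank/U computation", {
  set.seed(14)
  m <- matrix(rnbinom(50 * 2000, mu = 5, size = 1), nrow = 50,
              dimnames = list(paste0("c", 1:50), paste0("g", 1:2000)))
  for (i in 1:40) {
    sig <- sample(colnames(m), sample(3:25, 1))
    cell <- sample(rownames(m), 1)
    expect_equal(unname(rank_signature_score(m[cell, , drop = FALSE], sig)),
                 brute_signature_score(m[cell, ], sig),
                 tolerance = 1e-12)
  }
})

test_that("signature scores are invariant under monotone count transforms", {
  set.seed(6)
  m <- matrix(rnbinom(10 * 500, mu = 8, size = 2), nrow = 10,
              dimnames = list(paste0("c", 1:10), paste0("g", 1:500)))
  sig <- sample(colnames(m), 12)
  expect_equal(rank_signature_score(m, sig, r_max = 400),
               rank_signature_score(log1p(m) * 7, sig, r_max = 400))
})

test_that("cells are assigned to the state whose program they express", {
  genes <- c(paste0("a", 1:5), paste0("b", 1:5), "filler")
  m <- rbind(cellA = c(rep(50, 5), rep(0, 5), 1),
             cellB = c(rep(0, 5), rep(50, 5), 1),
             tie = c(rep(25, 5), rep(25, 5), 1))
  colnames(m) <- genes
  res <- assign_cell_state(m, list(A = paste0("a", 1:5),
                                   B = paste0("b", 1:5)), r_max = 11)
  expect_equal(unname(res$state[c("cellA", "cellB")]), c("A", "B"))
  expect_true(is.na(res$state[["tie"]]))
  expect_error(assign_cell_state(m, list(A = "a1")), class = "invalid_input")
})

test_that("state assignment recovers planted programs on simulated cells", {
  ds <- tiny_sim(seed = 19)
  tr <- ds$truth$droplets
  singlet_ids <- tr$droplet_id[!tr$is_doublet]
  res <- assign_cell_state(as.matrix(ds$expr[singlet_ids, ]),
                           ds$config$state_programs)
  truth_state <- tr$state[match(singlet_ids, tr$droplet_id)]
  expect_gte(mean(res$state == truth_state, na.rm = TRUE), 0.9)
})

test_that("wilcoxon DE gives p = 1 on duplicated groups and exact small-sample p-values", {
  set.seed(23)
  counts <- matrix(rnbinom(8 * 30, mu = 20, size = 5), nrow = 8,
                   dimnames = list(paste0("c", 1:8), paste0("g", 1:30)))
  same <- wilcoxon_de(rbind(counts, counts)[c(1:8, 9:16), ],
                      paste0("c", 1:8), paste0("c", 1:8))
  # identical groups: every gene is a perfect tie
  expect_true(all(same$p == 1))
  expect_true(all(same$lfc == 0))

  # exact enumeration oracle, no ties
  cn <- matrix(c(sample(seq(1, 1000, by = 7), 8 * 5)), nrow = 8,
               dimnames = list(paste0("c", 1:8), paste0("g", 1:5)))
  de <- wilcoxon_de(cn, paste0("c", 1:4), paste0("c", 5:8))
  for (j in 1:5) {
    norm <- normalize_expression(cn)
    expect_equal(de$p[j],
                 exact_wilcox_p(norm[1:4, j], norm[5:8, j]),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_de(cn, paste0("c", 1:2), paste0("c", 5:8)),
               class = "group_too_small")
})

test_that("wilcoxon DE is label-swap symmetric and BH keeps q >= p", {
  set.seed(5)
  counts <- matrix(rnbinom(12 * 40, mu = 15, size = 3), nrow = 12,
                   dimnames = list(paste0("c", 1:12), paste0("g", 1:40)))
  a <- paste0("c", 1:6); b <- paste0("c", 7:12)
  ab <- wilcoxon_de(counts, a, b)
  ba <- wilcoxon_de(counts, b, a)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$lfc, -ba$lfc)
  expect_true(all(ab$q >= ab$p - 1e-12))
  ord <- order(ab$p)
  expect_true(all(diff(ab$q[ord]) >= -1e-12))  # BH monotone in p order
})

test_that("fold-change matrices are 1 for the reference and recover planted effects", {
  set.seed(44)
  n <- 200
  labels <- data.frame(cell_id = paste0("c", 1:(2 * n)),
                       label = rep(c("NT", "KO"), each = n))
  mu <- c(gUp = 50, gFlat = 50, gAbsent = 0)
  counts <- t(vapply(seq_len(2 * n), function(i) {
    m <- mu
    if (i > n) m["gUp"] <- m["gUp"] * 2  # planted 2x in KO cells
    rnbinom(3, mu = m, size = 50)
  }, numeric(3)))
  dimnames(counts) <- list(labels$cell_id, names(mu))
  counts <- cbind(counts, ballast = 1000L)  # stabilize per-cell depth
  fc <- fold_change_matrix(counts, labels)
  expect_equal(unname(fc["NT", ]), rep(1, 4))
  expect_equal(unname(fc["KO", "gAbsent"]), 1)  # pseudocount
  expect_equal(unname(fc["KO", "gUp"]), 2, tolerance = 0.15)
})

test_that("DE selection applies the baseMean-dependent threshold", {
  rec <- data.frame(
    gene = c("a", "b", "c", "d"),
    baseMean = c(25, 2500, 4, 25),
    log2FoldChange = c(1.2, 0.45, 9, 1.31),
    padj = c(0.01, 0.05, 1e-9, 0.01))
  sel <- select_de_genes(rec)
  expect_false("a" %in% sel)  # threshold 5/sqrt(25)+0.3 = 1.3, 1.2 fails
  expect_true("b" %in% sel)   # threshold 0.4, 0.45 passes
  expect_false("c" %in% sel)  # baseMean <= 5 excluded outright
  expect_true("d" %in% sel)   # 1.31 > 1.3
})

test_that("loosening any DE rule component never removes a gene", {
  set.seed(12)
  rec <- data.frame(gene = paste0("g", 1:300),
                    baseMean = rlnorm(300, 3, 1),
                    log2FoldChange = rnorm(300, 0, 1.5),
                    padj = runif(300))
  base <- select_de_genes(rec)
  looser <- list(de_selection_rule(padj_max = 0.3),
                 de_selection_rule(basemean_min = 1),
                 de_selection_rule(lfc_offset = 0.1),
                 de_selection_rule(lfc_coef = 2))
  for (r in looser) expect_true(all(base %in% select_de_genes(rec, r)))
})

test_that("z-scored k-means standardizes rows and recovers separated groups", {
  set.seed(3)
  g1 <- matrix(rnorm(20 * 6, mean = rep(c(5, -5), each = 3), sd = 0.2),
               nrow = 20, byrow = TRUE)
  g2 <- matrix(rnorm(20 * 6, mean = rep(c(-5, 5), each = 3), sd = 0.2),
               nrow = 20, byrow = TRUE)
  m <- rbind(g1, g2)
  rownames(m) <- paste0("gene", 1:40)
  res <- cluster_zscore_kmeans(m, k = 2, seed = 1)
  expect_equal(unname(rowMeans(res$zmat)), rep(0, 40), tolerance = 1e-12)
  expect_equal(unname(apply(res$zmat, 1, sd)), rep(1, 40), tolerance = 1e-12)
  expect_equal(length(unique(res$cluster[1:20])), 1L)
  expect_equal(length(unique(res$cluster[21:40])), 1L)
  expect_false(res$cluster[[1]] == res$cluster[[40]])

  m2 <- rbind(m, constant = 7)
  res2 <- cluster_zscore_kmeans(m2, k = 2, seed = 1)
  expect_equal(unname(res2$zmat["constant", ]), rep(0, 6))
  expect_error(cluster_zscore_kmeans(m[1:3, ], k = 5), class = "k_too_large")
})

test_that("k-means clustering is reproducible for a fixed seed", {
  set.seed(99)
  m <- matrix(rnorm(200 * 8), nrow = 200,
              dimnames = list(paste0("g", 1:200), NULL))
  expect_identical(cluster_zscore_kmeans(m, 4, seed = 7)$cluster,
                   cluster_zscore_kmeans(m, 4, seed = 7)$cluster)
})
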