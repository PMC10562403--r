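test_that("relative counts normalize within cell and ignore depth", {
  m <- rbind(c1 = c(CD86 = 30, `PD-L1` = 10),
             c2 = c(CD86 = 300, `PD-L1` = 100),   # 10x deeper, same profile
             c3 = c(CD86 = 0, `PD-L1` = 0))
  rc <- rc_normalize(m)
  expect_equal(rc["c1", ], c(CD86 = 0.75, `PD-L1` = 0.25))
  expect_equal(rc["c1", ], rc["c2", ])
  expect_equal(rc["c3", ], c(CD86 = 0, `PD-L1` = 0))
})

hto3 <- function(dom) {
  # three singlet cells on HTO1 with given dominant counts, bg zero
  m <- cbind(HTO1 = dom, HTO2 = 0)
  rownames(m) <- paste0("c", seq_along(dom))
  calls <- data.frame(cell_id = rownames(m), status = "singlet",
                      hashtag = "HTO1")
  list(m = m, calls = calls)
}

test_that("HTO-Max divides dominant counts by the group mean", {
  d <- hto3(c(100, 200, 300))
  hm <- compute_hto_max(d$m, d$calls)
  expect_equal(unname(hm), c(0.5, 1.0, 1.5))
  expect_equal(mean(hm), 1, tolerance = 1e-9)
})

test_that("group normalization cancels per-hashtag staining efficiency", {
  set.seed(4)
  base <- rlnorm(200, log(100), 0.3)
  m <- rbind(cbind(HTO1 = base, HTO2 = 0),
             cbind(HTO1 = 0, HTO2 = 5 * base))  # 5x brighter antibody
  rownames(m) <- paste0("c", seq_len(400))
  calls <- data.frame(cell_id = rownames(m), status = "singlet",
                      hashtag = rep(c("HTO1", "HTO2"), each = 200))
  hm <- compute_hto_max(m, calls)
  expect_equal(unname(hm[1:200]), unname(hm[201:400]), tolerance = 1e-12)
})

test_that("the combined protein score is CD86 + HTO-Max - PD-L1", {
  rc <- rbind(c1 = c(CD86 = 0.75, `PD-L1` = 0.25),
              c2 = c(CD86 = 0.4, `PD-L1` = 0.4))
  hm <- c(c1 = 1.0, c2 = 0.8)
  sc <- protein_score(rc, hm)
  expect_equal(sc$score[sc$cell_id == "c1"], 1.5)
  expect_equal(sc$score[sc$cell_id == "c2"], 0.8)  # equal ADTs cancel
  expect_error(protein_score(rc[, 1, drop = FALSE], hm),
               class = "missing_modality")
})

test_that("raising a cell's raw CD86 count strictly raises its score", {
  raw <- rbind(a = c(CD86 = 50, `PD-L1` = 50),
               b = c(CD86 = 80, `PD-L1` = 50))
  hm <- c(a = 1, b = 1)
  sc <- protein_score(rc_normalize(raw), hm)
  expect_gt(sc$score[sc$cell_id == "b"], sc$score[sc$cell_id == "a"])
})

rank_fixture <- function(scores_by_label) {
  cells <- unlist(lapply(names(scores_by_label), function(l)
    paste0(l, "_", seq_along(scores_by_label[[l]]))))
  data.frame(cell_id = cells,
             score = unlist(scores_by_label, use.names = FALSE),
             label = rep(names(scores_by_label),
                         lengths(scores_by_label)))
}

test_that("rankings are relative to the NT median and sorted descending", {
  df <- rank_fixture(list(NT = c(1, 2, 3), A = c(4, 5, 6), B = c(0, 1, 2)))
  rk <- summarize_and_rank(df[, c("cell_id", "score")],
                           df[, c("cell_id", "label")])
  expect_equal(rk$relative_score[rk$label == "NT"], 0)
  expect_equal(rk$label, c("A", "NT", "B"))
  expect_equal(rk$relative_score[rk$label == "A"], 3)
  expect_equal(rk$rank, 1:3)
  expect_error(summarize_and_rank(df[, c("cell_id", "score")],
                                  data.frame(cell_id = df$cell_id,
                                             label = "A"),
                                  "NT"),
               class = "missing_reference")
})

test_that("ranking is invariant to cell order and null labels score near zero", {
  set.seed(9)
  df <- rank_fixture(split(rnorm(300), rep(c("NT", "A", "B"), each = 100)))
  rk1 <- summarize_and_rank(df[, c("cell_id", "score")],
                            df[, c("cell_id", "label")])
  shuf <- df[sample.int(nrow(df)), ]
  rk2 <- summarize_and_rank(shuf[, c("cell_id", "score")],
                            shuf[, c("cell_id", "label")])
  expect_equal(rk1, rk2)
  expect_lt(max(abs(rk1$relative_score)), 0.5)  # all from one distribution
})

test_that("a planted strongest combination ranks first on simulated data", {
  ds <- simulate_dataset(sim_config(n_cells = 2500L), seed = 33)
  calls <- classify_hashtags(clr_normalize(as.matrix(ds$hto)))
  sing <- calls[calls$status == "singlet", ]
  labs <- label_cells(assign_guides(ds$gdo[sing$cell_id, ]),
                      guide_to_gene_map(ds$feature_ref))
  combo <- filter_combinations(labs)
  hm <- compute_hto_max(ds$hto[sing$cell_id, ], sing)
  sc <- protein_score(rc_normalize(as.matrix(ds$adt[sing$cell_id, ])), hm)
  rk <- summarize_and_rank(sc, combo$retained)
  expect_equal(rk$label[1], "Cebpb+Med12")
})
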