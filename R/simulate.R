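#' Default guide pool: 32 targeting guides over 11 genes plus 4 non-targeting
#'
#' Ten genes carry three guides each and one carries two (32 targeting
#' guides), mirroring a focused validation pool for co-stimulation
#' regulators; four non-targeting guides define the control population.
#'
#' @return Data frame with columns `guide`, `gene`, `is_nt`.
#' @export
default_guide_pool <- function() {
  genes3 <- c("Cebpb", "Med12", "Nr4a3", "Zeb2", "Stat5b", "Socs1", "Stat3",
              "Brd4", "Kdm6a", "Spi1")
  pool <- rbind(
    data.frame(guide = paste0("g", rep(genes3, each = 3L), "_",
                              rep(1:3, times = length(genes3))),
               gene = rep(genes3, each = 3L), is_nt = FALSE),
    data.frame(guide = c("gHdac3_1", "gHdac3_2"), gene = "Hdac3",
               is_nt = FALSE),
    data.frame(guide = paste0("gNT_", 1:4), gene = "NT", is_nt = TRUE))
  rownames(pool) <- NULL
  pool
}

#' Default perturbation effects on surface proteins
#'
#' Per-gene log2 shifts of the CD86, PD-L1 and MHC-I surface levels caused
#' by knocking the gene out. The strongest planted combination is
#' Cebpb+Med12, which additionally carries a synergistic interaction term
#' (see [sim_config()]).
#'
#' @return Genes x c("CD86", "PD-L1", "MHC") numeric matrix of log2 effects.
#' @export
default_effect_matrix <- function() {
  m <- rbind(Cebpb  = c( 0.8, -0.8,  0.4),
             Med12  = c( 0.6, -0.5,  0.3),
             Nr4a3  = c( 0.3, -0.2,  0.1),
             Zeb2   = c( 0.0, -0.6,  0.0),
             Stat5b = c( 0.2, -0.4,  0.0),
             Socs1  = c( 0.1, -0.3,  0.1),
             Stat3  = c(-0.2,  0.2, -0.1),
             Brd4   = c(-0.3,  0.1,  0.0),
             Kdm6a  = c( 0.2,  0.0,  0.1),
             Spi1   = c(-0.1, -0.1,  0.0),
             Hdac3  = c( 0.3,  0.3,  0.1))
  colnames(m) <- c("CD86", "PD-L1", "MHC")
  m
}

default_state_programs <- function() {
  list(mature       = sprintf("MatG%02d", 1:25),
       inflammatory = sprintf("InfG%02d", 1:25),
       progenitor   = sprintf("ProG%02d", 1:25))
}

default_perturbation_programs <- function() {
  progs <- list(
    Cebpb = c(Cd86 = 1.0, Marco = -1.0, Mrc1 = -1.0, Cebpb = -1.5),
    Zeb2  = c(Cd274 = -0.8, Zeb2 = -1.5))
  # every other knockout silences (mostly) its own transcript
  for (g in c("Med12", "Nr4a3", "Stat5b", "Socs1", "Stat3", "Brd4",
              "Kdm6a", "Spi1", "Hdac3")) {
    progs[[g]] <- setNames(-1.5, g)
  }
  progs
}

#' Simulation configuration for a high-MOI perturbation CITE-seq experiment
#'
#' The defaults emulate the study design this package processes: bone-marrow
#' derived dendritic cells infected at a multiplicity of infection of 1.6
#' with a pool of 32 targeting guides over 11 genes plus non-targeting
#' controls, hashed with 5 hashtag antibodies against MHC-I/CD45, stained
#' with a two-antibody ADT panel (CD86, PD-L1), and loaded with droplet
#' doublets and ambient guide background. Integration numbers follow a
#' zero-truncated Poisson (selection keeps only infected cells). All counts
#' are negative binomial; perturbation effects compose additively in log2
#' space, with optional pairwise interaction terms for planted synergies.
#'
#' @param n_cells Number of true cells (default 4000).
#' @param moi_lambda Poisson rate of lentiviral integrations (default 1.6).
#' @param guide_pool Data frame `guide`/`gene`/`is_nt`
#'   (default [default_guide_pool()]).
#' @param n_htos Number of hashtags (default 5).
#' @param doublet_rate Fraction of droplets holding two cells (default 0.05).
#' @param hto_mu_pos,hto_mu_bg Mean counts of a cell's own hashtag and of
#'   background hashtags (defaults 200 and 10), per-HTO scaled by
#'   `hto_efficiency`.
#' @param hto_efficiency Per-hashtag staining-efficiency factors.
#' @param gdo_mu Mean GDO UMIs per integration copy (default 40).
#' @param gdo_ambient_mu Ambient mean per guide per cell (default 0.05).
#' @param adt_baseline Named baseline means for the ADT panel.
#' @param nb_dispersion Negative-binomial size parameter shared by all
#'   modalities (default 10).
#' @param effect_matrix Genes x (CD86, PD-L1, MHC) log2 effect matrix.
#' @param interaction_terms Named list (`"geneA+geneB"`, sorted) of extra
#'   log2 effect triples for co-occurring pairs.
#' @param n_genes Size of the synthetic transcript panel (default 500).
#' @param state_programs Named list of state marker-gene vectors.
#' @param state_probs State mixing proportions.
#' @param state_effect log2 up-shift of a state's markers (default 2).
#' @param perturbation_programs Named list: per perturbed gene, named log2
#'   shifts of panel transcripts.
#' @param depth_sdlog Log-normal sd of per-cell depth factors (default 0.25).
#' @param reads_per_umi Named list per modality of `c(min, lambda)`: reads
#'   per UMI are `min + Poisson(lambda)`. GDO defaults start at 5 so that a
#'   noise-free simulation survives the GDO read floor.
#' @param chimera_rate Fraction of UMIs acquiring a second, spurious feature
#'   (default 0.02).
#' @param chimera_frac Fraction of a chimeric UMI's reads on the spurious
#'   feature (default 0.1; 0.5 = balanced).
#' @param cbc_len,umi_len Barcode lengths for read-level simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 4000L,
                       moi_lambda = 1.6,
                       guide_pool = default_guide_pool(),
                       n_htos = 5L,
                       doublet_rate = 0.05,
                       hto_mu_pos = 200,
                       hto_mu_bg = 10,
                       hto_efficiency = c(1, 1.4, 0.8, 1.2, 0.9),
                       gdo_mu = 40,
                       gdo_ambient_mu = 0.05,
                       adt_baseline = c("CD86" = 150, "PD-L1" = 150),
                       nb_dispersion = 10,
                       effect_matrix = default_effect_matrix(),
                       interaction_terms = list(
                         "Cebpb+Med12" = c("CD86" = 0.5, "PD-L1" = -0.5,
                                           "MHC" = 0.3)),
                       n_genes = 500L,
                       state_programs = default_state_programs(),
                       state_probs = c(0.5, 0.3, 0.2),
                       state_effect = 2,
                       perturbation_programs = default_perturbation_programs(),
                       depth_sdlog = 0.25,
                       reads_per_umi = list(ADT = c(1, 2), HTO = c(1, 2),
                                            GDO = c(5, 3)),
                       chimera_rate = 0.02,
                       chimera_frac = 0.1,
                       cbc_len = 16L,
                       umi_len = 12L) {
  stopifnot(n_cells >= 1, moi_lambda > 0, doublet_rate >= 0, doublet_rate <= 1,
            nb_dispersion > 0, length(hto_efficiency) == n_htos,
            all(state_probs > 0), length(state_probs) == length(state_programs))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Zero-truncated Poisson sampler via the inverse-cdf trick.
ztp_sample <- function(n, lambda) {
  qpois(runif(n, stats::dpois(0, lambda), 1), lambda)
}

#' Probability of multiple integrations under a zero-truncated Poisson
#'
#' For integration count K ~ Poisson(lambda) conditioned on K >= 1 (cells
#' without any integration are removed by selection), returns
#' `P(K >= 2 | K >= 1) = (1 - exp(-lambda) - lambda exp(-lambda)) /
#' (1 - exp(-lambda))`. At lambda = 1.6 this is about 0.595: the design
#' point at which roughly half the cells carry guide combinations.
#'
#' @param lambda Mean of the untruncated Poisson (> 0).
#' @return The multi-integration fraction.
#' @export
ztp_multi_fraction <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) == 0 || any(lambda <= 0)) {
    pt_stop("non_positive_lambda", "lambda must be > 0")
  }
  (1 - exp(-lambda) - lambda * exp(-lambda)) / (1 - exp(-lambda))
}

# Synthetic transcript panel: named target/marker/state-program genes first,
# generic filler after. Deterministic (names only; means are drawn at
# simulation time).
panel_genes <- function(cfg) {
  special <- unique(c(rownames(cfg$effect_matrix), "Cd86", "Cd274", "Marco",
                      "Mrc1", "Ccr7", "Fscn1",
                      unlist(cfg$state_programs, use.names = FALSE),
                      unlist(lapply(cfg$perturbation_programs, names),
                             use.names = FALSE)))
  n_fill <- cfg$n_genes - length(special)
  if (n_fill < 0) pt_stop("invalid_config", "n_genes smaller than named panel")
  c(special, sprintf("G%04d", seq_len(n_fill)))
}

# Summed log2 tag effect for one cell's perturbed gene set.
cell_tag_effect <- function(genes, cfg) {
  d <- c("CD86" = 0, "PD-L1" = 0, "MHC" = 0)
  genes <- intersect(genes, rownames(cfg$effect_matrix))
  if (length(genes)) {
    d <- d + colSums(cfg$effect_matrix[genes, , drop = FALSE])
    if (length(genes) >= 2L && length(cfg$interaction_terms)) {
      prs <- utils::combn(sort(genes), 2L,
                          FUN = function(p) paste(p, collapse = "+"))
      for (p in intersect(prs, names(cfg$interaction_terms))) {
        d <- d + cfg$interaction_terms[[p]][names(d)]
      }
    }
  }
  d
}

#' Simulate a high-MOI perturbation CITE-seq dataset with ground truth
#'
#' Draws per-cell integration numbers from a zero-truncated Poisson, samples
#' guides with replacement from the pool, assigns one hashtag per cell,
#' merges a `doublet_rate` fraction of droplets, and draws ADT/HTO/GDO tag
#' counts and a synthetic transcript panel from negative binomials whose
#' means carry the perturbation, interaction and cell-state effects in log2
#' space. Fully deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `sim_dataset` with droplet x feature count
#'   matrices `adt`, `hto`, `gdo`, `expr`, the `feature_ref`
#'   ([feature_reference()]) used for read-level simulation, `truth`
#'   (`$cells` per true cell and `$droplets` per droplet), plus `config` and
#'   `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  pool <- cfg$guide_pool
  n <- cfg$n_cells
  g2g <- setNames(pool$gene, pool$guide)
  gp <- guide_params()

  k <- ztp_sample(n, cfg$moi_lambda)
  guides_per_cell <- lapply(k, function(ki)
    sample(pool$guide, ki, replace = TRUE))
  hashtag <- paste0("HTO", sample.int(cfg$n_htos, n, replace = TRUE))
  state <- sample(names(cfg$state_programs), n, replace = TRUE,
                  prob = cfg$state_probs)
  label <- vapply(guides_per_cell, function(g)
    label_perturbation(unique(g), g2g, gp), "")

  # droplet formation: doublet_rate of droplets hold two cells
  n_doub <- round(cfg$doublet_rate * n / (1 + cfg$doublet_rate))
  perm <- sample.int(n)
  droplet_of <- integer(n)
  if (n_doub > 0L) {
    droplet_of[perm[seq_len(2L * n_doub)]] <- rep(seq_len(n_doub), each = 2L)
  }
  rest <- if (n_doub > 0L) perm[-seq_len(2L * n_doub)] else perm
  droplet_of[rest] <- n_doub + seq_along(rest)
  n_drop <- n_doub + length(rest)
  droplet_ids <- random_dna_unique(n_drop, cfg$cbc_len)

  # per-cell log2 tag effects
  genes_per_cell <- lapply(guides_per_cell, function(g)
    setdiff(unique(g2g[unique(g)]), "NT"))
  dmat <- t(vapply(genes_per_cell, cell_tag_effect, numeric(3), cfg = cfg))

  nb <- function(mu) {
    out <- mu
    out[] <- rnbinom(length(mu), mu = as.vector(mu), size = cfg$nb_dispersion)
    out
  }
  by_droplet <- function(mu_cells) {
    agg <- rowsum(mu_cells, droplet_of)
    rownames(agg) <- droplet_ids[as.integer(rownames(agg))]
    agg[droplet_ids, , drop = FALSE]
  }

  adt_mu <- cbind("CD86" = cfg$adt_baseline[["CD86"]] * 2^dmat[, "CD86"],
                  "PD-L1" = cfg$adt_baseline[["PD-L1"]] * 2^dmat[, "PD-L1"])
  adt <- nb(by_droplet(adt_mu))

  hto_names <- paste0("HTO", seq_len(cfg$n_htos))
  hto_mu <- matrix(rep(cfg$hto_mu_bg * cfg$hto_efficiency, each = n),
                   nrow = n, dimnames = list(NULL, hto_names))
  own <- cbind(seq_len(n), match(hashtag, hto_names))
  hto_mu[own] <- hto_mu[own] +
    cfg$hto_mu_pos * cfg$hto_efficiency[own[, 2L]] * 2^dmat[, "MHC"]
  hto <- nb(by_droplet(hto_mu))

  gdo_mu <- matrix(cfg$gdo_ambient_mu, nrow = n, ncol = nrow(pool),
                   dimnames = list(NULL, pool$guide))
  for (i in seq_len(n)) {
    copies <- table(guides_per_cell[[i]])
    gdo_mu[i, names(copies)] <- gdo_mu[i, names(copies)] +
      cfg$gdo_mu * as.integer(copies)
  }
  gdo <- nb(by_droplet(gdo_mu))

  genes <- panel_genes(cfg)
  base_mu <- setNames(rlnorm(length(genes), log(10), 1), genes)
  expr_d <- matrix(0, nrow = n, ncol = length(genes),
                   dimnames = list(NULL, genes))
  for (s in names(cfg$state_programs)) {
    rows <- state == s
    expr_d[rows, cfg$state_programs[[s]]] <-
      expr_d[rows, cfg$state_programs[[s]]] + cfg$state_effect
  }
  for (i in seq_len(n)) {
    for (g in intersect(genes_per_cell[[i]],
                        names(cfg$perturbation_programs))) {
      prog <- cfg$perturbation_programs[[g]]
      expr_d[i, names(prog)] <- expr_d[i, names(prog)] + prog
    }
  }
  depth <- rlnorm(n, 0, cfg$depth_sdlog)
  expr_mu <- depth * t(base_mu * t(2^expr_d))
  expr <- nb(by_droplet(expr_mu))

  feature_ref <- feature_reference(data.frame(
    feature_id = c(colnames(adt), hto_names, pool$guide),
    display_name = c("CD86 antibody tag", "PD-L1 antibody tag",
                     paste0("hashtag-", seq_len(cfg$n_htos)), pool$guide),
    modality = c("ADT", "ADT", rep("HTO", cfg$n_htos),
                 rep("GDO", nrow(pool))),
    barcode_seq = random_dna_unique(2L + cfg$n_htos + nrow(pool), 15L),
    target_label = c("CD86", "PD-L1", hto_names, pool$gene),
    stringsAsFactors = FALSE))

  cells <- data.frame(
    cell = seq_len(n),
    droplet_id = droplet_ids[droplet_of],
    hashtag = hashtag,
    n_integrations = k,
    guides = vapply(guides_per_cell, paste, "", collapse = ","),
    label = label,
    state = state,
    d_cd86 = dmat[, "CD86"], d_pdl1 = dmat[, "PD-L1"], d_mhc = dmat[, "MHC"],
    stringsAsFactors = FALSE)
  memb <- split(seq_len(n), droplet_of)
  droplets <- data.frame(
    droplet_id = droplet_ids,
    n_members = lengths(memb)[as.character(seq_len(n_drop))],
    stringsAsFactors = FALSE)
  droplets$is_doublet <- droplets$n_members > 1L
  one <- vapply(memb[as.character(seq_len(n_drop))], function(ix) {
    if (length(ix) == 1L) ix else NA_integer_
  }, integer(1))
  droplets$hashtag <- ifelse(is.na(one), NA_character_, hashtag[one])
  droplets$label <- ifelse(is.na(one), NA_character_, label[one])
  droplets$state <- ifelse(is.na(one), NA_character_, state[one])
  droplets$same_hashtag <- vapply(memb[as.character(seq_len(n_drop))],
                                  function(ix)
                                    length(unique(hashtag[ix])) == 1L,
                                  logical(1))

  structure(list(adt = adt, hto = hto, gdo = gdo, expr = expr,
                 feature_ref = feature_ref,
                 truth = list(cells = cells, droplets = droplets),
                 config = cfg, seed = seed),
            class = "sim_dataset")
}

#' Per-droplet QC profiles from simulated (or counted) matrices
#'
#' @param gdo Droplets x guides GDO count matrix.
#' @param expr Droplets x genes cDNA count matrix (same rows).
#' @return Data frame with `cell_id`, `total_gdo_umis`, `total_cdna_umis`,
#'   `n_genes_detected`, ready for [apply_qc_filters()].
#' @export
qc_profiles_from_matrices <- function(gdo, expr) {
  stopifnot(identical(rownames(gdo), rownames(expr)))
  data.frame(cell_id = rownames(gdo),
             total_gdo_umis = as.integer(rowSums(gdo)),
             total_cdna_umis = as.integer(rowSums(expr)),
             n_genes_detected = as.integer(rowSums(expr > 0)),
             stringsAsFactors = FALSE)
}

#' Emit read-level tag evidence for a simulated dataset
#'
#' Expands every tag UMI of the dataset into a (CBC, UMI, tag sequence,
#' read count) record: read counts are `min + Poisson(lambda)` per the
#' modality's `reads_per_umi` config, and a `chimera_rate` fraction of UMIs
#' gain a second, spurious feature of the same modality carrying
#' `chimera_frac` of the reads. UMI sequences are distinct within a droplet.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param config Simulation config (defaults to the dataset's own).
#' @param seed Integer seed.
#' @return Data frame with columns `cbc`, `umi`, `tag_seq`, `n_reads`,
#'   suitable for [count_tags()].
#' @export
simulate_tag_reads <- function(dataset, config = dataset$config, seed = 1L) {
  cfg <- config
  set.seed(seed)
  ref <- dataset$feature_ref
  bc <- setNames(ref$barcode_seq, ref$feature_id)
  mats <- list(ADT = dataset$adt, HTO = dataset$hto, GDO = dataset$gdo)
  parts <- list()
  for (modality in names(mats)) {
    m <- as.matrix(mats[[modality]])
    idx <- which(m > 0, arr.ind = TRUE)
    if (!nrow(idx)) next
    cnt <- m[idx]
    parts[[modality]] <- data.table::data.table(
      cbc = rep(rownames(m)[idx[, 1L]], cnt),
      feature_id = rep(colnames(m)[idx[, 2L]], cnt),
      modality = modality)
  }
  dt <- data.table::rbindlist(parts)
  if (!nrow(dt)) {
    return(data.frame(cbc = character(0), umi = character(0),
                      tag_seq = character(0), n_reads = integer(0)))
  }
  data.table::setorder(dt, cbc, modality, feature_id)
  dt[, umi := random_dna_unique(.N, cfg$umi_len), by = cbc]
  rp <- cfg$reads_per_umi
  dt[, n_reads := rp[[modality[1L]]][1L] + rpois(.N, rp[[modality[1L]]][2L]),
     by = modality]
  dt[, tag_seq := bc[feature_id]]

  out <- dt[, .(cbc, umi, tag_seq, n_reads)]
  if (cfg$chimera_rate > 0) {
    chim <- dt[runif(.N) < cfg$chimera_rate]
    if (nrow(chim)) {
      feats_by_mod <- split(ref$feature_id, ref$modality)
      chim[, other := vapply(seq_len(.N), function(i) {
        alt <- setdiff(feats_by_mod[[modality[i]]], feature_id[i])
        if (length(alt)) sample(alt, 1L) else NA_character_
      }, character(1))]
      chim <- chim[!is.na(other)]
      extra <- chim[, .(cbc, umi, tag_seq = bc[other],
                        n_reads = pmax(1L, as.integer(round(
                          n_reads * cfg$chimera_frac / (1 - cfg$chimera_frac)))))]
      out <- rbind(out, extra)
    }
  }
  data.table::setorder(out, cbc, umi, tag_seq)
  as.data.frame(out)
}
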