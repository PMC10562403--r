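pt_log <- function(verbosity, level, msg, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] >= levels[[verbosity %||% "info"]]) {
    message(sprintf("%s [%s] %s", format(Sys.time(), "%H:%M:%S"),
                    toupper(level), sprintf(msg, ...)))
  }
}

take_args <- function(fun, overrides) {
  overrides <- overrides %||% list()
  do.call(fun, overrides[intersect(names(overrides), names(formals(fun)))])
}

#' Run the full tag-to-ranking pipeline
#'
#' Executes the stages end to end: obtain input matrices (either simulated
#' from a config block or read from 10x-style MTX directories), apply
#' per-cell QC, CLR-normalize and demultiplex hashtags, call guides and
#' gene-level perturbation labels, drop rare combinations, compute the
#' combined protein score, and rank combinations against the non-targeting
#' reference. All artifacts are written under `output_dir` together with a
#' JSON run report (parameter echo, per-stage tallies, md5 manifest); the
#' report contains no timestamps, so re-running the same config and seed
#' reproduces it byte for byte.
#'
#' @param config A named list, or the path of a YAML file, with (all
#'   optional except `output_dir`): `seed`, `verbosity`
#'   (`"debug"`/`"info"`/`"warn"`), `simulate` (a block of [sim_config()]
#'   overrides) or `input` (directories `adt_mtx`, `hto_mtx`, `gdo_mtx`,
#'   `expr_mtx`), `qc` ([qc_params()] overrides), `guides` ([guide_params()]
#'   overrides), and `score` (`reference_label`, `cd86`, `pdl1`).
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      pt_stop("config_error", "config file not found: %s", config)
    }
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$output_dir
  if (is.null(out_dir)) pt_stop("config_error", "output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  verbosity <- config$verbosity %||% "info"
  seed <- config$seed %||% 1L

  stage <- "input"
  report <- list(package_version = as.character(utils::packageVersion("perturbtag")),
                 seed = seed, stages = list(), files = list())
  on_fail <- function(e) {
    writeLines(sprintf("stage: %s\n%s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    pt_stop("stage_failure", "pipeline failed at stage '%s': %s", stage,
            conditionMessage(e))
  }
  tryCatch({
    if (!is.null(config$simulate) || is.null(config$input)) {
      pt_log(verbosity, "info", "simulating input dataset (seed %d)", seed)
      sim_cfg <- take_args(sim_config, config$simulate)
      ds <- simulate_dataset(sim_cfg, seed = seed)
      adt <- ds$adt; hto <- ds$hto; gdo <- ds$gdo; expr <- ds$expr
      guide_map <- guide_to_gene_map(ds$feature_ref)
      report$stages$input <- list(mode = "simulated",
                                  n_droplets = nrow(adt))
    } else {
      for (key in c("adt_mtx", "hto_mtx", "gdo_mtx", "expr_mtx")) {
        p <- config$input[[key]]
        if (is.null(p) || !dir.exists(p)) {
          pt_stop("config_error", "input path missing or absent: %s = %s",
                  key, p %||% "<unset>")
        }
      }
      pt_log(verbosity, "info", "reading input matrices")
      adt <- read_count_matrix(config$input$adt_mtx)
      hto <- read_count_matrix(config$input$hto_mtx)
      gdo <- read_count_matrix(config$input$gdo_mtx)
      expr <- read_count_matrix(config$input$expr_mtx)
      guide_map <- setNames(colnames(gdo), colnames(gdo))
      if (!is.null(config$input$feature_ref)) {
        guide_map <- guide_to_gene_map(
          load_feature_reference(config$input$feature_ref))
      }
      report$stages$input <- list(mode = "files", n_droplets = nrow(adt))
    }

    stage <- "qc"
    qp <- take_args(qc_params, config$qc)
    qc <- apply_qc_filters(qc_profiles_from_matrices(gdo, expr), qp)
    pt_log(verbosity, "info", "QC retained %d / %d droplets",
           qc$report$n_retained, qc$report$n_input)
    report$stages$qc <- qc$report
    keep <- qc$retained

    stage <- "demux"
    calls <- classify_hashtags(clr_normalize(hto[keep, , drop = FALSE]))
    singlets <- calls$cell_id[calls$status == "singlet"]
    pt_log(verbosity, "info", "%d hashtag singlets, %d doublets, %d negatives",
           sum(calls$status == "singlet"), sum(calls$status == "doublet"),
           sum(calls$status == "negative"))
    report$stages$demux <- as.list(table(calls$status))

    stage <- "assign"
    gp <- take_args(guide_params, config$guides)
    guide_calls <- assign_guides(gdo[singlets, , drop = FALSE], gp)
    labels <- label_cells(guide_calls, guide_map, gp)
    combo <- filter_combinations(labels, gp)
    pt_log(verbosity, "info",
           "%d cells with called guides; %d cells in %d retained combinations",
           nrow(labels), nrow(combo$retained),
           length(unique(combo$retained$label)))
    report$stages$assign <- list(
      n_singlets = length(singlets),
      n_called = nrow(labels),
      n_after_combo_filter = nrow(combo$retained),
      n_labels = length(unique(combo$retained$label)),
      n_labels_dropped = nrow(combo$dropped))

    stage <- "score"
    sc_cfg <- config$score %||% list()
    hto_max <- compute_hto_max(hto[singlets, , drop = FALSE],
                               calls[calls$status == "singlet", , drop = FALSE])
    rc <- rc_normalize(adt[singlets, , drop = FALSE])
    scores <- protein_score(rc, hto_max,
                            cd86 = sc_cfg$cd86 %||% "CD86",
                            pdl1 = sc_cfg$pdl1 %||% "PD-L1")
    ranked <- summarize_and_rank(scores, combo$retained,
                                 sc_cfg$reference_label %||% "NT")
    pt_log(verbosity, "info", "top combination: %s (relative score %.3f)",
           ranked$label[1L], ranked$relative_score[1L])
    report$stages$score <- list(n_scored = nrow(scores),
                                n_ranked_labels = nrow(ranked))

    stage <- "write"
    outputs <- list(
      hashtag_calls.tsv = calls,
      guide_calls.tsv = guide_calls,
      labels.tsv = combo$retained,
      dropped_combinations.tsv = combo$dropped,
      cell_scores.tsv = scores,
      ranked_combinations.tsv = ranked)
    for (fn in names(outputs)) {
      utils::write.table(outputs[[fn]], file.path(out_dir, fn), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    report$params <- list(qc = unclass(qp), guides = unclass(gp),
                          score = sc_cfg)
    report$files <- lapply(names(outputs), function(fn)
      list(file = fn,
           md5 = unname(tools::md5sum(file.path(out_dir, fn)))))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    pt_log(verbosity, "info", "wrote %d artifacts to %s",
           length(outputs) + 1L, out_dir)
  }, perturbtag_error = function(e) {
    if (inherits(e, "config_error") || inherits(e, "stage_failure")) stop(e)
    on_fail(e)
  }, error = function(e) {
    if (inherits(e, "stage_failure") || inherits(e, "config_error")) stop(e)
    on_fail(e)
  })
  invisible(report)
}
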