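#' Run the full simulate / demux / quantify / analyze pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' under `out_dir` (`sim/`, `demux/`, `quantify/`, `analysis/`), a resolved
#' config snapshot, and a line-structured log (`stage`, `metric`, `value`).
#' Each stage is deterministic given the global seed (stages draw child
#' seeds via [derive_seed()]), so a rerun reproduces byte-identical count
#' matrices, and later stages can be run alone against a pre-existing
#' `sim/` directory.
#'
#' @param config a [sim_config()] (see [fixture_config()] for built-ins).
#' @param schema a [barcode_schema()].
#' @param out_dir output directory.
#' @param stages subset of `c("simulate", "demux", "quantify", "analyze")`.
#' @param seed global seed.
#' @param demux_opts list: `min_umi`, `collapse`, `umi_mismatch`.
#' @param quantify_opts list: `pseudocount`.
#' @param analysis_opts list: `k`, `n_components`, `perplexity`, `tsne`
#'   (logical; t-SNE embedding is skipped when `FALSE`).
#' @return invisible list with the in-memory results of the executed
#'   stages (`sim`, `demux`, `clr`, `assignment`, `qc`, `pca`, `clusters`,
#'   `tsne`) and `log`.
#' @export
run_pipeline <- function(config, schema, out_dir,
                         stages = c("simulate", "demux", "quantify", "analyze"),
                         seed = 1,
                         demux_opts = list(),
                         quantify_opts = list(),
                         analysis_opts = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dm <- utils::modifyList(list(min_umi = 10, collapse = "directional",
                               umi_mismatch = 1), demux_opts)
  qt <- utils::modifyList(list(pseudocount = 1), quantify_opts)
  an <- utils::modifyList(list(k = 4, n_components = 3, perplexity = 30,
                               tsne = TRUE), analysis_opts)
  log_rows <- list()
  note <- function(stage, metric, value) {
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      stage = stage, metric = metric, value = value, stringsAsFactors = FALSE)
  }
  res <- list()
  sim_dir <- file.path(out_dir, "sim")

  if ("simulate" %in% stages) {
    res$sim <- simulate_experiment(config, schema, sim_dir, seed = seed)
    note("simulate", "n_cells", nrow(res$sim$truth$cells))
    note("simulate", "n_molecules", nrow(res$sim$truth$molecules))
    note("simulate", "n_reads", res$sim$files$n_reads)
  }

  if ("demux" %in% stages) {
    r1 <- file.path(sim_dir, "reads_R1.fastq.gz")
    r2 <- file.path(sim_dir, "reads_R2.fastq.gz")
    if (!file.exists(r1) || !file.exists(r2)) {
      stop("run_pipeline(): demux stage needs simulated reads under ", sim_dir)
    }
    res$demux <- demux_fastq(r1, r2, schema, config$panel,
                             min_umi = dm$min_umi, collapse = dm$collapse,
                             umi_mismatch = dm$umi_mismatch)
    demux_dir <- file.path(out_dir, "demux")
    write_count_matrix(res$demux$counts, demux_dir, config$panel)
    write_tsv(res$demux$ledger, file.path(demux_dir, "ledger.tsv"))
    note("demux", "n_reads_in", res$demux$ledger$n[res$demux$ledger$reason == "input"])
    note("demux", "n_reads_assigned", res$demux$ledger$n[res$demux$ledger$reason == "assigned"])
    note("demux", "n_cells_called", nrow(res$demux$counts))
  }

  if ("quantify" %in% stages) {
    counts <- if (!is.null(res$demux)) res$demux$counts
              else read_count_matrix(file.path(out_dir, "demux"))
    qdir <- file.path(out_dir, "quantify")
    dir.create(qdir, recursive = TRUE, showWarnings = FALSE)
    res$clr <- clr_transform(counts, pseudocount = qt$pseudocount)
    write_tsv(data.frame(cell = rownames(res$clr), res$clr,
                         check.names = FALSE), file.path(qdir, "clr.tsv"))
    if (!is.null(config$hashtag_code) &&
        length(config$hashtag_code$samples) >= 1) {
      res$assignment <- assign_samples(res$clr, config$hashtag_code)
      write_tsv(res$assignment, file.path(qdir, "assignments.tsv"))
      note("quantify", "n_undetermined",
           sum(res$assignment$label == "undetermined"))
    }
    cells_tsv <- file.path(sim_dir, "cells.tsv")
    flags <- if (file.exists(cells_tsv)) {
      truth_flags_for_cells(rownames(counts), read_tsv(cells_tsv))
    } else rep("none", nrow(counts))
    res$qc <- control_qc(counts, flags, config$panel,
                         pseudocount = qt$pseudocount,
                         ledger = if (!is.null(res$demux)) res$demux$ledger)
    write_tsv(qc_report_table(res$qc), file.path(qdir, "qc.tsv"))
    note("quantify", "n_ht2_called", res$qc$n_ht2_called)
    note("quantify", "n_ht3_called", res$qc$n_ht3_called)
  }

  if ("analyze" %in% stages) {
    if (is.null(res$clr)) stop("run_pipeline(): analyze stage needs the quantify stage")
    adir <- file.path(out_dir, "analysis")
    dir.create(adir, recursive = TRUE, showWarnings = FALSE)
    k_comp <- min(an$n_components, ncol(res$clr))
    res$pca <- pca_scores(res$clr, n_components = k_comp)
    res$clusters <- kmeans_cluster(res$pca$scores, k = min(an$k, nrow(res$clr)),
                                   seed = derive_seed(seed, "kmeans"))
    emb <- data.frame(cell = rownames(res$clr), res$pca$scores,
                      cluster = as.integer(res$clusters), check.names = FALSE)
    if (isTRUE(an$tsne) && nrow(res$clr) - 1 >= 3 * an$perplexity) {
      res$tsne <- tsne_embed(res$clr, seed = derive_seed(seed, "tsne"),
                             perplexity = an$perplexity)
      emb <- cbind(emb, res$tsne$coords)
    }
    write_tsv(emb, file.path(adir, "embeddings.tsv"))
    note("analyze", "k", an$k)
    note("analyze", "n_components", k_comp)
  }

  res$log <- do.call(rbind, log_rows)
  write_tsv(res$log, file.path(out_dir, "pipeline_log.tsv"))
  resolved <- list(
    stages = stages, seed = seed, demux = dm, quantify = qt,
    analysis = an[c("k", "n_components", "perplexity", "tsne")],
    wells_per_round = config$wells_per_round,
    n_regular_cells = sum(unlist(config$n_cells)),
    ht2_spike_fraction = config$ht2_spike_fraction,
    ht3_spike_fraction = config$ht3_spike_fraction,
    ligation_success_prob = config$ligation_success_prob,
    blocking_failure_prob = config$blocking_failure_prob,
    swap_rate = config$swap_rate,
    mean_reads_per_molecule = config$mean_reads_per_molecule,
    seq_error_rate = config$seq_error_rate
  )
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
  invisible(res)
}
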