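#' Built-in simulated experiment designs
#'
#' Three named scenarios at desk scale:
#'
#' * `two_lines` — a 1:1 mixture of two immortalised human cell lines
#'   (a T-lymphoblast line marked by CD4/CD45/CD28 and an embryonic-kidney
#'   line marked by CD56/CD155/CD29) profiled with a 7-antibody panel
#'   (6 markers + isotype control) plus hashtags; hashtag-only swap
#'   controls (5% of the initial pool) and late-spike blocking controls
#'   (5% after round 1) are included, along with a 2% non-specifically
#'   stained population (high isotype + residual control-hashtag signal).
#'   1,900 regular cells by default, i.e. a 2,000-cell initial pool.
#' * `ten_patients` — ten pooled hashtag-coded blood/bone-marrow-style
#'   samples over a 29-antibody hematology panel (28 markers + isotype),
#'   coded by combinations of four hashtags; includes a kappa-restricted
#'   B-lymphoproliferative sample (`patient1`) and a CD4/CD25/PD1-high
#'   T-lymphoma-like sample (`patient9`).
#' * `controls_only` — only the two spike-in control populations; a
#'   demultiplexer must call (approximately) only the pre-round-1
#'   hashtag-only cells.
#'
#' @param name fixture name.
#' @param n_cells optional override of regular-cell counts (named as the
#'   scenario's samples, or a single total for `two_lines`).
#' @param seed seed used for panel/whitelist generation.
#' @param ... further overrides passed to [sim_config()] (e.g.
#'   `swap_rate`, `blocking_failure_prob`, `seq_error_rate`).
#' @return list with `config` (a [sim_config()]) and `schema`
#'   (a [barcode_schema()]).
#' @export
fixture_config <- function(name = c("two_lines", "ten_patients", "controls_only"),
                           n_cells = NULL, seed = 1, ...) {
  name <- match.arg(name)
  schema <- barcode_schema(seed = derive_seed(seed, paste0("schema_", name)))
  cfg <- switch(name,
                two_lines = two_lines_config(n_cells, seed, ...),
                ten_patients = ten_patients_config(n_cells, seed, ...),
                controls_only = controls_only_config(seed, ...))
  list(config = cfg, schema = schema)
}

two_lines_panel <- function(seed = 1) {
  antibody_panel(
    name = c("CD56", "CD155", "CD29", "CD4", "CD45", "CD28",
             "IgG1", "HT1", "HT2", "HT3"),
    class = c(rep("marker", 6), "isotype_control", rep("hashtag", 3)),
    seed = derive_seed(seed, "two_lines_panel")
  )
}

two_lines_config <- function(n_cells = NULL, seed = 1, ...) {
  panel <- two_lines_panel(seed)
  cell_types <- list(
    jurkat = c(CD4 = 50, CD45 = 60, CD28 = 30, CD29 = 12),
    hek293t = c(CD56 = 50, CD155 = 55, CD29 = 40),
    nonspecific = c(CD56 = 10, CD155 = 10, CD29 = 10, CD4 = 10, CD45 = 10,
                    CD28 = 10, IgG1 = 35, HT3 = 35)
  )
  total <- if (is.null(n_cells)) 1900L else as.integer(sum(unlist(n_cells)))
  sim_config(
    panel = panel,
    cell_types = cell_types,
    composition = list(mix = c(jurkat = 0.49, hek293t = 0.49, nonspecific = 0.02)),
    n_cells = c(mix = total),
    hashtag_code = build_hashtag_code("mix", "HT1"),
    ...
  )
}

ten_patients_panel <- function(seed = 1) {
  markers <- c("CD45", "CD19", "CD20", "CD3", "CD4", "CD8", "CD5", "CD7",
               "CD2", "CD25", "PD1", "CTLA4", "IgKappa", "IgLambda", "CD56",
               "CD16", "CD14", "CD11b", "CD33", "CD34", "CD38", "CD10",
               "CD23", "HLA-DR", "CD123", "CD138", "CD30", "CD15")
  antibody_panel(
    name = c(markers, "IgG1", "HT-A", "HT-B", "HT-C", "HT-D", "HT2", "HT3"),
    class = c(rep("marker", length(markers)), "isotype_control",
              rep("hashtag", 6)),
    seed = derive_seed(seed, "ten_patients_panel")
  )
}

ten_patients_config <- function(n_cells = NULL, seed = 1, ...) {
  panel <- ten_patients_panel(seed)
  cell_types <- list(
    bcell_kappa = c(CD45 = 60, CD19 = 50, CD20 = 45, IgKappa = 40,
                    CD23 = 15, `HLA-DR` = 30, CD38 = 10),
    bcell_lambda = c(CD45 = 60, CD19 = 50, CD20 = 45, IgLambda = 40,
                     CD23 = 15, `HLA-DR` = 30, CD38 = 10),
    tcell_cd4 = c(CD45 = 60, CD3 = 55, CD4 = 45, CD5 = 25, CD7 = 25, CD2 = 30),
    tcell_cd8 = c(CD45 = 60, CD3 = 55, CD8 = 45, CD5 = 25, CD7 = 25, CD2 = 30),
    nk = c(CD45 = 60, CD56 = 45, CD16 = 35, CD7 = 20),
    mono = c(CD45 = 55, CD14 = 50, CD33 = 40, CD11b = 40, `HLA-DR` = 35,
             CD15 = 15),
    cll_kappa = c(CD45 = 55, CD19 = 50, CD20 = 40, CD5 = 30, CD23 = 25,
                  IgKappa = 45),
    atll = c(CD45 = 55, CD3 = 50, CD4 = 45, CD25 = 45, PD1 = 40, CTLA4 = 20)
  )
  normal <- c(bcell_kappa = 0.06, bcell_lambda = 0.04, tcell_cd4 = 0.35,
              tcell_cd8 = 0.20, nk = 0.10, mono = 0.25)
  composition <- stats::setNames(rep(list(normal), 10), paste0("patient", 1:10))
  composition$patient1 <- c(cll_kappa = 0.45, bcell_kappa = 0.03,
                            bcell_lambda = 0.02, tcell_cd4 = 0.25,
                            tcell_cd8 = 0.12, nk = 0.05, mono = 0.08)
  composition$patient9 <- c(atll = 0.50, tcell_cd4 = 0.10, tcell_cd8 = 0.08,
                            bcell_kappa = 0.04, bcell_lambda = 0.03,
                            nk = 0.08, mono = 0.17)
  if (is.null(n_cells)) n_cells <- stats::setNames(rep(150L, 10), paste0("patient", 1:10))
  code <- build_hashtag_code(paste0("patient", 1:10),
                             c("HT-A", "HT-B", "HT-C", "HT-D"))
  sim_config(panel = panel, cell_types = cell_types, composition = composition,
             n_cells = n_cells, hashtag_code = code, ...)
}

controls_only_config <- function(seed = 1, ...) {
  panel <- two_lines_panel(seed)
  args <- list(...)
  args$panel <- panel
  args$cell_types <- list()
  args$composition <- list()
  args$n_cells <- stats::setNames(integer(0), character(0))
  args$hashtag_code <- NULL
  if (is.null(args$ht2_n)) args$ht2_n <- 300L
  if (is.null(args$ht3_n)) args$ht3_n <- 300L
  do.call(sim_config, args)
}

#' Write a named fixture to disk
#'
#' Simulates the named scenario and writes its FASTQ pair, truth tables,
#' antibody panel, whitelists, hashtag code and a config snapshot into
#' `out_dir`.
#'
#' @inheritParams fixture_config
#' @param out_dir output directory.
#' @param seed global seed.
#' @return list with `config`, `schema`, `truth` and the file paths.
#' @export
make_fixture <- function(name, out_dir, seed = 1, n_cells = NULL, ...) {
  fx <- fixture_config(name, n_cells = n_cells, seed = seed, ...)
  sim <- simulate_experiment(fx$config, fx$schema, out_dir, seed = seed)
  write_antibody_panel(fx$config$panel, file.path(out_dir, "panel.tsv"))
  for (r in c("round1", "round2", "round3")) {
    write_whitelist(fx$schema$whitelists[[r]],
                    file.path(out_dir, paste0("whitelist_", r, ".txt")))
  }
  if (!is.null(fx$config$hashtag_code)) {
    write_hashtag_code(fx$config$hashtag_code, file.path(out_dir, "hashtag_code.tsv"))
  }
  snapshot <- list(fixture = name, seed = seed,
                   n_regular_cells = sum(unlist(fx$config$n_cells)),
                   ht2_spike_fraction = fx$config$ht2_spike_fraction,
                   ht3_spike_fraction = fx$config$ht3_spike_fraction,
                   wells_per_round = fx$config$wells_per_round,
                   mean_reads_per_molecule = fx$config$mean_reads_per_molecule,
                   seq_error_rate = fx$config$seq_error_rate)
  yaml::write_yaml(snapshot, file.path(out_dir, "fixture.yaml"))
  c(fx, sim)
}
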