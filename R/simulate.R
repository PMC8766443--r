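#' Simulation configuration
#'
#' Describes a forward-simulated split-pool antibody-tag experiment: the
#' antibody panel, cell types (mean bound-antibody copy numbers per
#' antibody), per-sample composition, the hashtag sample code, spike-in
#' control fractions, the split-pool layout, and the noise processes
#' (ligation failure, splint-blocking failure, antibody swapping, PCR read
#' duplication, sequencing substitution error).
#'
#' Spike-in controls mirror the standard experimental design: `HT2` cells
#' are stained only with one hashtag and enter *before* round 1 (they read
#' out antibody swapping / barcode hopping); `HT3` cells are stained only
#' with a second hashtag and are spiked in *after* the first-round
#' ligation, so with perfect splint blocking they can never acquire a
#' round-1 barcode and must vanish from the called cells.
#'
#' @param panel an [antibody_panel()].
#' @param cell_types named list; each element is a named numeric vector of
#'   mean antibody copy numbers (names must be panel antibodies). Antibodies
#'   not listed default to `background_mean`.
#' @param composition named list: sample id -> named numeric vector of
#'   cell-type proportions (summing to 1).
#' @param n_cells named integer vector: regular (non-spike) cells per sample.
#' @param hashtag_code a [build_hashtag_code()] over the panel's coding
#'   hashtags; `NULL` builds one over all hashtags except the controls.
#' @param ht2_hashtag,ht3_hashtag names of the control hashtags.
#' @param ht2_spike_fraction fraction of the initial pool made of
#'   hashtag-only swap controls (default 0.05).
#' @param ht3_spike_fraction late-spike fraction of the total cell count
#'   after round 1 (default 0.05).
#' @param ht2_n,ht3_n optional absolute control-cell counts overriding the
#'   fractions (used e.g. for controls-only runs).
#' @param hashtag_mean mean copy number of a sample's coding hashtags.
#' @param control_hashtag_mean mean copy number of the control hashtag on
#'   spike-in cells (their only antibody).
#' @param background_mean mean copy number of non-specific background
#'   staining for every antibody (including isotype and stray hashtags).
#' @param dispersion log-normal sdlog of per-cell antigen abundance around
#'   the type mean.
#' @param wells_per_round wells in ligation round 1, round 2, PCR round.
#' @param ligation_success_prob per-molecule Bernoulli success probability
#'   for ligation rounds 1 and 2 (length 2, default both 1).
#' @param blocking_failure_prob probability that a late-spike molecule
#'   illegitimately acquires a round-1 barcode from the pooled mix.
#' @param swap_rate probability that a molecule dissociates and adopts the
#'   complete well path of a uniformly chosen other cell.
#' @param pcr_cycles PCR cycle count (metadata; duplication is modelled as
#'   per-molecule read multiplicity).
#' @param mean_reads_per_molecule mean sequenced read pairs per molecule
#'   (geometric multiplicity; 1 means no duplication).
#' @param seq_error_rate per-base substitution probability.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(panel,
                       cell_types,
                       composition,
                       n_cells,
                       hashtag_code = NULL,
                       ht2_hashtag = "HT2",
                       ht3_hashtag = "HT3",
                       ht2_spike_fraction = 0.05,
                       ht3_spike_fraction = 0.05,
                       ht2_n = NULL,
                       ht3_n = NULL,
                       hashtag_mean = 60,
                       control_hashtag_mean = 150,
                       background_mean = 1,
                       dispersion = 0.35,
                       wells_per_round = c(96, 96, 96),
                       ligation_success_prob = c(1, 1),
                       blocking_failure_prob = 0,
                       swap_rate = 0,
                       pcr_cycles = 14,
                       mean_reads_per_molecule = 1.5,
                       seq_error_rate = 0.002) {
  if (length(cell_types) == 0 && is.null(ht2_n) && is.null(ht3_n)) {
    stop("sim_config(): empty cell-type list")
  }
  probs <- c(ht2_spike_fraction, ht3_spike_fraction, ligation_success_prob,
             blocking_failure_prob, swap_rate, seq_error_rate)
  if (any(probs < 0 | probs > 1)) stop("sim_config(): probabilities must lie in [0, 1]")
  stopifnot(length(wells_per_round) == 3, all(wells_per_round >= 1),
            length(ligation_success_prob) == 2,
            mean_reads_per_molecule >= 1)
  for (ty in names(cell_types)) {
    unknown <- setdiff(names(cell_types[[ty]]), panel$name)
    if (length(unknown)) {
      stop("sim_config(): cell type '", ty, "' references unknown antibodies: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (length(composition)) {
    stopifnot(setequal(names(composition), names(n_cells)))
    for (s in names(composition)) {
      stopifnot(all(names(composition[[s]]) %in% names(cell_types)),
                abs(sum(composition[[s]]) - 1) < 1e-8)
    }
  }
  coding_hashtags <- setdiff(panel_names_of_class(panel, "hashtag"),
                             c(ht2_hashtag, ht3_hashtag))
  if (is.null(hashtag_code) && length(n_cells)) {
    if (!length(coding_hashtags)) stop("sim_config(): no coding hashtags in panel")
    hashtag_code <- build_hashtag_code(names(n_cells), coding_hashtags)
  }
  structure(list(
    panel = panel, cell_types = cell_types, composition = composition,
    n_cells = n_cells, hashtag_code = hashtag_code,
    ht2_hashtag = ht2_hashtag, ht3_hashtag = ht3_hashtag,
    ht2_spike_fraction = ht2_spike_fraction,
    ht3_spike_fraction = ht3_spike_fraction,
    ht2_n = ht2_n, ht3_n = ht3_n,
    hashtag_mean = hashtag_mean, control_hashtag_mean = control_hashtag_mean,
    background_mean = background_mean, dispersion = dispersion,
    wells_per_round = as.integer(wells_per_round),
    ligation_success_prob = ligation_success_prob,
    blocking_failure_prob = blocking_failure_prob,
    swap_rate = swap_rate, pcr_cycles = pcr_cycles,
    mean_reads_per_molecule = mean_reads_per_molecule,
    seq_error_rate = seq_error_rate
  ), class = "sim_config")
}

# deterministic integer split of n into proportions p (sums exactly to n)
split_counts <- function(n, p) {
  cum <- round(cumsum(p) / sum(p) * n)
  diff(c(0L, cum))
}

#' Simulate the cell population and its true antigen abundances
#'
#' Draws per-cell bound-antibody copy numbers from a log-normal/Poisson
#' mixture around the cell type's mean (sdlog = `dispersion`), stamps each
#' regular cell with its sample's coding-hashtag subset, and appends the
#' spike-in control populations: `ht2_only` cells (pre-round-1 hashtag-only
#' swap controls) and `ht3_late_spike` cells (post-round-1 blocking
#' controls), both carrying only their control hashtag.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (simulation is deterministic given the seed).
#' @return object of class `sim_truth`: list with `cells` (data.frame:
#'   cell_id, sample_id, cell_type, control_flag) and `counts` (integer
#'   matrix cells x antibodies of true molecule copy numbers).
#' @export
simulate_cells <- function(config, seed = 1) {
  panel <- config$panel
  with_seed(seed, {
    rows <- list()
    n_regular <- sum(unlist(config$n_cells))
    for (s in names(config$n_cells)) {
      comp <- config$composition[[s]]
      nk <- split_counts(config$n_cells[[s]], comp)
      for (i in seq_along(comp)) {
        if (nk[i] > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = s, cell_type = names(comp)[i],
            control_flag = "none", n = nk[i], stringsAsFactors = FALSE)
        }
      }
    }
    f2 <- config$ht2_spike_fraction
    n_ht2 <- config$ht2_n %||% round(f2 / (1 - f2) * n_regular)
    pool_total <- n_regular + n_ht2
    n_ht3 <- config$ht3_n %||% round(config$ht3_spike_fraction * pool_total)
    if (n_ht2 > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = "spike_control", cell_type = "ht2_control",
        control_flag = "ht2_only", n = n_ht2, stringsAsFactors = FALSE)
    }
    if (n_ht3 > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = "spike_control", cell_type = "ht3_control",
        control_flag = "ht3_late_spike", n = n_ht3, stringsAsFactors = FALSE)
    }
    plan <- do.call(rbind, rows)
    cells <- data.frame(
      cell_id = sprintf("cell%06d", seq_len(sum(plan$n))),
      sample_id = rep(plan$sample_id, plan$n),
      cell_type = rep(plan$cell_type, plan$n),
      control_flag = rep(plan$control_flag, plan$n),
      stringsAsFactors = FALSE
    )
    n <- nrow(cells)
    p <- nrow(panel)
    means <- matrix(config$background_mean, nrow = n, ncol = p,
                    dimnames = list(cells$cell_id, panel$name))
    # sample coding hashtags
    if (!is.null(config$hashtag_code)) {
      for (s in names(config$hashtag_code$samples)) {
        idx <- cells$sample_id == s & cells$control_flag == "none"
        if (any(idx)) {
          means[idx, config$hashtag_code$samples[[s]]] <- config$hashtag_mean
        }
      }
    }
    # cell-type overrides (may touch any antibody, e.g. residual control
    # hashtag on non-specifically stained cells)
    for (ty in names(config$cell_types)) {
      idx <- cells$cell_type == ty & cells$control_flag == "none"
      ov <- config$cell_types[[ty]]
      if (any(idx) && length(ov)) means[idx, names(ov)] <- rep(ov, each = sum(idx))
    }
    # spike-in controls carry only their hashtag antibody
    for (fl in c("ht2_only", "ht3_late_spike")) {
      idx <- cells$control_flag == fl
      if (any(idx)) {
        means[idx, ] <- 0
        ht <- if (fl == "ht2_only") config$ht2_hashtag else config$ht3_hashtag
        means[idx, ht] <- config$control_hashtag_mean
      }
    }
    lam <- means
    pos <- means > 0
    lam[pos] <- exp(rnorm(sum(pos), mean = log(means[pos]), sd = config$dispersion))
    counts <- matrix(0L, n, p, dimnames = dimnames(means))
    counts[pos] <- rpois(sum(pos), lam[pos])
    structure(list(cells = cells, counts = counts, config = config),
              class = "sim_truth")
  })
}

#' Simulate split-pool barcoding of stained cells
#'
#' Assigns each cell a uniform-random well in ligation rounds 1 and 2 and a
#' PCR well in round 3; late-spike (`ht3_late_spike`) cells skip round 1 and
#' have no round-1 well. Every antibody molecule inherits its cell's well
#' path, then noise is applied per molecule: with probability `swap_rate`
#' the molecule adopts the full well path of a random other cell; each
#' ligation round succeeds with `ligation_success_prob` (failed molecules
#' lack that round's barcode and are unsequenceable); with probability
#' `blocking_failure_prob` a late-spike molecule illegitimately acquires a
#' random round-1 barcode. Each molecule receives a uniform-random UMI.
#'
#' @param truth a [simulate_cells()] result.
#' @param schema a [barcode_schema()]; well counts must match the config.
#' @param seed integer seed.
#' @return `sim_truth` augmented with well-path columns on `$cells`
#'   (`r1_well`, `r2_well`, `r3_well`, barcode strings, `cell_key`) and a
#'   `$molecules` data.table (molecule_id, cell_id, antibody, umi, r1, r2,
#'   r3, complete).
#' @export
simulate_splitpool <- function(truth, schema, seed = 1) {
  config <- truth$config
  stopifnot(identical(schema$wells_per_round, config$wells_per_round))
  wl <- schema$whitelists
  umi_len <- schema$segments_read2$length[schema$segments_read2$role == "umi"]
  with_seed(seed, {
    cells <- truth$cells
    n <- nrow(cells)
    w <- schema$wells_per_round
    cells$r1_well <- sample.int(w[1], n, replace = TRUE)
    cells$r1_well[cells$control_flag == "ht3_late_spike"] <- NA_integer_
    cells$r2_well <- sample.int(w[2], n, replace = TRUE)
    cells$r3_well <- sample.int(w[3], n, replace = TRUE)
    cells$r1 <- wl$round1[cells$r1_well]
    cells$r2 <- wl$round2[cells$r2_well]
    cells$r3 <- wl$round3[cells$r3_well]
    cells$cell_key <- ifelse(is.na(cells$r1), NA_character_,
                             paste(cells$r1, cells$r2, cells$r3, sep = "_"))

    nz <- which(truth$counts > 0, arr.ind = TRUE)
    cnt <- truth$counts[nz]
    cell_idx <- rep(nz[, 1], cnt)
    ab_idx <- rep(nz[, 2], cnt)
    nmol <- length(cell_idx)
    mol <- data.table::data.table(
      molecule_id = seq_len(nmol),
      cell_idx = cell_idx,
      antibody = config$panel$name[ab_idx]
    )
    # antibody dissociation/re-binding: adopt another cell's full well path
    if (config$swap_rate > 0 && n > 1) {
      sw <- which(runif(nmol) < config$swap_rate)
      if (length(sw)) {
        new_idx <- sample.int(n - 1L, length(sw), replace = TRUE)
        new_idx <- new_idx + (new_idx >= mol$cell_idx[sw])  # exclude self
        mol[sw, cell_idx := new_idx]
      }
    }
    mol[, `:=`(
      cell_id = cells$cell_id[cell_idx],
      r1 = cells$r1[cell_idx],
      r2 = cells$r2[cell_idx],
      r3 = cells$r3[cell_idx]
    )]
    is_late <- cells$control_flag[mol$cell_idx] == "ht3_late_spike"
    p_lig <- config$ligation_success_prob
    lig1 <- runif(nmol) < p_lig[1]
    lig2 <- runif(nmol) < p_lig[2]
    # blocking failure: late molecules pick up a stray round-1 barcode
    if (config$blocking_failure_prob > 0 && any(is_late)) {
      bf <- is_late & runif(nmol) < config$blocking_failure_prob
      if (any(bf)) {
        mol[bf, r1 := wl$round1[sample.int(w[1], sum(bf), replace = TRUE)]]
        lig1[bf] <- TRUE
      }
    }
    lig1[is_late & is.na(mol$r1)] <- FALSE
    mol[!lig1, r1 := NA_character_]
    mol[!lig2, r2 := NA_character_]
    mol[, umi := random_dna(nmol, umi_len)]
    mol[, complete := !is.na(r1) & !is.na(r2) & !is.na(r3)]
    mol[, cell_idx := NULL]
    truth$cells <- cells
    truth$molecules <- mol
    truth
  })
}

#' Render labeled molecules as paired-end FASTQ with ground truth
#'
#' Molecules with a complete barcode triple each yield a geometric number of
#' read pairs (mean `mean_reads_per_molecule`) sharing the molecule's UMI,
#' mimicking PCR duplication; incomplete molecules are dropped (they cannot
#' amplify). Read 1 carries `round3 + linker + round2 + linker + round1`
#' padded to the read length; read 2 carries `antibody barcode + UMI`
#' padded likewise. Substitution errors are applied i.i.d. per base.
#' Qualities are constant; read names link back to molecule ids.
#'
#' @param truth a [simulate_splitpool()] result.
#' @param schema the [barcode_schema()] used for barcoding.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return list of paths: `r1`, `r2` (gzip FASTQ), `cells`, `molecules`
#'   (truth TSVs), plus `n_reads`.
#' @export
simulate_reads <- function(truth, schema, out_dir, seed = 1) {
  config <- truth$config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mol <- truth$molecules[truth$molecules$complete]
  with_seed(seed, {
    mu <- config$mean_reads_per_molecule
    nread <- if (mu <= 1) rep(1L, nrow(mol)) else rgeom(nrow(mol), prob = 1 / mu) + 1L
    ridx <- rep(seq_len(nrow(mol)), nread)
    dup <- sequence(nread)
    name <- paste0("m", mol$molecule_id[ridx], ":", dup)
    stuffer1 <- strrep("A", schema$read1_length -
                         segments_span(schema$segments_read1))
    stuffer2 <- strrep("A", schema$read2_length -
                         segments_span(schema$segments_read2))
    ab_seq <- config$panel$sequence[match(mol$antibody, config$panel$name)]
    r1_seq <- paste0(mol$r3[ridx], schema$linker1, mol$r2[ridx],
                     schema$linker2, mol$r1[ridx], stuffer1)
    r2_seq <- paste0(ab_seq[ridx], mol$umi[ridx], stuffer2)
    r1_seq <- inject_errors(r1_seq, config$seq_error_rate)
    r2_seq <- inject_errors(r2_seq, config$seq_error_rate)

    r1_path <- file.path(out_dir, "reads_R1.fastq.gz")
    r2_path <- file.path(out_dir, "reads_R2.fastq.gz")
    write_fastq(r1_seq, name, r1_path)
    write_fastq(r2_seq, name, r2_path)

    cells_path <- file.path(out_dir, "cells.tsv")
    molecules_path <- file.path(out_dir, "molecules.tsv")
    write_tsv(truth$cells, cells_path)
    mol_out <- data.table::copy(mol)
    mol_out[, n_reads := nread]
    write_tsv(mol_out, molecules_path)
    list(r1 = r1_path, r2 = r2_path, cells = cells_path,
         molecules = molecules_path, n_reads = length(name))
  })
}

write_fastq <- function(seqs, names, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Run the full simulator: cells, split-pool, reads
#'
#' Convenience wrapper chaining [simulate_cells()], [simulate_splitpool()]
#' and [simulate_reads()] with stage-derived child seeds.
#'
#' @param config a [sim_config()].
#' @param schema a [barcode_schema()].
#' @param out_dir output directory.
#' @param seed global seed; stages use [derive_seed()] children.
#' @return list with `truth` (`sim_truth`) and `files` (paths from
#'   [simulate_reads()]).
#' @export
simulate_experiment <- function(config, schema, out_dir, seed = 1) {
  truth <- simulate_cells(config, derive_seed(seed, "cells"))
  truth <- simulate_splitpool(truth, schema, derive_seed(seed, "splitpool"))
  files <- simulate_reads(truth, schema, out_dir, derive_seed(seed, "reads"))
  list(truth = truth, files = files)
}
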