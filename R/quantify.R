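#' Centered log-ratio transform of antibody counts
#'
#' For each cell with counts `x`, the CLR score of antibody `i` is
#' `log((x_i + pseudocount) / g(x + pseudocount))` where `g` is the
#' geometric mean over the cell's antibodies, making scores comparable
#' across cells of different sequencing depth. Rows of the log form sum to
#' zero. `log = FALSE` gives the plain ratio-to-geometric-mean variant.
#'
#' @param counts cells-by-antibody matrix (sparse or dense, non-negative).
#' @param pseudocount added to every count before the ratio; must be
#'   positive when any count is zero.
#' @param log_base base of the logarithm (default natural).
#' @param log apply the logarithm (default `TRUE`).
#' @return dense numeric matrix of CLR scores with attributes
#'   `pseudocount`, `log_base`, `log`.
#' @examples
#' clr_transform(matrix(c(1, 1, 1, 8), nrow = 1), pseudocount = 0)
#' @export
clr_transform <- function(counts, pseudocount = 1, log_base = exp(1), log = TRUE) {
  x <- as.matrix(counts)
  if (any(x < 0)) stop("clr_transform(): counts must be non-negative")
  if (pseudocount <= 0 && any(x == 0)) {
    stop("clr_transform(): zero counts require a positive pseudocount")
  }
  lx <- base::log(x + pseudocount, base = log_base)
  ctr <- lx - rowMeans(lx)
  out <- if (log) ctr else log_base^ctr
  dimnames(out) <- dimnames(x)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "log_base") <- log_base
  attr(out, "log") <- log
  out
}

#' Expected barcode-collision fraction
#'
#' Probability that a given cell shares its three-part well-barcode
#' combination with at least one of the other `n - 1` cells when all `n`
#' cells are deposited uniformly at random among `m` combinations:
#' `1 - (1 - 1/m)^(n-1)` exactly, or the Poisson-process approximation
#' `1 - exp(-(n-1)/m)`. Keeping the occupancy `n/m` at a few percent keeps
#' this doublet rate correspondingly low.
#'
#' @param n number of cells.
#' @param m total barcode capacity (product of wells per round).
#' @param method `"exact"` or `"poisson"`.
#' @return collision fraction in `[0, 1]`.
#' @examples
#' expected_collision_fraction(17694, 96^3)
#' @export
expected_collision_fraction <- function(n, m, method = c("exact", "poisson")) {
  method <- match.arg(method)
  stopifnot(n >= 0, m >= 1)
  if (n <= 1) return(0)
  switch(method,
         exact = 1 - (1 - 1 / m)^(n - 1),
         poisson = 1 - exp(-(n - 1) / m))
}

#' Monte-Carlo estimate of the collision fraction
#'
#' Deposits `n` cells uniformly at random among `m` barcode-triple bins and
#' measures the fraction of cells whose bin holds two or more cells,
#' averaged over `reps` replicates.
#'
#' @inheritParams expected_collision_fraction
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return list with `mean`, `se` (standard error over replicates) and
#'   `replicates`.
#' @export
simulate_collision_fraction <- function(n, m, reps = 20, seed = 1) {
  with_seed(seed, {
    fr <- vapply(seq_len(reps), function(r) {
      bins <- sample.int(m, n, replace = TRUE)
      occ <- tabulate(bins, nbins = m)
      sum(occ[occ > 1]) / n
    }, numeric(1))
    list(mean = mean(fr), se = stats::sd(fr) / sqrt(reps), replicates = fr)
  })
}

#' Maximum cell loading for a target barcode occupancy
#'
#' The dilution rule: load at most `floor(target_occupancy * m)` cells so
#' that the cells profiled across all wells stay below the chosen fraction
#' of the total barcode capacity, keeping collision doublets rare.
#'
#' @param m total barcode capacity.
#' @param target_occupancy maximum occupancy fraction (e.g. 0.02).
#' @return integer maximum cell count.
#' @examples
#' max_loading(96^3, 0.02)  # 17694
#' @export
max_loading <- function(m, target_occupancy) {
  stopifnot(target_occupancy > 0, target_occupancy < 1)
  as.integer(floor(target_occupancy * m))
}

#' Two-class positivity split of one score vector
#'
#' Threshold-free positive/negative call: 2-means on the 1-D scores with
#' deterministic extreme-value initialisation (Lloyd); the cluster with the
#' higher centre is positive. Degenerate inputs (no spread) are all
#' negative.
#'
#' @param x numeric scores.
#' @return logical vector, with the implied `threshold` (midpoint between
#'   cluster centres) as an attribute.
#' @export
positivity_split <- function(x) {
  if (length(x) < 2 || diff(range(x)) < 1e-10) {
    out <- rep(FALSE, length(x))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  km <- kmeans(x, centers = matrix(range(x), ncol = 1),
               algorithm = "Lloyd", iter.max = 100)
  pos_cluster <- which.max(km$centers)
  out <- km$cluster == pos_cluster
  attr(out, "threshold") <- mean(km$centers)
  out
}

#' Assign cells to samples by decoding hashtag combinations
#'
#' Calls each hashtag positive/negative per cell (2-means on that
#' hashtag's CLR scores by default, or a fixed CLR threshold) and matches
#' the positive set against the sample code: an exact match assigns the
#' sample; a set containing two or more full codes is `multi_sample`
#' (ambiguous, e.g. doublets); anything else is `undetermined`.
#'
#' @param clr CLR matrix from [clr_transform()] (cells x antibodies).
#' @param code a [build_hashtag_code()].
#' @param method `"kmeans"` (per-hashtag 2-means) or `"threshold"`.
#' @param threshold fixed CLR positivity threshold for
#'   `method = "threshold"`.
#' @return data.frame with `cell` and `label` (sample id,
#'   `"undetermined"`, or `"multi_sample"`); the logical positivity matrix
#'   is attached as attribute `positivity`.
#' @export
assign_samples <- function(clr, code, method = c("kmeans", "threshold"),
                           threshold = NULL) {
  method <- match.arg(method)
  hts <- code$hashtags
  missing_ht <- setdiff(hts, colnames(clr))
  if (length(missing_ht)) {
    stop("assign_samples(): hashtags absent from matrix: ",
         paste(missing_ht, collapse = ", "))
  }
  n <- nrow(clr)
  pos <- matrix(FALSE, n, length(hts), dimnames = list(rownames(clr), hts))
  for (h in hts) {
    pos[, h] <- if (method == "kmeans") {
      as.logical(positivity_split(clr[, h]))
    } else {
      if (is.null(threshold)) stop("assign_samples(): threshold method needs a threshold")
      clr[, h] > threshold
    }
  }
  code_keys <- vapply(code$samples, subset_key, character(1))
  sig <- apply(pos, 1, function(p) subset_key(hts[p]))
  label <- names(code$samples)[match(sig, code_keys)]
  unresolved <- which(is.na(label))
  if (length(unresolved)) {
    contains <- vapply(code$samples, function(s) {
      rowSums(pos[unresolved, s, drop = FALSE]) == length(s)
    }, logical(length(unresolved)))
    if (is.null(dim(contains))) contains <- matrix(contains, nrow = 1)
    n_codes <- rowSums(contains)
    label[unresolved] <- ifelse(n_codes >= 2, "multi_sample", "undetermined")
  }
  out <- data.frame(cell = rownames(clr) %||% seq_len(n), label = label,
                    stringsAsFactors = FALSE)
  attr(out, "positivity") <- pos
  out
}

#' Look up simulator truth flags for called cells
#'
#' Matches called barcode-triple keys back to the simulated cells. Keys
#' colliding between a control and a regular cell inherit the control flag
#' (conservative for control accounting). Late-spike cells have no round-1
#' barcode and hence no full key; a called key matching no truth cell is
#' attributed to `ht3_late_spike` when its round-2/round-3 pair belongs to
#' a late-spike cell (the signature of a molecule that illegitimately
#' acquired a round-1 barcode), and `"none"` otherwise.
#'
#' @param cell_keys character vector of called `r1_r2_r3` keys.
#' @param truth_cells the simulator `cells` table (needs `cell_key`,
#'   `control_flag` and the `r2`/`r3` barcode columns).
#' @return character vector of flags aligned with `cell_keys`.
#' @export
truth_flags_for_cells <- function(cell_keys, truth_cells) {
  tc <- truth_cells[!is.na(truth_cells$cell_key), ]
  flag <- tc$control_flag[match(cell_keys, tc$cell_key)]
  # match() takes the first occurrence; re-scan for control collisions
  ctrl <- tc[tc$control_flag != "none", ]
  hit <- match(cell_keys, ctrl$cell_key)
  flag[!is.na(hit)] <- ctrl$control_flag[hit[!is.na(hit)]]
  # unmatched keys: blocking-failure fragments of late-spike cells carry
  # that cell's round-2/round-3 wells under an arbitrary round-1 barcode
  late <- truth_cells[truth_cells$control_flag == "ht3_late_spike", ]
  if (nrow(late) && anyNA(flag) && !is.null(late$r2)) {
    suffix <- sub("^[^_]*_", "", cell_keys)
    late_suffix <- paste(late$r2, late$r3, sep = "_")
    idx <- is.na(flag) & suffix %in% late_suffix
    flag[idx] <- "ht3_late_spike"
  }
  flag[is.na(flag)] <- "none"
  flag
}

#' Spike-in control quality report
#'
#' Quantifies the three control readouts of the split-pool design:
#' (a) how many called cells trace back to late-spike (`ht3_late_spike`)
#' controls — any nonzero count means splint blocking failed; (b) marker
#' signal on hashtag-only (`ht2_only`) cells relative to ordinary cells —
#' leakage measures antibody swapping / barcode hopping; (c) the
#' isotype-control score distribution, a gauge of non-specific staining.
#'
#' @param counts cells-by-antibody count matrix (called cells).
#' @param flags per-cell control flags aligned with `rownames(counts)`
#'   (from [truth_flags_for_cells()] in simulation, or a hashtag-only
#'   signature on real data).
#' @param panel an [antibody_panel()] (classes pick the marker and isotype
#'   columns).
#' @param pseudocount CLR pseudocount.
#' @param ledger optional demux discard ledger to echo into the report.
#' @return object of class `qc_report`: list with `n_cells`,
#'   `n_ht2_called`, `n_ht3_called`, `ht2_marker_clr`, `other_marker_clr`,
#'   `ht2_marker_leakage` (difference), `isotype_summary`, `ledger`.
#' @export
control_qc <- function(counts, flags, panel, pseudocount = 1, ledger = NULL) {
  stopifnot(length(flags) == nrow(counts))
  clr <- clr_transform(counts, pseudocount = pseudocount)
  markers <- intersect(panel_names_of_class(panel, "marker"), colnames(clr))
  isotypes <- intersect(panel_names_of_class(panel, "isotype_control"), colnames(clr))
  ht2 <- flags == "ht2_only"
  other <- flags == "none"
  ht2_marker <- if (any(ht2) && length(markers)) mean(clr[ht2, markers]) else NA_real_
  other_marker <- if (any(other) && length(markers)) mean(clr[other, markers]) else NA_real_
  iso_summary <- if (length(isotypes)) {
    iso <- as.vector(clr[, isotypes])
    c(mean = mean(iso), sd = stats::sd(iso),
      q95 = unname(stats::quantile(iso, 0.95)))
  } else c(mean = NA_real_, sd = NA_real_, q95 = NA_real_)
  structure(list(
    n_cells = nrow(counts),
    n_ht2_called = sum(ht2),
    n_ht3_called = sum(flags == "ht3_late_spike"),
    ht2_fraction = if (nrow(counts)) sum(ht2) / nrow(counts) else NA_real_,
    ht2_marker_clr = ht2_marker,
    other_marker_clr = other_marker,
    ht2_marker_leakage = ht2_marker - other_marker,
    isotype_summary = iso_summary,
    ledger = ledger
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:\n")
  cat(sprintf("  called cells: %d\n", x$n_cells))
  cat(sprintf("  hashtag-only (HT2) controls called: %d (%.2f%%)\n",
              x$n_ht2_called, 100 * x$ht2_fraction))
  cat(sprintf("  late-spike (HT3) cells called: %d%s\n", x$n_ht3_called,
              if (x$n_ht3_called == 0) " (blocking intact)" else " (blocking failure!)"))
  cat(sprintf("  marker CLR on HT2 controls vs others: %.3f vs %.3f (leakage %.3f)\n",
              x$ht2_marker_clr, x$other_marker_clr, x$ht2_marker_leakage))
  cat(sprintf("  isotype CLR: mean %.3f, sd %.3f, q95 %.3f\n",
              x$isotype_summary["mean"], x$isotype_summary["sd"],
              x$isotype_summary["q95"]))
  invisible(x)
}

qc_report_table <- function(x) {
  data.frame(
    metric = c("n_cells", "n_ht2_called", "n_ht3_called", "ht2_fraction",
               "ht2_marker_clr", "other_marker_clr", "ht2_marker_leakage",
               "isotype_mean", "isotype_sd", "isotype_q95"),
    value = c(x$n_cells, x$n_ht2_called, x$n_ht3_called, x$ht2_fraction,
              x$ht2_marker_clr, x$other_marker_clr, x$ht2_marker_leakage,
              unname(x$isotype_summary)),
    stringsAsFactors = FALSE
  )
}
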