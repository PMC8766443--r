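#' Parse raw read pairs into barcode fields
#'
#' Slices each read at the schema's segment offsets without any error
#' correction. Reads shorter than the last segment end on either mate are
#' rejected with reason `"truncated"`.
#'
#' @param r1,r2 character vectors of read-1 / read-2 sequences (paired by
#'   position).
#' @param schema a [barcode_schema()].
#' @return data.frame with columns `read` (index), `r1_bc`, `r2_bc`,
#'   `r3_bc`, `antibody_bc`, `umi`, `keep` (logical) and `reason`
#'   (`NA` or `"truncated"`).
#' @export
parse_read_pairs <- function(r1, r2, schema) {
  stopifnot(length(r1) == length(r2))
  span1 <- segments_span(schema$segments_read1)
  span2 <- segments_span(schema$segments_read2)
  ok <- nchar(r1) >= span1 & nchar(r2) >= span2
  seg1 <- schema$segments_read1
  seg2 <- schema$segments_read2
  cut1 <- function(role) {
    i <- which(seg1$role == role)
    substr(r1, seg1$offset[i], segment_end(seg1)[i])
  }
  cut2 <- function(role) {
    i <- which(seg2$role == role)
    substr(r2, seg2$offset[i], segment_end(seg2)[i])
  }
  out <- data.frame(
    read = seq_along(r1),
    r1_bc = cut1("round1_well"),
    r2_bc = cut1("round2_well"),
    r3_bc = cut1("round3_pcr"),
    antibody_bc = cut2("antibody_barcode"),
    umi = cut2("umi"),
    keep = ok,
    reason = ifelse(ok, NA_character_, "truncated"),
    stringsAsFactors = FALSE
  )
  out[!ok, c("r1_bc", "r2_bc", "r3_bc", "antibody_bc", "umi")] <- NA_character_
  out
}

#' Correct one observed barcode against a whitelist
#'
#' Returns the unique whitelist entry within Hamming distance
#' `max_mismatch`; rejects (returns `NA`) when no entry is close enough or
#' when two or more entries tie at the minimum distance within the radius
#' (ties are never broken arbitrarily). `N` bases count as mismatches.
#'
#' @param observed a single observed barcode string.
#' @param whitelist character vector of equal-length whitelist entries.
#' @param max_mismatch correction radius.
#' @return the corrected barcode, or `NA_character_` on rejection.
#' @examples
#' correct_barcode("AAAT", c("AAAA", "TTTT"), 1)  # "AAAA"
#' correct_barcode("AATT", c("AAAA", "TTTT"), 1)  # rejected: NA
#' @export
correct_barcode <- function(observed, whitelist, max_mismatch = 1) {
  if (nchar(observed) != nchar(whitelist[1])) {
    stop("correct_barcode(): observed length does not match whitelist length")
  }
  correct_barcodes(observed, whitelist, max_mismatch)
}

#' Correct a vector of observed barcodes against a whitelist
#'
#' Vectorised version of [correct_barcode()]: exact matches are resolved by
#' hashing; only the unique non-matching strings pay the Hamming scan.
#'
#' @inheritParams correct_barcode
#' @param observed character vector of observed barcodes.
#' @return character vector: corrected entries, `NA` where rejected.
#' @export
correct_barcodes <- function(observed, whitelist, max_mismatch = 1) {
  hit <- match(observed, whitelist)
  res <- whitelist[hit]
  miss <- which(is.na(hit) & !is.na(observed))
  if (length(miss) && max_mismatch >= 1) {
    uo <- unique(observed[miss])
    wl_m <- seq_char_matrix(whitelist)
    corr <- vapply(uo, function(o) {
      if (nchar(o) != nrow(wl_m)) return(NA_character_)
      d <- hamming_to_matrix(o, wl_m)
      dm <- min(d)
      if (dm <= max_mismatch && sum(d == dm) == 1L) whitelist[which.min(d)]
      else NA_character_
    }, character(1), USE.NAMES = FALSE)
    res[miss] <- corr[match(observed[miss], uo)]
  }
  res
}

#' Collapse a UMI multiset to a molecule count
#'
#' `exact` counts distinct UMI strings. `directional` merges UMI `B` into
#' UMI `A` when `Hamming(A, B) <= umi_mismatch` and
#' `count(A) >= 2 * count(B) - 1`, then counts the connected components of
#' the merge graph — absorbing PCR/sequencing-error satellites of abundant
#' UMIs without joining genuinely distinct molecules of similar abundance.
#'
#' @param umis character vector of observed UMIs, one per read (duplicates
#'   encode read multiplicity).
#' @param method `"directional"` (default) or `"exact"`.
#' @param umi_mismatch maximum Hamming distance for a directional merge.
#' @return integer molecule count.
#' @examples
#' collapse_umis(c(rep("AAAA", 5), "AAAT"), "directional")  # 1
#' collapse_umis(c(rep("AAAA", 5), "AAAT"), "exact")        # 2
#' @export
collapse_umis <- function(umis, method = c("directional", "exact"),
                          umi_mismatch = 1) {
  method <- match.arg(method)
  if (length(umis) == 0) return(0L)
  tab <- table(umis)
  u <- names(tab)
  k <- length(u)
  if (method == "exact" || k == 1) return(k)
  cnt <- as.integer(tab)
  m <- seq_char_matrix(u)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(k - 1)) {
    d <- colSums(m[, (i + 1):k, drop = FALSE] != m[, i])
    for (jj in which(d <= umi_mismatch)) {
      j <- i + jj
      hi <- max(cnt[i], cnt[j]); lo <- min(cnt[i], cnt[j])
      if (hi >= 2L * lo - 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

# Directional/exact collapse over many (group, umi) records at once.
# dt: data.table with columns gid, umi. Returns data.table(gid, count).
# Fast path for umi_mismatch == 1 uses the masked-key neighbour trick:
# two UMIs at Hamming distance exactly 1 share a masked key at the
# differing position.
collapse_umis_grouped <- function(dt, method = "directional", umi_mismatch = 1) {
  per_umi <- dt[, .(reads = .N), by = .(gid, umi)]
  if (method == "exact" || umi_mismatch < 1) {
    return(per_umi[, .(count = .N), by = gid])
  }
  if (umi_mismatch != 1) {
    # generic fallback: reference implementation per group
    return(dt[, .(count = collapse_umis(umi, method, umi_mismatch)), by = gid])
  }
  per_umi[, uid := .I]
  L <- nchar(per_umi$umi[1])
  pairs_list <- vector("list", L)
  for (p in seq_len(L)) {
    masked <- paste0(substr(per_umi$umi, 1, p - 1), ".",
                     substr(per_umi$umi, p + 1, L))
    mk <- data.table::data.table(gid = per_umi$gid, masked = masked,
                                 uid = per_umi$uid, reads = per_umi$reads)
    mk <- mk[mk[, .N, by = .(gid, masked)][N > 1], on = c("gid", "masked")]
    if (nrow(mk)) {
      pr <- merge(mk, mk, by = c("gid", "masked"), allow.cartesian = TRUE)
      pr <- pr[uid.x < uid.y]
      pairs_list[[p]] <- pr[, .(gid, uid.x, uid.y, reads.x, reads.y)]
    }
  }
  pairs <- data.table::rbindlist(pairs_list)
  counts <- per_umi[, .(count = .N), by = gid]
  if (nrow(pairs)) {
    pairs <- unique(pairs, by = c("uid.x", "uid.y"))
    hi <- pmax(pairs$reads.x, pairs$reads.y)
    lo <- pmin(pairs$reads.x, pairs$reads.y)
    pairs <- pairs[hi >= 2L * lo - 1L]
    if (nrow(pairs)) {
      n_u <- nrow(per_umi)
      parent <- seq_len(n_u)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (r in seq_len(nrow(pairs))) {
        ri <- find(pairs$uid.x[r]); rj <- find(pairs$uid.y[r])
        if (ri != rj) parent[ri] <- rj
      }
      per_umi[, comp := vapply(uid, find, integer(1))]
      counts <- per_umi[, .(count = data.table::uniqueN(comp)), by = gid]
    }
  }
  counts
}

#' Group corrected reads into called cells
#'
#' Groups reads by their corrected barcode triple (one candidate cell per
#' distinct triple), collapses UMIs per (cell, antibody), and drops triples
#' whose total UMI count falls below `min_umi`. Reads failing any
#' correction are tallied in a discard ledger by first failing stage.
#'
#' @param records data.frame from [parse_read_pairs()] with corrected
#'   columns `r1`, `r2`, `r3`, `antibody` (NA = rejected) and `umi`.
#' @param min_umi minimum total UMIs for a triple to be called a cell
#'   (default 10); `0` disables the filter.
#' @param collapse UMI collapse method, `"directional"` or `"exact"`.
#' @param umi_mismatch Hamming radius for directional collapse.
#' @return object of class `cell_calls`: data.table with columns
#'   `cell_key`, `r1`, `r2`, `r3`, `antibody`, `reads`, `umis`, with
#'   attributes `ledger` (data.frame reason/n) and `params`.
#' @export
call_cells <- function(records, min_umi = 10, collapse = c("directional", "exact"),
                       umi_mismatch = 1) {
  collapse <- match.arg(collapse)
  n_total <- nrow(records)
  reason <- rep(NA_character_, n_total)
  if (!is.null(records$reason)) reason <- records$reason
  for (stage in c("r1", "r2", "r3", "antibody")) {
    bad <- is.na(reason) & is.na(records[[stage]])
    reason[bad] <- paste0(stage, "_uncorrected")
  }
  ok <- is.na(reason)
  ledger_tab <- table(factor(reason[!ok]))
  dt <- data.table::as.data.table(records[ok, c("r1", "r2", "r3", "antibody", "umi")])
  if (nrow(dt)) {
    dt[, cell_key := paste(r1, r2, r3, sep = "_")]
    dt[, gid := .GRP, by = .(cell_key, antibody)]
    counts <- collapse_umis_grouped(dt[, .(gid, umi)], collapse, umi_mismatch)
    calls <- dt[, .(reads = .N, r1 = r1[1], r2 = r2[1], r3 = r3[1]),
                by = .(cell_key, antibody, gid)]
    calls <- merge(calls, counts, by = "gid")
    data.table::setnames(calls, "count", "umis")
    calls[, gid := NULL]
    totals <- calls[, .(total = sum(umis)), by = cell_key]
    kept_keys <- totals[total >= min_umi, cell_key]
    dropped_cells <- nrow(totals) - length(kept_keys)
    calls <- calls[cell_key %in% kept_keys]
  } else {
    calls <- data.table::data.table(cell_key = character(0), antibody = character(0),
                                    gid = integer(0), reads = integer(0),
                                    r1 = character(0), r2 = character(0),
                                    r3 = character(0), umis = integer(0))
    calls[, gid := NULL]
    dropped_cells <- 0L
  }
  ledger <- data.frame(
    reason = c("input", "assigned", names(ledger_tab)),
    n = c(n_total, sum(ok), as.integer(ledger_tab)),
    stringsAsFactors = FALSE
  )
  data.table::setcolorder(calls, c("cell_key", "r1", "r2", "r3",
                                   "antibody", "reads", "umis"))
  structure(calls,
            class = c("cell_calls", class(calls)),
            ledger = ledger,
            dropped_low_umi_cells = dropped_cells,
            params = list(min_umi = min_umi, collapse = collapse,
                          umi_mismatch = umi_mismatch))
}

#' Assemble a sparse cells-by-antibody count matrix from cell calls
#'
#' @param calls a [call_cells()] result.
#' @param panel an [antibody_panel()]; fixes the column set and order.
#' @return sparse `dgCMatrix` (cells x antibodies) of UMI counts, with the
#'   call ledger attached as attribute `ledger`.
#' @export
count_matrix <- function(calls, panel) {
  keys <- sort(unique(calls$cell_key))
  i <- match(calls$cell_key, keys)
  j <- match(calls$antibody, panel$name)
  if (anyNA(j)) stop("count_matrix(): calls contain antibodies absent from the panel")
  m <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(calls$umis),
                            dims = c(length(keys), nrow(panel)),
                            dimnames = list(keys, panel$name))
  attr(m, "ledger") <- attr(calls, "ledger")
  m
}

#' Write / read a count matrix as a MatrixMarket triplet directory
#'
#' Writes `matrix.mtx` plus `barcodes.tsv` (the barcode-triple cell keys)
#' and `features.tsv` (antibody name and class), the conventional exchange
#' layout for cell-by-feature count matrices.
#'
#' @param m sparse or dense cells-by-antibody matrix.
#' @param dir output directory (created if needed).
#' @param panel an [antibody_panel()] supplying feature classes.
#' @return `write_count_matrix`: the directory, invisibly.
#'   `read_count_matrix`: a `dgCMatrix` with dimnames restored.
#' @export
write_count_matrix <- function(m, dir, panel) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m) %||% character(0), file.path(dir, "barcodes.tsv"))
  feat <- data.frame(name = colnames(m),
                     class = panel$class[match(colnames(m), panel$name)],
                     stringsAsFactors = FALSE)
  write_tsv(feat, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  # keep the general (non-symmetric) representation so dimnames are free
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  rn <- readLines(file.path(dir, "barcodes.tsv"))
  feat <- read_tsv(file.path(dir, "features.tsv"))
  dimnames(m) <- list(rn, feat$name)
  m
}

#' Demultiplex a paired-end FASTQ run into a cell-by-antibody count matrix
#'
#' Full demultiplexing pass: read the FASTQ pair, slice barcode segments,
#' error-correct the three well barcodes and the antibody barcode against
#' their whitelists, group reads by barcode triple, collapse UMIs, filter
#' low-UMI triples, and assemble the sparse count matrix.
#'
#' @param r1_path,r2_path gzip FASTQ paths (synchronised pairs).
#' @param schema a [barcode_schema()].
#' @param panel an [antibody_panel()].
#' @param min_umi minimum total UMIs per called cell (default 10).
#' @param collapse UMI collapse method.
#' @param umi_mismatch Hamming radius for directional collapse.
#' @param max_mismatch correction radius override (default: the schema's).
#' @return list with `counts` (sparse matrix), `calls` (the [call_cells()]
#'   table) and `ledger`.
#' @export
demux_fastq <- function(r1_path, r2_path, schema, panel,
                        min_umi = 10, collapse = "directional",
                        umi_mismatch = 1, max_mismatch = NULL) {
  radius <- max_mismatch %||% schema$correction_radius
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  rec <- parse_read_pairs(unname(r1), unname(r2), schema)
  rec$r1 <- correct_barcodes(rec$r1_bc, schema$whitelists$round1, radius)
  rec$r2 <- correct_barcodes(rec$r2_bc, schema$whitelists$round2, radius)
  rec$r3 <- correct_barcodes(rec$r3_bc, schema$whitelists$round3, radius)
  rec$antibody_seq <- correct_barcodes(rec$antibody_bc, panel$sequence, radius)
  rec$antibody <- panel$name[match(rec$antibody_seq, panel$sequence)]
  calls <- call_cells(rec, min_umi = min_umi, collapse = collapse,
                      umi_mismatch = umi_mismatch)
  counts <- count_matrix(calls, panel)
  list(counts = counts, calls = calls, ledger = attr(calls, "ledger"))
}
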