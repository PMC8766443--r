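#' Barcode read-layout schema
#'
#' Describes how a split-pool antibody-tag library is laid out on a read
#' pair: read 1 carries the three well barcodes (PCR round first, then the
#' second and first ligation rounds, separated by fixed linkers), read 2
#' carries the antibody barcode followed by the UMI. The schema also holds
#' the per-round well-barcode whitelists and the error-correction radius.
#'
#' @param well_barcode_length length (nt) of each well barcode.
#' @param antibody_barcode_length length (nt) of the antibody barcode.
#' @param umi_length length (nt) of the unique molecular identifier.
#' @param wells_per_round integer vector of length 3: wells used in ligation
#'   round 1, ligation round 2, and the PCR round.
#' @param read1_length,read2_length sequenced read lengths (nt).
#' @param linker1,linker2 fixed linker sequences between well-barcode
#'   segments on read 1.
#' @param whitelists optional named list (`round1`, `round2`, `round3`) of
#'   well-barcode whitelists; generated by rejection sampling at minimum
#'   pairwise Hamming distance 3 when `NULL`.
#' @param correction_radius maximum number of mismatches corrected per
#'   barcode segment during demultiplexing.
#' @param seed seed used when whitelists are generated internally.
#' @return An object of class `barcode_schema`.
#' @examples
#' sch <- barcode_schema(wells_per_round = c(8, 8, 8))
#' validate_schema(sch)
#' @export
barcode_schema <- function(well_barcode_length = 8,
                           antibody_barcode_length = 15,
                           umi_length = 10,
                           wells_per_round = c(96, 96, 96),
                           read1_length = 100,
                           read2_length = 50,
                           linker1 = "CAGTGC",
                           linker2 = "GTCAGA",
                           whitelists = NULL,
                           correction_radius = 1,
                           seed = 1) {
  stopifnot(length(wells_per_round) == 3, all(wells_per_round >= 1))
  wells_per_round <- as.integer(wells_per_round)
  if (is.null(whitelists)) {
    whitelists <- list(
      round1 = generate_whitelist(wells_per_round[1], well_barcode_length,
                                  seed = derive_seed(seed, "whitelist_round1")),
      round2 = generate_whitelist(wells_per_round[2], well_barcode_length,
                                  seed = derive_seed(seed, "whitelist_round2")),
      round3 = generate_whitelist(wells_per_round[3], well_barcode_length,
                                  seed = derive_seed(seed, "whitelist_round3"))
    )
  }
  bl <- well_barcode_length
  l1 <- nchar(linker1); l2 <- nchar(linker2)
  segments_read1 <- data.frame(
    role = c("round3_pcr", "linker", "round2_well", "linker", "round1_well"),
    offset = cumsum(c(1, bl, l1, bl, l2)),
    length = c(bl, l1, bl, l2, bl),
    stringsAsFactors = FALSE
  )
  segments_read2 <- data.frame(
    role = c("antibody_barcode", "umi"),
    offset = c(1, 1 + antibody_barcode_length),
    length = c(antibody_barcode_length, umi_length),
    stringsAsFactors = FALSE
  )
  structure(list(
    read1_length = as.integer(read1_length),
    read2_length = as.integer(read2_length),
    segments_read1 = segments_read1,
    segments_read2 = segments_read2,
    linker1 = linker1,
    linker2 = linker2,
    wells_per_round = wells_per_round,
    whitelists = whitelists,
    correction_radius = as.integer(correction_radius)
  ), class = "barcode_schema")
}

#' @export
print.barcode_schema <- function(x, ...) {
  cat("barcode_schema:",
      sprintf("R1 %dnt / R2 %dnt;", x$read1_length, x$read2_length),
      sprintf("wells %s;", paste(x$wells_per_round, collapse = "x")),
      sprintf("capacity %d triples\n", prod(x$wells_per_round)))
  cat("  read1 segments:",
      paste(sprintf("%s[%d+%d]", x$segments_read1$role,
                    x$segments_read1$offset, x$segments_read1$length),
            collapse = " "), "\n")
  cat("  read2 segments:",
      paste(sprintf("%s[%d+%d]", x$segments_read2$role,
                    x$segments_read2$offset, x$segments_read2$length),
            collapse = " "), "\n")
  invisible(x)
}

segment_end <- function(seg) seg$offset + seg$length - 1L

# span (last base needed) of a segment table
segments_span <- function(seg) max(segment_end(seg))

#' Validate a barcode schema
#'
#' Checks that segments are disjoint and fit inside the read lengths, that
#' whitelists are duplicate-free sets of correct-length DNA strings, and
#' that whitelist sizes match `wells_per_round`. Validation is report-based:
#' an empty character vector means the schema is usable.
#'
#' @param schema a [barcode_schema()].
#' @return character vector of violation messages (length 0 when valid).
#' @export
validate_schema <- function(schema) {
  v <- character(0)
  check_segments <- function(seg, read_len, read_name) {
    out <- character(0)
    ends <- segment_end(seg)
    for (i in seq_len(nrow(seg))) {
      if (seg$offset[i] < 1 || ends[i] > read_len) {
        out <- c(out, sprintf("segment exceeds read length: %s %s [%d..%d] on %d-nt read",
                              read_name, seg$role[i], seg$offset[i], ends[i], read_len))
      }
    }
    if (nrow(seg) > 1) {
      o <- order(seg$offset)
      for (i in seq_len(nrow(seg) - 1)) {
        a <- o[i]; b <- o[i + 1]
        if (ends[a] >= seg$offset[b]) {
          out <- c(out, sprintf("overlapping segments: %s %s and %s",
                                read_name, seg$role[a], seg$role[b]))
        }
      }
    }
    out
  }
  v <- c(v, check_segments(schema$segments_read1, schema$read1_length, "read1"))
  v <- c(v, check_segments(schema$segments_read2, schema$read2_length, "read2"))
  bl <- schema$segments_read1$length[schema$segments_read1$role == "round1_well"][1]
  for (r in c("round1", "round2", "round3")) {
    wl <- schema$whitelists[[r]]
    if (is.null(wl)) { v <- c(v, sprintf("missing whitelist: %s", r)); next }
    if (anyDuplicated(wl)) v <- c(v, sprintf("duplicate whitelist entry: %s", r))
    if (any(nchar(wl) != bl)) {
      v <- c(v, sprintf("whitelist entry length mismatch: %s (expected %d nt)", r, bl))
    }
    if (any(grepl("[^ACGT]", wl))) {
      v <- c(v, sprintf("whitelist alphabet outside {A,C,G,T}: %s", r))
    }
  }
  sizes <- vapply(schema$whitelists[c("round1", "round2", "round3")], length, integer(1))
  if (!all(is.na(sizes)) && any(sizes != schema$wells_per_round)) {
    v <- c(v, "whitelist sizes do not match wells_per_round")
  }
  v
}

#' Minimum pairwise Hamming distance of a whitelist
#'
#' A whitelist supports unambiguous correction at radius `r` iff its minimum
#' pairwise Hamming distance is at least `2r + 1`.
#'
#' @param whitelist character vector of at least two equal-length DNA strings.
#' @return integer minimum over all pairs.
#' @examples
#' min_pairwise_hamming(c("AAAA", "AATT", "TTTT"))
#' @export
min_pairwise_hamming <- function(whitelist) {
  whitelist <- unique(whitelist)
  n <- length(whitelist)
  if (n < 2) stop("min_pairwise_hamming(): need at least 2 distinct entries")
  if (length(unique(nchar(whitelist))) != 1) {
    stop("min_pairwise_hamming(): entries must have equal length")
  }
  m <- seq_char_matrix(whitelist)
  best <- nchar(whitelist[1])
  for (i in seq_len(n - 1)) {
    d <- colSums(m[, (i + 1):n, drop = FALSE] != m[, i])
    best <- min(best, d)
    if (best == 0) break
  }
  as.integer(best)
}

#' Generate a barcode whitelist by rejection sampling
#'
#' Draws random sequences and keeps those at Hamming distance at least
#' `min_dist` from every accepted sequence, so single-substitution
#' correction is unambiguous at the default `min_dist = 3`.
#'
#' @param n number of barcodes.
#' @param length barcode length (nt).
#' @param min_dist minimum pairwise Hamming distance to enforce.
#' @param seed optional seed (local to this call).
#' @param max_tries candidate draws before giving up.
#' @return character vector of `n` barcodes.
#' @export
generate_whitelist <- function(n, length, min_dist = 3, seed = NULL,
                               max_tries = 1000 * n) {
  with_seed(seed, {
    accepted <- character(0)
    acc_m <- NULL
    tries <- 0
    while (length(accepted) < n) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop(sprintf("generate_whitelist(): could not place %d barcodes of length %d at distance >= %d",
                     n, length, min_dist))
      }
      cand <- random_dna(1, length)
      if (is.null(acc_m) ||
          min(hamming_to_matrix(cand, acc_m)) >= min_dist) {
        accepted <- c(accepted, cand)
        acc_m <- seq_char_matrix(accepted)
      }
    }
    accepted
  })
}

#' Read / write whitelists (one sequence per line)
#' @param path file path.
#' @return `read_whitelist` returns a character vector.
#' @export
read_whitelist <- function(path) readLines(path)

#' @rdname read_whitelist
#' @param whitelist character vector of barcodes.
#' @export
write_whitelist <- function(whitelist, path) {
  writeLines(whitelist, path)
  invisible(path)
}

#' Antibody panel
#'
#' A panel maps antibody names to their DNA barcodes and functional class:
#' `marker` (antigen-specific), `hashtag` (sample/batch label against
#' ubiquitous surface proteins) or `isotype_control` (non-binding control).
#' Barcode sequences are generated at minimum pairwise Hamming distance 3
#' when not supplied.
#'
#' @param name character vector of antibody names.
#' @param class character vector of classes, recycled; one of `marker`,
#'   `hashtag`, `isotype_control`.
#' @param sequence optional character vector of barcode sequences.
#' @param barcode_length barcode length used when sequences are generated.
#' @param seed seed for barcode generation.
#' @return data.frame of class `antibody_panel` with columns
#'   `name`, `sequence`, `class`.
#' @export
antibody_panel <- function(name, class = "marker", sequence = NULL,
                           barcode_length = 15, seed = 1) {
  if (anyDuplicated(name)) stop("antibody_panel(): antibody names must be unique")
  class <- rep_len(class, length(name))
  bad <- setdiff(class, c("marker", "hashtag", "isotype_control"))
  if (length(bad)) stop("antibody_panel(): unknown class: ", paste(bad, collapse = ", "))
  if (is.null(sequence)) {
    sequence <- generate_whitelist(length(name), barcode_length,
                                   seed = derive_seed(seed, "antibody_panel"))
  }
  if (anyDuplicated(sequence)) stop("antibody_panel(): barcode sequences must be unique")
  structure(data.frame(name = name, sequence = sequence, class = class,
                       stringsAsFactors = FALSE),
            class = c("antibody_panel", "data.frame"))
}

#' @rdname antibody_panel
#' @param path TSV path with columns name, sequence, class.
#' @export
read_antibody_panel <- function(path) {
  df <- read_tsv(path)
  antibody_panel(df$name, df$class, df$sequence)
}

#' @rdname antibody_panel
#' @param panel an `antibody_panel`.
#' @export
write_antibody_panel <- function(panel, path) {
  write_tsv(as.data.frame(panel)[, c("name", "sequence", "class")], path)
}

panel_names_of_class <- function(panel, cls) panel$name[panel$class %in% cls]

#' Combinatorial hashtag sample code
#'
#' Assigns each sample a distinct non-empty subset of the hashtag
#' antibodies, enumerated deterministically: singletons in hashtag order,
#' then pairs in lexicographic index order, then triples, and so on. With
#' four hashtags up to 15 samples can be coded; ten samples use the four
#' singletons and the six pairs.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param hashtag_names character vector of hashtag antibody names.
#' @return object of class `hashtag_code`: list with `samples` (named list
#'   sample -> hashtag subset) and `hashtags`.
#' @examples
#' code <- build_hashtag_code(paste0("patient", 1:10), paste0("HT-", LETTERS[1:4]))
#' decode_hashtags(code, code$samples[["patient7"]])
#' @export
build_hashtag_code <- function(sample_ids, hashtag_names) {
  stopifnot(!anyDuplicated(sample_ids), !anyDuplicated(hashtag_names))
  h <- length(hashtag_names)
  capacity <- 2^h - 1
  if (length(sample_ids) > capacity) {
    stop(sprintf("build_hashtag_code(): %d samples exceed the %d non-empty subsets of %d hashtags",
                 length(sample_ids), capacity, h))
  }
  subsets <- list()
  for (size in seq_len(h)) {
    cmb <- utils::combn(h, size)
    for (j in seq_len(ncol(cmb))) subsets[[length(subsets) + 1]] <- hashtag_names[cmb[, j]]
  }
  samples <- subsets[seq_along(sample_ids)]
  names(samples) <- sample_ids
  structure(list(samples = samples, hashtags = hashtag_names),
            class = "hashtag_code")
}

subset_key <- function(x) paste(sort(x), collapse = "+")

#' Decode a hashtag subset back to its sample
#' @param code a [build_hashtag_code()] object.
#' @param hashtags character vector: the positive hashtag set of a cell.
#' @return the sample id, or `NA_character_` if the subset codes no sample.
#' @export
decode_hashtags <- function(code, hashtags) {
  keys <- vapply(code$samples, subset_key, character(1))
  hit <- match(subset_key(hashtags), keys)
  if (is.na(hit)) NA_character_ else names(code$samples)[hit]
}

#' @export
print.hashtag_code <- function(x, ...) {
  cat(sprintf("hashtag_code: %d samples over %d hashtags (%s)\n",
              length(x$samples), length(x$hashtags),
              paste(x$hashtags, collapse = ", ")))
  for (s in names(x$samples)) {
    cat(sprintf("  %s -> {%s}\n", s, paste(x$samples[[s]], collapse = ", ")))
  }
  invisible(x)
}

#' @rdname build_hashtag_code
#' @param code a `hashtag_code`.
#' @param path TSV path (columns sample_id, hashtags with `+`-joined names).
#' @export
write_hashtag_code <- function(code, path) {
  df <- data.frame(sample_id = names(code$samples),
                   hashtags = vapply(code$samples, function(s) paste(s, collapse = "+"),
                                     character(1)),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname build_hashtag_code
#' @export
read_hashtag_code <- function(path) {
  df <- read_tsv(path)
  samples <- strsplit(df$hashtags, "+", fixed = TRUE)
  names(samples) <- df$sample_id
  structure(list(samples = samples, hashtags = unique(unlist(samples))),
            class = "hashtag_code")
}
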