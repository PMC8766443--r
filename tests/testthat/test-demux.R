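small_schema <- function() barcode_schema(wells_per_round = c(12, 12, 12), seed = 21)

test_that("parse_read_pairs inverts read construction and flags truncation", {
  sch <- small_schema()
  wl <- sch$whitelists
  r1 <- paste0(wl$round3[4], sch$linker1, wl$round2[7], sch$linker2,
               wl$round1[2], strrep("G", 64))
  ab <- strrep("ACG", 5)
  umi <- strrep("TG", 5)
  r2 <- paste0(ab, umi, strrep("G", 25))
  rec <- parse_read_pairs(r1, r2, sch)
  expect_true(rec$keep)
  expect_identical(rec$r1_bc, wl$round1[2])
  expect_identical(rec$r2_bc, wl$round2[7])
  expect_identical(rec$r3_bc, wl$round3[4])
  expect_identical(rec$antibody_bc, ab)
  expect_identical(rec$umi, umi)

  rec2 <- parse_read_pairs(substr(r1, 1, 20), r2, sch)
  expect_false(rec2$keep)
  expect_identical(rec2$reason, "truncated")
  expect_true(is.na(rec2$r1_bc))
})

test_that("barcode correction accepts unique near matches and rejects ties", {
  expect_identical(correct_barcode("AAAT", c("AAAA", "TTTT"), 1), "AAAA")
  expect_identical(correct_barcode("AAAA", c("AAAA", "TTTT"), 1), "AAAA")
  expect_true(is.na(correct_barcode("AATT", c("AAAA", "TTTT"), 1)))
  expect_true(is.na(correct_barcode("AT", c("AA", "TT"), 1)))  # ambiguous tie
  expect_true(is.na(correct_barcode("ANAA", c("AAAA", "TTTT"), 0)))  # N = mismatch
  expect_identical(correct_barcode("ANAA", c("AAAA", "TTTT"), 1), "AAAA")
  expect_error(correct_barcode("AAA", c("AAAA", "TTTT"), 1), "length")
})

test_that("single substitutions always correct under a distance-3 whitelist", {
  wl <- generate_whitelist(10, 6, min_dist = 3, seed = 33)
  bases <- c("A", "C", "G", "T")
  for (w in wl) {
    for (pos in 1:6) {
      for (b in setdiff(bases, substr(w, pos, pos))) {
        corrupted <- w
        substr(corrupted, pos, pos) <- b
        expect_identical(correct_barcode(corrupted, wl, 1), w)
      }
    }
  }
})

test_that("UMI collapse follows the directional merge rule", {
  expect_identical(collapse_umis(c(rep("AAAA", 5), "AAAT"), "directional"), 1L)
  expect_identical(collapse_umis(c(rep("AAAA", 5), "AAAT"), "exact"), 2L)
  expect_identical(collapse_umis(character(0)), 0L)
  # counts 3 and 3: 3 >= 2*3-1 fails, so the pair stays split
  expect_identical(collapse_umis(c(rep("AAAA", 3), rep("AAAT", 3)), "directional"), 2L)
  # chain: AAAA(9) absorbs AAAT(2); AAAT absorbs AATT(1) -> one component
  expect_identical(
    collapse_umis(c(rep("AAAA", 9), rep("AAAT", 2), "AATT"), "directional"), 1L)
  # distance 2 is out of reach at mismatch 1
  expect_identical(collapse_umis(c(rep("AAAA", 9), "AATT"), "directional"), 2L)
})

test_that("directional <= exact <= read count on random UMI multisets", {
  set.seed(44)
  for (i in 1:25) {
    umis <- sample(random_dna <- replicate(8, paste(sample(c("A", "C", "G", "T"),
                                                           4, replace = TRUE),
                                                    collapse = "")),
                   30, replace = TRUE)
    d <- collapse_umis(umis, "directional")
    e <- collapse_umis(umis, "exact")
    expect_lte(d, e)
    expect_lte(e, length(umis))
    expect_gte(d, 1)
  }
})

test_that("grouped UMI collapse agrees with the per-group reference", {
  set.seed(55)
  groups <- lapply(1:40, function(g) {
    pool <- replicate(sample(2:6, 1),
                      paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
                            collapse = ""))
    sample(pool, sample(3:25, 1), replace = TRUE)
  })
  dt <- data.table::data.table(
    gid = rep(seq_along(groups), lengths(groups)),
    umi = unlist(groups))
  for (m in c("directional", "exact")) {
    got <- splitADT:::collapse_umis_grouped(dt, m, 1)
    expected <- vapply(groups, collapse_umis, integer(1), method = m)
    expect_identical(got$count[order(got$gid)], expected[sort(unique(dt$gid))],
                     label = m)
  }
})

test_that("call_cells groups by barcode triple and keeps a conserving ledger", {
  rec <- data.frame(
    r1 = c("w5", "w5", "w5", NA, "w9", "w9"),
    r2 = c("w12", "w12", "w12", "w12", "w1", "w1"),
    r3 = c("w3", "w3", "w3", "w3", "w2", "w2"),
    antibody = c("CD4", "CD4", "CD8", "CD4", "CD8", NA),
    umi = c("AAAA", "CCCC", "GGGG", "TTTT", "AAAA", "CCCC"),
    stringsAsFactors = FALSE
  )
  calls <- call_cells(rec, min_umi = 0)
  expect_identical(sort(unique(calls$cell_key)), c("w5_w12_w3", "w9_w1_w2"))
  one <- calls[calls$cell_key == "w5_w12_w3", ]
  expect_identical(sum(one$umis), 3L)  # 2 CD4 UMIs + 1 CD8 UMI
  ledger <- attr(calls, "ledger")
  get_n <- function(r) ledger$n[ledger$reason == r]
  expect_identical(get_n("input"), get_n("assigned") + get_n("r1_uncorrected") +
                     get_n("antibody_uncorrected"))

  # min_umi filter drops the 1-UMI triple but not the 3-UMI one
  calls10 <- call_cells(rec, min_umi = 2)
  expect_identical(unique(calls10$cell_key), "w5_w12_w3")
})

test_that("count matrices round-trip through MatrixMarket exactly", {
  panel <- antibody_panel(c("CD4", "CD8"), "marker", seed = 9)
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(1, 3),
                            dims = c(2, 2),
                            dimnames = list(c("k1", "k2"), panel$name))
  dir <- file.path(tempdir(), "mtx_roundtrip")
  write_count_matrix(m, dir, panel)
  back <- read_count_matrix(dir)
  expect_identical(as.matrix(back), as.matrix(m))
  expect_identical(Matrix::nnzero(back), 2L)

  empty <- m[0, , drop = FALSE]
  dir2 <- file.path(tempdir(), "mtx_empty")
  write_count_matrix(empty, dir2, panel)
  back2 <- read_count_matrix(dir2)
  expect_identical(dim(back2), c(0L, 2L))
})

test_that("noise-free simulate -> demux round trip reproduces truth exactly", {
  run <- mini_noiseless()
  truth <- truth_key_counts(run, run$config$panel)
  got <- as.matrix(run$demux$counts)
  expect_identical(sort(rownames(got)), sort(rownames(truth)))
  got <- got[rownames(truth), colnames(truth)]
  expect_true(all(got == truth))
  # every parsed field is on-whitelist when the error rate is zero
  ledger <- run$demux$ledger
  expect_identical(ledger$n[ledger$reason == "input"],
                   ledger$n[ledger$reason == "assigned"])
})

test_that("late-spike control cells are never called when blocking holds", {
  run <- mini_noiseless()
  ht3_keys <- run$truth$cells$cell_key[run$truth$cells$control_flag == "ht3_late_spike"]
  expect_true(all(is.na(ht3_keys)))
  flags <- truth_flags_for_cells(rownames(run$demux$counts), run$truth$cells)
  expect_identical(sum(flags == "ht3_late_spike"), 0L)
})

test_that("demux of a noisy run stays conservative and near-complete", {
  run <- mini_two_lines()
  ledger <- run$demux$ledger
  n_in <- ledger$n[ledger$reason == "input"]
  n_assigned <- ledger$n[ledger$reason == "assigned"]
  n_rejected <- sum(ledger$n[!ledger$reason %in% c("input", "assigned")])
  expect_identical(n_in, n_assigned + n_rejected)
  # radius-1 correction over distance-3 whitelists keeps nearly every read
  expect_gt(n_assigned / n_in, 0.99)
})
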