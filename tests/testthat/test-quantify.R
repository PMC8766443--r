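test_that("CLR matches direct evaluation of the centered log-ratio", {
  expect_equal(as.vector(clr_transform(matrix(c(5, 5, 5, 5), 1), pseudocount = 0)),
               c(0, 0, 0, 0))
  # g = 8^(1/4); scores log(1/g) x3, log(8/g)
  got <- as.vector(clr_transform(matrix(c(1, 1, 1, 8), 1), pseudocount = 0))
  expect_equal(got, c(-0.5199, -0.5199, -0.5199, 1.5596), tolerance = 1e-4)
  expect_equal(sum(got), 0, tolerance = 1e-12)
})

test_that("CLR rows sum to zero and scores are scale-invariant", {
  set.seed(14)
  x <- matrix(rpois(600, 8), nrow = 60)
  clr <- clr_transform(x, pseudocount = 1)
  expect_true(all(abs(rowSums(clr)) < 1e-9))
  # multiplying a composition by a positive scalar leaves ratios unchanged
  y <- matrix(c(2, 4, 8, 16), 1)
  expect_equal(as.vector(clr_transform(y, pseudocount = 0)),
               as.vector(clr_transform(7 * y, pseudocount = 0)),
               tolerance = 1e-12)
  expect_error(clr_transform(matrix(0, 1, 3), pseudocount = 0), "pseudocount")
  # the ratio (no-log) variant multiplies to 1 per row
  r <- clr_transform(y, pseudocount = 0, log = FALSE)
  expect_equal(prod(r), 1, tolerance = 1e-12)
})

test_that("collision fraction follows the occupancy closed form", {
  m <- 96^3
  expect_identical(expected_collision_fraction(1, m), 0)
  expect_equal(expected_collision_fraction(17694, m), 0.0198, tolerance = 1e-4)
  expect_lte(expected_collision_fraction(17694, m), 0.02)
  # exact and Poisson forms agree closely in the dilute regime
  for (n in c(100, 5000, 17694, floor(0.05 * m))) {
    expect_lt(abs(expected_collision_fraction(n, m) -
                    expected_collision_fraction(n, m, "poisson")), 1e-4)
  }
  # monotone in n, antitone in m
  ns <- c(10, 100, 1000, 10000)
  fr <- vapply(ns, expected_collision_fraction, numeric(1), m = m)
  expect_true(all(diff(fr) > 0))
  ms <- c(96^2, 96^3, 96^4)
  fm <- vapply(ms, function(m) expected_collision_fraction(1000, m), numeric(1))
  expect_true(all(diff(fm) < 0))
})

test_that("Monte-Carlo collisions agree with the closed form within 3 SE", {
  n <- 2000; m <- 48^3
  mc <- simulate_collision_fraction(n, m, reps = 50, seed = 123)
  expect_lt(abs(mc$mean - expected_collision_fraction(n, m)), 3 * mc$se)
})

test_that("max_loading applies the dilution floor", {
  expect_identical(max_loading(884736, 0.02), 17694L)
  expect_identical(max_loading(100, 0.02), 2L)
  # one extra 96-well round multiplies capacity (and loading) by 96:
  # almost two orders of magnitude
  expect_equal(max_loading(96^4, 0.02) / max_loading(96^3, 0.02), 96,
               tolerance = 1e-4)
  expect_error(max_loading(100, 0), "target_occupancy")
})

test_that("hashtag combination decoding recovers every sample exactly", {
  code <- build_hashtag_code(paste0("s", 1:10), paste0("H", 1:4))
  set.seed(31)
  per_sample <- 30
  counts <- NULL
  labels <- character(0)
  for (s in names(code$samples)) {
    block <- matrix(rpois(per_sample * 6, 2), per_sample, 6,
                    dimnames = list(NULL, c(paste0("H", 1:4), "CD4", "CD8")))
    block[, code$samples[[s]]] <- matrix(rpois(per_sample * length(code$samples[[s]]), 60),
                                         per_sample)
    block[, "CD4"] <- rpois(per_sample, 30)
    counts <- rbind(counts, block)
    labels <- c(labels, rep(s, per_sample))
  }
  rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  clr <- clr_transform(counts)
  asg <- assign_samples(clr, code)
  expect_identical(asg$label, labels)

  # a cell positive for every hashtag spans several codes: multi_sample
  all_pos <- counts
  all_pos[1, paste0("H", 1:4)] <- 500
  asg2 <- assign_samples(clr_transform(all_pos), code)
  expect_identical(asg2$label[1], "multi_sample")

  expect_error(assign_samples(clr[, c("CD4", "CD8")], code), "absent")
})

test_that("fixed-threshold positivity is available for sample assignment", {
  code <- build_hashtag_code(c("sA", "sB"), c("H1", "H2"))
  clr <- matrix(c(2, -1, -1, 2), 2, 2, dimnames = list(c("x", "y"), c("H1", "H2")))
  asg <- assign_samples(clr, code, method = "threshold", threshold = 0)
  expect_identical(asg$label, c("sA", "sB"))
  expect_error(assign_samples(clr, code, method = "threshold"), "threshold")
})

test_that("control QC reports zero late-spike cells and background leakage without swapping", {
  run <- mini_two_lines()
  flags <- truth_flags_for_cells(rownames(run$demux$counts), run$truth$cells)
  qc <- control_qc(run$demux$counts, flags, run$config$panel,
                   ledger = run$demux$ledger)
  expect_identical(qc$n_ht3_called, 0L)
  expect_gt(qc$n_ht2_called, 0)
  # without swapping, hashtag-only cells sit below ordinary cells on markers
  expect_lt(qc$ht2_marker_clr, qc$other_marker_clr)
})

test_that("marker leakage onto hashtag-only controls increases with the swap rate", {
  base <- mini_two_lines()
  leakage_at <- function(run) {
    flags <- truth_flags_for_cells(rownames(run$demux$counts), run$truth$cells)
    control_qc(run$demux$counts, flags, run$config$panel)$ht2_marker_leakage
  }
  fx <- fixture_config("two_lines", n_cells = 250, seed = 7, swap_rate = 0.2)
  dir <- file.path(tempdir(), "swapped_run")
  sim <- simulate_experiment(fx$config, fx$schema, dir, seed = 7)
  dmx <- demux_fastq(sim$files$r1, sim$files$r2, fx$schema, fx$config$panel)
  swapped <- c(fx, sim, list(demux = dmx))
  expect_gt(leakage_at(swapped), leakage_at(base))
})

test_that("blocking failure lets late-spike cells leak into the called set", {
  fx <- fixture_config("controls_only", seed = 13, blocking_failure_prob = 0.5,
                       ht2_n = 60, ht3_n = 60)
  dir <- file.path(tempdir(), "blocking_fail")
  sim <- simulate_experiment(fx$config, fx$schema, dir, seed = 13)
  # illegitimate round-1 barcodes scatter a cell's molecules across many
  # triples, so detection needs permissive cell calling
  dmx <- demux_fastq(sim$files$r1, sim$files$r2, fx$schema, fx$config$panel,
                     min_umi = 1)
  flags <- truth_flags_for_cells(rownames(dmx$counts), sim$truth$cells)
  qc <- control_qc(dmx$counts, flags, fx$config$panel)
  expect_gt(qc$n_ht3_called, 0)
})
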