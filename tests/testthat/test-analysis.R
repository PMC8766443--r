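# two well-separated log-normal populations over 6 antibodies
blob_clr <- function(n_per = 120, seed = 17) {
  with_seed <- splitADT:::with_seed
  with_seed(seed, {
    means <- rbind(a = c(60, 2, 30, 2, 10, 5),
                   b = c(2, 60, 2, 30, 10, 5))
    counts <- NULL
    for (g in rownames(means)) {
      lam <- exp(matrix(rnorm(n_per * 6, log(means[g, ]), 0.3),
                        n_per, byrow = TRUE))
      counts <- rbind(counts, matrix(rpois(n_per * 6, lam), n_per))
    }
    colnames(counts) <- c("CD4", "CD56", "CD28", "CD155", "CD45", "IgG1")
    rownames(counts) <- sprintf("c%04d", seq_len(nrow(counts)))
    list(clr = clr_transform(counts),
         labels = rep(c("a", "b"), each = n_per))
  })
}

test_that("PCA separates distinct populations with orthonormal loadings", {
  bl <- blob_clr()
  p <- pca_scores(bl$clr, n_components = 3)
  a <- p$scores[bl$labels == "a", 1]
  b <- p$scores[bl$labels == "b", 1]
  expect_true(max(min(a), min(b)) > min(max(a), max(b)) ||
                max(a) < min(b) || max(b) < min(a))
  gram <- crossprod(p$loadings)
  expect_equal(gram, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  # sign convention: the dominant loading of each component is positive
  for (j in 1:3) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_error(pca_scores(bl$clr, n_components = 99), "exceeds")
})

test_that("full-rank PCA reconstructs the centered data", {
  bl <- blob_clr(40)
  k <- ncol(bl$clr)
  p <- pca_scores(bl$clr, n_components = k)
  centered <- sweep(as.matrix(bl$clr), 2, p$center)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - centered)), 1e-8)
})

test_that("k-means recovers well-separated populations and obeys contracts", {
  skip_if_not_installed("mclust")
  run <- full_two_lines()
  flags <- truth_flags_for_cells(rownames(run$demux$counts), run$truth$cells)
  truth_lab <- run$truth$cells$cell_type[
    match(rownames(run$demux$counts), run$truth$cells$cell_key)]
  truth_lab[flags == "ht2_only"] <- "ht2_control"
  keep <- !is.na(truth_lab)
  clr <- clr_transform(run$demux$counts[keep, ])
  p <- pca_scores(clr, 3)
  for (s in c(1, 2, 42)) {
    lab <- kmeans_cluster(p$scores, k = 4, seed = s)
    expect_gte(mclust::adjustedRandIndex(lab, truth_lab[keep]), 0.95)
  }
  expect_identical(unique(kmeans_cluster(p$scores, k = 1)), 1L)
  # duplicating every point leaves the partition pattern intact
  lab1 <- kmeans_cluster(p$scores, k = 4, seed = 3)
  lab2 <- kmeans_cluster(rbind(p$scores, p$scores), k = 4, seed = 3)
  expect_gte(mclust::adjustedRandIndex(rep(lab1, 2), lab2), 0.999)
  expect_error(kmeans_cluster(p$scores[1:3, ], k = 10), "exceeds")
})

test_that("t-SNE is deterministic under a fixed seed and separates populations", {
  skip_if_not_installed("cluster")
  bl <- blob_clr(100)
  e1 <- tsne_embed(bl$clr, seed = 5, perplexity = 20)
  e2 <- tsne_embed(bl$clr, seed = 5, perplexity = 20)
  expect_identical(e1$coords, e2$coords)
  sil <- cluster::silhouette(as.integer(factor(bl$labels)),
                             stats::dist(e1$coords))
  expect_gt(mean(sil[, "sil_width"]), 0)
  # random initialisation also runs (non-default path)
  e3 <- tsne_embed(bl$clr, seed = 5, perplexity = 20, pca_init = FALSE)
  expect_false(identical(e1$coords, e3$coords))
  expect_error(tsne_embed(bl$clr[1:10, ], perplexity = 30), "too few cells")
})

test_that("gates nest within their parents and recover design fractions", {
  # mixture with 84% CD19+CD3- B cells among CD45+ cells, plus a CD45-
  # non-hematopoietic population so the CD45 gate has two classes to split
  panel <- antibody_panel(c("CD45", "CD19", "CD3", "CD56", "IgG1",
                            "HT1", "HT2", "HT3"),
                          c(rep("marker", 4), "isotype_control",
                            rep("hashtag", 3)), seed = 19)
  cfg <- sim_config(
    panel = panel,
    cell_types = list(b = c(CD45 = 60, CD19 = 50),
                      t = c(CD45 = 60, CD3 = 50),
                      other = c(CD56 = 40)),
    composition = list(s1 = c(b = 0.63, t = 0.12, other = 0.25)),
    n_cells = c(s1 = 1600), ht2_spike_fraction = 0, ht3_spike_fraction = 0)
  tr <- simulate_cells(cfg, seed = 19)
  clr <- clr_transform(tr$counts)
  rownames(clr) <- tr$cells$cell_id
  gs <- gate_set(clr)
  gs <- gate(gs, "CD45pos", "CD45", ">")
  gs <- gate(gs, "CD19pos", "CD19", ">", parent = "CD45pos")
  # CD3 threshold estimated on the CD45+ parent (where both classes exist),
  # then applied inside the CD19+ gate
  cd3_thr <- attr(positivity_split(clr[gate_mask(gs, "CD45pos"), "CD3"]),
                  "threshold")
  gs <- gate(gs, "Bcells", "CD3", "<", threshold = cd3_thr, parent = "CD19pos")
  rep_tab <- gate_report(gs)
  expect_true(all(gate_mask(gs, "Bcells") <= gate_mask(gs, "CD19pos")))
  expect_true(all(gate_mask(gs, "CD19pos") <= gate_mask(gs, "CD45pos")))
  expect_true(all(rep_tab$fraction >= 0 & rep_tab$fraction <= 1))
  b_frac <- sum(gate_mask(gs, "Bcells")) / sum(gate_mask(gs, "CD45pos"))
  expect_equal(b_frac, 0.84, tolerance = 3 * sqrt(0.84 * 0.16 / 1200) / 0.84)
  expect_equal(gs$gates$CD45pos$fraction, 0.75, tolerance = 0.05)

  # threshold below every score keeps the whole parent
  gs2 <- gate(gs, "all", "CD45", ">", threshold = min(clr[, "CD45"]) - 1)
  expect_identical(gate_mask(gs2, "all"), gate_mask(gs2, "root"))
  expect_error(gate(gs, "x", "nope", ">"), "unknown marker")
  expect_error(gate(gs, "x", "CD45", ">", parent = "nope"), "unknown parent")
})

test_that("kappa-lambda ratio arithmetic and interpretation follow the clinical rule", {
  clr <- matrix(0, 90, 2, dimnames = list(NULL, c("IgKappa", "IgLambda")))
  clr[1:60, "IgKappa"] <- 3
  clr[61:90, "IgLambda"] <- 3
  mask <- rep(TRUE, 90)
  r <- kappa_lambda_ratio(clr, mask, threshold = 1)
  expect_equal(r$ratio, 2)
  expect_identical(r$interpretation, "normal")  # 1-2 is the normal range

  clr2 <- clr[, c(2, 1)]
  colnames(clr2) <- c("IgKappa", "IgLambda")
  r2 <- kappa_lambda_ratio(clr2, mask, threshold = 1)
  expect_equal(r2$ratio, 0.5)
  expect_identical(r2$interpretation, "lambda-expanded")

  clr3 <- clr; clr3[, "IgLambda"] <- 0
  expect_warning(r3 <- kappa_lambda_ratio(clr3, mask, threshold = 1), "infinite")
  expect_identical(r3$ratio, Inf)

  # ratio ignores cells outside the gate
  clr4 <- rbind(clr, matrix(c(0, 3), 50, 2, byrow = TRUE,
                            dimnames = list(NULL, colnames(clr))))
  r4 <- kappa_lambda_ratio(clr4, c(mask, rep(FALSE, 50)), threshold = 1)
  expect_equal(r4$ratio, r$ratio)
  expect_error(kappa_lambda_ratio(clr, rep(FALSE, 90), threshold = 1), "empty gate")
})

test_that("a clonally restricted B-cell simulation is flagged kappa-expanded", {
  panel <- antibody_panel(c("CD45", "CD19", "IgKappa", "IgLambda", "IgG1",
                            "HT1", "HT2", "HT3"),
                          c(rep("marker", 4), "isotype_control",
                            rep("hashtag", 3)), seed = 23)
  cfg <- sim_config(
    panel = panel,
    cell_types = list(bk = c(CD45 = 60, CD19 = 50, IgKappa = 45),
                      bl = c(CD45 = 60, CD19 = 50, IgLambda = 45)),
    composition = list(s1 = c(bk = 0.9, bl = 0.1)),
    n_cells = c(s1 = 600), ht2_spike_fraction = 0, ht3_spike_fraction = 0)
  tr <- simulate_cells(cfg, seed = 23)
  clr <- clr_transform(tr$counts)
  r <- kappa_lambda_ratio(clr, rep(TRUE, nrow(clr)))
  expect_gt(r$ratio, 2)
  expect_identical(r$interpretation, "kappa-expanded")
})

test_that("non-specific cells are flagged via the control-marker component", {
  set.seed(29)
  n <- 1000
  means <- rbind(a = c(60, 2, 30, 2, 2, 2),
                 b = c(2, 60, 2, 30, 2, 2))
  grp <- sample(c("a", "b"), n, replace = TRUE)
  lam <- exp(matrix(rnorm(n * 6, log(means[grp, ]), 0.3), n))
  counts <- matrix(rpois(n * 6, lam), n)
  colnames(counts) <- c("CD4", "CD56", "CD28", "CD155", "IgG1", "HT3")
  ns <- sample(n, 0.02 * n)
  counts[ns, c("IgG1", "HT3")] <- matrix(rpois(length(ns) * 2, 50), length(ns))
  clr <- clr_transform(counts)
  mask <- flag_nonspecific(clr, control_markers = c("IgG1", "HT3"))
  sens <- sum(mask[ns]) / length(ns)
  expect_gte(sens, 0.9)
  flagged_frac <- mean(mask)
  expect_lt(abs(flagged_frac - 0.02), 0.02)
  expect_error(flag_nonspecific(clr, character(0)), "control markers")

  # degenerate composition: all CLR columns constant, controls carry no variance
  counts2 <- counts
  counts2[, ] <- 5
  expect_warning(m2 <- flag_nonspecific(clr_transform(counts2),
                                        c("IgG1", "HT3")), "zero variance")
  expect_false(any(m2))
})
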