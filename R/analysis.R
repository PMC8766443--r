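#' Principal component analysis of CLR scores
#'
#' Centered PCA with a deterministic sign convention: each component is
#' oriented so its largest-magnitude loading is positive, making scores
#' reproducible across platforms.
#'
#' @param clr cells-by-antibody CLR matrix.
#' @param n_components number of components to keep.
#' @return object of class `pca_embedding`: list with `scores`
#'   (cells x components), `loadings` (antibodies x components, orthonormal),
#'   `sdev`, `var_explained`, `center`.
#' @export
pca_scores <- function(clr, n_components = 3) {
  x <- as.matrix(clr)
  if (n_components > ncol(x)) {
    stop("pca_scores(): n_components exceeds the number of antibodies")
  }
  if (any(!is.finite(x))) stop("pca_scores(): non-finite values")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  structure(list(scores = sco, loadings = rot,
                 sdev = pc$sdev[seq_len(k)],
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center,
                 n_components = k),
            class = "pca_embedding")
}

#' K-means clustering of embedding scores
#'
#' Best-of-restarts k-means (Hartigan-Wong) on the given score matrix,
#' deterministic for a fixed seed.
#'
#' @param scores numeric matrix (cells x dimensions), e.g. PCA scores.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_restarts random restarts; the labeling with the lowest total
#'   within-cluster sum of squares wins.
#' @return integer vector of cluster labels (1..k) with the fitted
#'   `kmeans` object attached as attribute `fit`.
#' @export
kmeans_cluster <- function(scores, k, seed = 1, n_restarts = 10) {
  scores <- as.matrix(scores)
  if (k < 1) stop("kmeans_cluster(): k must be >= 1")
  if (k > nrow(scores)) stop("kmeans_cluster(): k exceeds the number of cells")
  fit <- with_seed(seed, kmeans(scores, centers = k, nstart = n_restarts,
                                iter.max = 100))
  structure(fit$cluster, fit = fit)
}

#' t-SNE embedding of CLR scores with PCA initialisation
#'
#' Two-dimensional Barnes-Hut t-SNE of the CLR matrix. By default the
#' embedding is initialised from the top-2 PCA scores (rescaled to the
#' conventional small spread), which anchors the global geometry and makes
#' the map reproducible; random initialisation is available behind
#' `pca_init = FALSE`.
#'
#' @param clr cells-by-antibody CLR matrix.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (requires at least `3 * perplexity`
#'   cells plus one).
#' @param pca_init initialise from PCA (default) or randomly.
#' @param max_iter gradient-descent iterations.
#' @return object of class `tsne_embedding`: list with `coords`
#'   (cells x 2), `perplexity`, `seed`, `pca_init`.
#' @export
tsne_embed <- function(clr, seed = 1, perplexity = 30, pca_init = TRUE,
                       max_iter = 500) {
  x <- as.matrix(clr)
  if (nrow(x) - 1 < 3 * perplexity) {
    stop("tsne_embed(): too few cells for perplexity ", perplexity)
  }
  init <- NULL
  if (pca_init) {
    p <- pca_scores(x, n_components = 2)
    init <- scale(p$scores, center = TRUE, scale = FALSE)
    init <- init / stats::sd(init[, 1]) * 1e-4
  }
  fit <- with_seed(seed, Rtsne::Rtsne(
    x, dims = 2, perplexity = perplexity, theta = 0.5,
    pca = FALSE, check_duplicates = FALSE, max_iter = max_iter,
    Y_init = init, verbose = FALSE))
  coords <- fit$Y
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("tsne1", "tsne2")
  structure(list(coords = coords, perplexity = perplexity, seed = seed,
                 pca_init = pca_init),
            class = "tsne_embedding")
}

#' Hierarchical gating of CLR scores
#'
#' `gate_set()` creates a gating tree over a CLR matrix with a root gate
#' containing every cell. `gate()` adds a child gate: cells of the parent
#' gate passing `marker comparator threshold`. With `threshold = NULL` the
#' threshold is derived by a two-class split ([positivity_split()]) of the
#' marker's scores *within the parent population*, mirroring how flow
#' plots are gated population by population.
#'
#' @param clr cells-by-antibody CLR matrix.
#' @return `gate_set`: an object of class `gate_set`.
#' @export
gate_set <- function(clr) {
  clr <- as.matrix(clr)
  structure(list(
    clr = clr,
    gates = list(root = list(mask = rep(TRUE, nrow(clr)), parent = NA_character_,
                             marker = NA_character_, comparator = NA_character_,
                             threshold = NA_real_, fraction = 1))
  ), class = "gate_set")
}

#' @rdname gate_set
#' @param gs a `gate_set`.
#' @param name name of the new gate.
#' @param marker antibody name to gate on.
#' @param comparator `">"` (positive) or `"<"` (negative).
#' @param threshold CLR threshold; `NULL` derives it within the parent.
#' @param parent name of the parent gate (default `"root"`).
#' @return `gate`: the updated `gate_set`.
#' @export
gate <- function(gs, name, marker, comparator = c(">", "<"),
                 threshold = NULL, parent = "root") {
  comparator <- match.arg(comparator)
  if (!marker %in% colnames(gs$clr)) stop("gate(): unknown marker: ", marker)
  if (!parent %in% names(gs$gates)) stop("gate(): unknown parent gate: ", parent)
  if (name %in% names(gs$gates)) stop("gate(): gate already exists: ", name)
  pmask <- gs$gates[[parent]]$mask
  scores <- gs$clr[, marker]
  if (is.null(threshold)) {
    sp <- positivity_split(scores[pmask])
    threshold <- attr(sp, "threshold")
    if (is.na(threshold)) threshold <- Inf  # degenerate parent: nothing positive
  }
  pass <- if (comparator == ">") scores > threshold else scores < threshold
  mask <- unname(pmask & pass)
  gs$gates[[name]] <- list(mask = mask, parent = parent, marker = marker,
                           comparator = comparator, threshold = threshold,
                           fraction = if (sum(pmask)) sum(mask) / sum(pmask) else NA_real_)
  gs
}

#' @rdname gate_set
#' @return `gate_mask`: logical mask of one gate.
#' @export
gate_mask <- function(gs, name) gs$gates[[name]]$mask

#' @rdname gate_set
#' @return `gate_report`: data.frame with one row per gate (name, parent,
#'   marker, comparator, threshold, n, fraction of parent).
#' @export
gate_report <- function(gs) {
  do.call(rbind, lapply(names(gs$gates), function(nm) {
    g <- gs$gates[[nm]]
    data.frame(name = nm, parent = g$parent, marker = g$marker,
               comparator = g$comparator, threshold = g$threshold,
               n = sum(g$mask), fraction = g$fraction,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.gate_set <- function(x, ...) {
  print(gate_report(x))
  invisible(x)
}

#' Kappa-lambda light-chain ratio within a gate
#'
#' Counts kappa-positive and lambda-positive cells inside a (typically
#' B-cell) gate and reports their ratio. A ratio between 1 and 2 is
#' interpreted as `"normal"`; above 2 as `"kappa-expanded"` and below 1 as
#' `"lambda-expanded"`, both signatures of clonal light-chain restriction.
#'
#' @param clr cells-by-antibody CLR matrix.
#' @param mask logical gate mask (e.g. from [gate_mask()]).
#' @param kappa_marker,lambda_marker column names of the light-chain
#'   antibodies.
#' @param threshold fixed CLR positivity threshold; `NULL` uses a
#'   two-class split within the gate per marker.
#' @return list with `ratio`, `n_kappa`, `n_lambda`, `interpretation`.
#'   Zero lambda-positive cells yield `ratio = Inf` with a warning.
#' @export
kappa_lambda_ratio <- function(clr, mask, kappa_marker = "IgKappa",
                               lambda_marker = "IgLambda", threshold = NULL) {
  clr <- as.matrix(clr)
  stopifnot(kappa_marker %in% colnames(clr), lambda_marker %in% colnames(clr))
  if (!any(mask)) stop("kappa_lambda_ratio(): empty gate")
  call_pos <- function(marker) {
    x <- clr[mask, marker]
    if (is.null(threshold)) as.logical(positivity_split(x)) else x > threshold
  }
  nk <- sum(call_pos(kappa_marker))
  nl <- sum(call_pos(lambda_marker))
  if (nl == 0) {
    warning("kappa_lambda_ratio(): no lambda-positive cells; ratio is infinite")
    ratio <- Inf
  } else {
    ratio <- nk / nl
  }
  interpretation <- if (ratio > 2) "kappa-expanded"
                    else if (ratio < 1) "lambda-expanded"
                    else "normal"
  list(ratio = ratio, n_kappa = nk, n_lambda = nl,
       interpretation = interpretation)
}

#' Flag non-specifically stained cells via a control-marker component
#'
#' Finds the principal component on which the control antibodies (isotype
#' controls, stray hashtags) load most strongly in a common direction,
#' orients it so
#' control loadings point positive, and flags cells whose robust z-score
#' (median/MAD) on that component exceeds `mad_cutoff`. When the control
#' markers carry no variance, no component is selected and the mask is
#' empty (with a warning).
#'
#' @param clr cells-by-antibody CLR matrix.
#' @param control_markers character vector of control antibody names.
#' @param pca optional precomputed [pca_scores()] (all components used
#'   otherwise).
#' @param mad_cutoff robust z threshold (default 2.5).
#' @return logical mask over cells with attributes `component`,
#'   `concentration` (per-component control loading mass), `cutoff`.
#' @export
flag_nonspecific <- function(clr, control_markers, pca = NULL, mad_cutoff = 2.5) {
  clr <- as.matrix(clr)
  missing_m <- setdiff(control_markers, colnames(clr))
  if (!length(control_markers) || length(missing_m)) {
    stop("flag_nonspecific(): control markers missing from matrix: ",
         paste(missing_m, collapse = ", "))
  }
  if (all(apply(clr[, control_markers, drop = FALSE], 2, var) < 1e-12)) {
    warning("flag_nonspecific(): control markers have zero variance; empty mask")
    out <- rep(FALSE, nrow(clr))
    attr(out, "component") <- NA_integer_
    return(out)
  }
  if (is.null(pca)) pca <- pca_scores(clr, n_components = ncol(clr))
  # co-directional control loading mass: a component where the controls all
  # point the same way (cells staining for everything at once), not a
  # contrast between two controls
  conc <- colSums(pca$loadings[control_markers, , drop = FALSE])^2
  j <- which.max(conc)
  s <- sign(sum(pca$loadings[control_markers, j]))
  if (s == 0) s <- 1
  x <- pca$scores[, j] * s
  med <- median(x)
  sc <- mad(x)
  if (sc < 1e-12) sc <- stats::sd(x)
  z <- (x - med) / sc
  out <- z > mad_cutoff
  attr(out, "component") <- unname(j)
  attr(out, "concentration") <- conc
  attr(out, "cutoff") <- mad_cutoff
  out
}
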