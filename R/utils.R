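#' @import data.table
#' @importFrom stats kmeans mad median prcomp rbinom rgeom rnorm rpois runif var
#' @importFrom utils head
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded helpers do not perturb the caller's stream.
#' A `NULL` seed evaluates the code under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific child seed from a global seed
#'
#' Stable arithmetic mix of the global seed and a stage label, kept below
#' 2^31 so it is always a valid integer seed. Used so pipeline stages can be
#' rerun independently yet reproducibly.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

#' Random DNA sequences
#' @param n number of sequences.
#' @param len length of each sequence.
#' @return character vector of `n` sequences over A/C/G/T.
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
}

# split equal-length strings into an L x n character matrix
seq_char_matrix <- function(x) {
  if (length(x) == 0) return(matrix(character(0), nrow = 0))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = nchar(x[1]))
}

#' Hamming distance between two equal-length strings
#' @param a,b DNA strings of equal length.
#' @return integer number of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): strings must have equal length")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Hamming distances from one string to every member of a set (as L x n matrix)
hamming_to_matrix <- function(obs, set_matrix) {
  oc <- strsplit(obs, "", fixed = TRUE)[[1]]
  colSums(set_matrix != oc)
}

#' Inject i.i.d. substitution errors into fixed-length sequences
#'
#' Each base is substituted independently with probability `rate`; the
#' replacement is drawn uniformly from the three other bases. Vectorised by
#' error-rank passes so runtime scales with the number of errors, not bases.
#'
#' @param seqs character vector of equal-length sequences.
#' @param rate per-base substitution probability.
#' @return character vector with errors applied.
#' @keywords internal
inject_errors <- function(seqs, rate) {
  n <- length(seqs)
  if (n == 0 || rate <= 0) return(seqs)
  len <- nchar(seqs[1])
  nerr <- rbinom(n, len, rate)
  mx <- max(nerr)
  k <- 1L
  while (k <= mx) {
    i <- which(nerr >= k)
    pos <- sample.int(len, length(i), replace = TRUE)
    s <- seqs[i]
    cur <- substr(s, pos, pos)
    shift <- sample.int(3L, length(i), replace = TRUE)
    repl <- DNA_BASES[(match(cur, DNA_BASES) - 1L + shift) %% 4L + 1L]
    substr(s, pos, pos) <- repl
    seqs[i] <- s
    k <- k + 1L
  }
  seqs
}

# write a data.frame as TSV (no quoting surprises, reproducible)
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", ...))
}
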