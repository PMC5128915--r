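#' Shifting-and-scaling invariant expression similarity
#'
#' Scores two expression profiles in \[0, 1\], returning 1 whenever one profile
#' is an affine transform of the other (`y = a*x + b`, `a != 0`), i.e. for
#' pure shifting, pure scaling, and combined shifting-and-scaling patterns.
#' The default realization is the absolute Pearson correlation over
#' pairwise-complete positions; absolute Spearman is available as a
#' rank-based robustness option. Negative scale factors score 1 as well:
#' the measure captures pattern similarity, not sign.
#'
#' @param x,y numeric profiles of equal length (>= 2). `NA` allowed.
#' @param measure `"abspearson"` (default) or `"absspearman"`.
#' @return a score in \[0, 1\], or `NA` when fewer than 2 pairwise-complete
#'   positions exist or either profile is constant on the complete positions
#'   (zero variance gives no direction of change to compare).
#' @examples
#' expression_similarity(c(1, 2, 3), c(3, 4, 5))   # shifting -> 1
#' expression_similarity(c(1, 2, 3), c(5, 3, 1))   # y = -2x + 7 -> 1
#' expression_similarity(c(1, 2, 3), c(1, 3, 2))   # 0.5
#' @export
expression_similarity <- function(x, y,
                                  measure = c("abspearson", "absspearman")) {
  measure <- match.arg(measure)
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 2L) stop("profiles must have length >= 2")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  r <- stats::cor(x, y,
                  method = if (measure == "abspearson") "pearson" else "spearman")
  min(1, abs(r))
}

#' Similarity matrix container
#' @keywords internal
new_sim_matrix <- function(scores, measure) {
  structure(list(scores = scores, measure = measure), class = "sim_matrix")
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("sim_matrix: %d genes (%s), %d NA pair scores\n",
              nrow(x$scores), x$measure,
              sum(is.na(x$scores[upper.tri(x$scores)]))))
  invisible(x)
}

#' Ordered pair-evaluation count for an all-vs-all similarity pass
#'
#' The naive all-vs-all computation evaluates every ordered gene pair,
#' including self-pairs: `n^2` evaluations for `n` genes (e.g. more than
#' 81 million for a ~9000-gene microarray).
#'
#' @param n_genes number of genes.
#' @return `n_genes^2` as a double.
#' @export
pair_evaluations <- function(n_genes) as.numeric(n_genes)^2

#' Gene-gene similarity matrix
#'
#' Applies [expression_similarity()] to every unordered gene pair of a
#' preprocessed expression matrix. The computation is a pure function of the
#' value matrix and measure, so it can be chunked or parallelized externally;
#' this implementation is single-CPU and vectorized through [stats::cor()]
#' with pairwise-complete observations.
#'
#' @param m an `expr_matrix` (preprocessed: unique gene IDs).
#' @param measure passed to [expression_similarity()].
#' @return a `sim_matrix`: symmetric scores in \[0, 1\] with unit diagonal for
#'   genes having >= 2 distinct finite values; undefined pairs (too few
#'   complete positions, constant profiles) are `NA` and fall below any
#'   threshold downstream. `attr(, "n_evaluations")` records the ordered
#'   pair-evaluation count `n^2`.
#' @export
similarity_matrix <- function(m, measure = c("abspearson", "absspearman")) {
  measure <- match.arg(measure)
  stopifnot(inherits(m, "expr_matrix"))
  if (anyDuplicated(rownames(m$values)))
    stop("duplicate gene IDs; run preprocess_expression() first")
  vals <- t(m$values)
  method <- if (measure == "abspearson") "pearson" else "spearman"
  r <- suppressWarnings(
    stats::cor(vals, use = "pairwise.complete.obs", method = method)
  )
  s <- abs(r)
  s[s > 1] <- 1
  # pairs with < 2 complete positions: cor() may still return +/-1 from a
  # single degenerate overlap in some paths; recompute the overlap counts
  fin <- is.finite(m$values)
  overlap <- fin %*% t(fin)
  s[overlap < 2L] <- NA_real_
  diag_ok <- apply(m$values, 1L, function(v) {
    v <- v[is.finite(v)]
    length(v) >= 2L && stats::sd(v) > 0
  })
  diag(s) <- ifelse(diag_ok, 1, NA_real_)
  out <- new_sim_matrix(s, measure)
  attr(out, "n_evaluations") <- pair_evaluations(nrow(s))
  out
}

#' Threshold a similarity matrix into a co-expression network
#'
#' Two genes are connected iff their similarity score is at least `delta`
#' (inclusive). Undefined (`NA`) scores never produce an edge. The diagonal
#' is always zero (no self-loops).
#'
#' @param s a `sim_matrix`.
#' @param delta similarity threshold in (0, 1].
#' @return a `coexpr_network`: logical adjacency matrix, the `delta` used, and
#'   the degree sequence (`$degrees`, row sums of the adjacency).
#' @export
build_network <- function(s, delta) {
  stopifnot(inherits(s, "sim_matrix"))
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta <= 0 || delta > 1)
    stop("`delta` must be a single value in (0, 1]")
  adj <- s$scores >= delta
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  structure(
    list(adjacency = adj, delta = delta, degrees = rowSums(adj)),
    class = "coexpr_network"
  )
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("coexpr_network: %d genes, %d edges at delta = %g\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$delta))
  invisible(x)
}

#' Write a similarity (or semantic) matrix as TSV
#'
#' Gene x gene matrix with a leading header row and column of gene IDs; the
#' same dialect is used for expression-similarity and semantic matrices.
#'
#' @param scores symmetric numeric matrix with gene dimnames, or a
#'   `sim_matrix` / `semantic_matrix` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(scores, path) {
  if (inherits(scores, c("sim_matrix", "semantic_matrix")))
    scores <- scores$scores
  df <- data.frame(GENE = rownames(scores), scores,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @return numeric matrix with gene dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
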