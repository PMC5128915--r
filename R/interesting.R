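#' Rank border genes by differential-expression variance
#'
#' Scores each pooled border gene by its expression variance across all
#' samples (normal and disease pooled; the spread between the two classes
#' dominates the pooled variance when a gene is differentially expressed) and
#' keeps the top `k`. `de_stat = "meandiff"` ranks by the absolute difference
#' of class means instead.
#'
#' @param border character vector of border gene IDs (subset of the matrix).
#' @param m an `expr_matrix` with `sample_class` set; two classes are
#'   required for `"meandiff"`.
#' @param k number of genes to keep (default 2000); clamped to the pool size
#'   with a warning when the pool is smaller.
#' @param de_stat `"variance"` (default) or `"meandiff"`.
#' @return list with `ranked` (data.frame `gene_id`, `score`, descending with
#'   lexicographic tie-break) and `top` (character vector of the top-k IDs).
#' @export
rank_by_variance <- function(border, m, k = 2000L,
                             de_stat = c("variance", "meandiff")) {
  de_stat <- match.arg(de_stat)
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$sample_class))
    stop("sample classes are required; supply them via `sample_class =` or ",
         "a `class_file =` sidecar when reading the matrix")
  border <- unique(border)
  missing_genes <- setdiff(border, rownames(m$values))
  if (length(missing_genes))
    stop("border genes absent from the expression matrix: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  vals <- m$values[border, , drop = FALSE]
  score <- switch(de_stat,
    variance = apply(vals, 1L, stats::var, na.rm = TRUE),
    meandiff = {
      classes <- unique(m$sample_class)
      if (length(classes) != 2L)
        stop("`meandiff` needs exactly 2 sample classes, found ",
             length(classes))
      a <- rowMeans(vals[, m$sample_class == classes[1L], drop = FALSE],
                    na.rm = TRUE)
      b <- rowMeans(vals[, m$sample_class == classes[2L], drop = FALSE],
                    na.rm = TRUE)
      abs(a - b)
    })
  score[is.na(score)] <- 0
  ord <- order(-score, border)
  ranked <- data.frame(gene_id = border[ord], score = score[ord],
                       stringsAsFactors = FALSE)
  if (k > nrow(ranked)) {
    warning("k = ", k, " exceeds the border pool size (", nrow(ranked),
            "); keeping all")
    k <- nrow(ranked)
  }
  list(ranked = ranked, top = ranked$gene_id[seq_len(k)])
}

#' Map gene identifiers through an offline two-column table
#'
#' Replaces live web ID translation with a user-supplied mapping (e.g. probe
#' -> Entrez). When a source ID maps to several targets the first occurrence
#' in file order is kept, with a warning.
#'
#' @param genes character vector of source IDs.
#' @param mapping a two-column data.frame (from, to) or a path to a
#'   headerless two-column TSV.
#' @return list with `mapped` (data.frame `from`, `to`, in input order) and
#'   `unmapped` (character vector of IDs with no entry).
#' @export
map_ids <- function(genes, mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- utils::read.table(mapping, sep = "\t", header = FALSE,
                                 colClasses = "character", quote = "")
  }
  if (ncol(mapping) < 2L) stop("mapping must have two columns (from, to)")
  from <- as.character(mapping[[1L]]); to <- as.character(mapping[[2L]])
  dup <- duplicated(from)
  if (any(dup & from %in% genes))
    warning("multiple mappings for: ",
            paste(unique(from[dup & from %in% genes]), collapse = ", "),
            "; keeping the first by file order")
  idx <- match(genes, from)
  mapped <- data.frame(from = genes[!is.na(idx)], to = to[idx[!is.na(idx)]],
                       stringsAsFactors = FALSE)
  list(mapped = mapped, unmapped = genes[is.na(idx)])
}

#' Select interesting genes by the mean-semantic-similarity threshold
#'
#' Computes `beta`, the mean of the defined off-diagonal (upper-triangle)
#' scores of a gene semantic matrix, and flags a gene as interesting when it
#' participates in at least one pair scoring `>= beta` (inclusive). The
#' `"rowmean"` rule instead requires a gene's mean similarity to all others
#' to reach `beta`.
#'
#' @param sem a `semantic_matrix` over >= 2 genes.
#' @param rule `"any"` (default) or `"rowmean"`.
#' @return list with `beta`, `interesting` (character vector), and
#'   `per_gene` data.frame (`gene_id`, `mean_semantic`, `max_semantic`,
#'   `interesting`).
#' @export
select_interesting <- function(sem, rule = c("any", "rowmean")) {
  rule <- match.arg(rule)
  stopifnot(inherits(sem, "semantic_matrix"))
  s <- sem$scores
  if (nrow(s) < 2L) stop("need at least 2 genes to compute beta")
  ut <- s[upper.tri(s)]
  if (all(is.na(ut))) stop("all pairwise semantic scores are undefined")
  beta <- mean(ut, na.rm = TRUE)
  off <- s
  diag(off) <- NA_real_
  mean_sem <- rowMeans(off, na.rm = TRUE)
  max_sem <- suppressWarnings(apply(off, 1L, max, na.rm = TRUE))
  max_sem[!is.finite(max_sem)] <- NA_real_
  flag <- switch(rule,
                 any = !is.na(max_sem) & max_sem >= beta,
                 rowmean = !is.na(mean_sem) & mean_sem >= beta)
  per_gene <- data.frame(gene_id = rownames(s),
                         mean_semantic = as.numeric(mean_sem),
                         max_semantic = as.numeric(max_sem),
                         interesting = flag, stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  list(beta = beta, interesting = per_gene$gene_id[flag], per_gene = per_gene)
}

#' Border-gene prioritization pipeline
#'
#' Pools border genes across modules, ranks them by differential-expression
#' variance, optionally maps identifiers, computes the Lin/BMA gene semantic
#' matrix over the top-k set, and applies the beta mean-threshold filter.
#'
#' @param modules a `thd_modules` object.
#' @param m the preprocessed `expr_matrix` (with sample classes).
#' @param ann an `annotation_index` (namespace typically BP).
#' @param mapping optional two-column mapping (see [map_ids()]); `NULL` uses
#'   expression gene IDs directly as annotation IDs.
#' @param k top-variance cut (default 2000).
#' @param de_stat,combine,rule passed to [rank_by_variance()],
#'   [gene_semantic_matrix()] and [select_interesting()].
#' @return an `interesting_report`: `border_pool`, `ranked`, `k_selected`,
#'   `mapping` (data.frame from/to for the selected genes), `semantic`
#'   (`semantic_matrix`), `beta`, `interesting` (annotation-side IDs),
#'   `per_gene` table with provenance (`module_id`).
#' @export
find_interesting_genes <- function(modules, m, ann, mapping = NULL,
                                   k = 2000L, de_stat = "variance",
                                   combine = "bma", rule = "any") {
  stopifnot(inherits(modules, "thd_modules"))
  pool <- border_pool(modules)
  if (!nrow(pool)) stop("no border genes were marked; nothing to prioritize")
  ranking <- rank_by_variance(pool$gene_id, m, k = k, de_stat = de_stat)

  if (is.null(mapping)) {
    map <- data.frame(from = ranking$top, to = ranking$top,
                      stringsAsFactors = FALSE)
    unmapped <- character(0)
  } else {
    mm <- map_ids(ranking$top, mapping)
    map <- mm$mapped
    unmapped <- mm$unmapped
  }
  if (nrow(map) < 2L)
    stop("fewer than 2 of the selected border genes could be mapped")

  sem <- gene_semantic_matrix(map$to, ann, combine = combine)
  sel <- select_interesting(sem, rule = rule)

  per_gene <- sel$per_gene
  per_gene$from <- map$from[match(per_gene$gene_id, map$to)]
  per_gene$module_id <- pool$module_id[match(per_gene$from, pool$gene_id)]
  per_gene$variance_score <-
    ranking$ranked$score[match(per_gene$from, ranking$ranked$gene_id)]

  structure(
    list(border_pool = pool, ranked = ranking$ranked,
         k_selected = ranking$top, mapping = map, unmapped = unmapped,
         semantic = sem, beta = sel$beta, interesting = sel$interesting,
         per_gene = per_gene),
    class = "interesting_report"
  )
}

#' @export
print.interesting_report <- function(x, ...) {
  cat(sprintf(
    "interesting_report: %d border genes -> top %d by variance -> beta = %.4f -> %d interesting\n",
    nrow(x$border_pool), length(x$k_selected), x$beta, length(x$interesting)))
  invisible(x)
}
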