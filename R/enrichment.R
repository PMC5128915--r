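#' Exact hypergeometric over-representation p-value
#'
#' Upper-tail probability `P[X >= hits]` for a hypergeometric draw of
#' `module_size` genes from a population of `population` genes of which
#' `term_size` carry the annotation. Exact (via [stats::phyper()]), never
#' normal-approximated. A low p indicates the module hits the term more often
#' than a random gene set of the same size would.
#'
#' @param hits number of module genes annotated to the term.
#' @param module_size number of module genes in the population.
#' @param term_size number of population genes annotated to the term.
#' @param population total annotated genes.
#' @return p-value in (0, 1].
#' @export
hypergeom_p <- function(hits, module_size, term_size, population) {
  if (any(c(hits, module_size, term_size, population) < 0) ||
      hits > min(module_size, term_size) ||
      module_size > population || term_size > population)
    stop("inconsistent counts: need 0 <= hits <= min(module_size, term_size) <= population")
  stats::phyper(hits - 1, term_size, population - term_size, module_size,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' `q_i = min over ranks j >= i of p_(j) * m / j`, mapped back to input
#' order: the minimum false discovery rate at which each hypothesis would be
#' called significant. Delegates to [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in the input order; empty input gives an empty vector.
#' @export
bh_qvalues <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-module GO-term enrichment
#'
#' Tests every term annotated (under the true-path rule) to at least one
#' module gene against the annotation corpus: the population is all genes
#' with at least one annotation in the index's namespace, and q-values are
#' BH-adjusted within the module's own term family, mirroring per-module
#' enrichment tables.
#'
#' @param module a `gene_module` (from [extract_modules()]) or a character
#'   vector of gene IDs.
#' @param ann an `annotation_index`.
#' @return data.frame with columns `term_id`, `term_name`, `module_hits`,
#'   `module_size`, `term_size`, `population`, `p`, `q`, sorted by ascending
#'   p (term-ID tie-break). Empty (with a warning) when no module gene is in
#'   the corpus.
#' @export
enrich_module <- function(module, ann) {
  stopifnot(inherits(ann, "annotation_index"))
  genes <- if (inherits(module, "gene_module")) module$members else module
  genes <- intersect(unique(genes), names(ann$propagated))
  empty <- data.frame(term_id = character(), term_name = character(),
                      module_hits = integer(), module_size = integer(),
                      term_size = integer(), population = integer(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE)
  if (!length(genes)) {
    warning("no module gene found in the annotation corpus")
    return(empty)
  }
  hit_counts <- table(unlist(ann$propagated[genes], use.names = FALSE))
  terms <- names(hit_counts)
  p <- vapply(seq_along(terms), function(i)
    hypergeom_p(as.integer(hit_counts[[i]]), length(genes),
                ann$term_count[[terms[i]]], ann$corpus_size),
    numeric(1))
  out <- data.frame(
    term_id = terms,
    term_name = ann$ontology$terms$name[match(terms, ann$ontology$terms$id)],
    module_hits = as.integer(hit_counts),
    module_size = length(genes),
    term_size = as.integer(ann$term_count[terms]),
    population = ann$corpus_size,
    p = p,
    q = bh_qvalues(p),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
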