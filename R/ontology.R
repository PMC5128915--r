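#' Load an OBO ontology
#'
#' Minimal reader for OBO 1.2/1.4 term stanzas. Only `is_a` edges are kept by
#' default (`relationship: part_of` optionally included); obsolete terms are
#' dropped. The result partitions terms by namespace and records one root per
#' namespace (a term with no parents). The hierarchy must be a DAG.
#'
#' @param path path to an `.obo` file.
#' @param include_part_of also treat `relationship: part_of` as a parent edge.
#' @return an `ontology_index`: `$terms` data.frame (`id`, `name`,
#'   `namespace`), `$parents` named list of parent-ID vectors, `$ancestors`
#'   named list of ancestor IDs (transitive closure, including the term
#'   itself), `$roots` named character vector (namespace -> root ID).
#' @export
load_obo <- function(path, include_part_of = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  stanza_starts <- which(lines == "[Term]")
  if (!length(stanza_starts)) stop("no [Term] stanzas found in ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  # any stanza header ends the previous term
  other <- which(grepl("^\\[", lines) & lines != "[Term]")

  ids <- character(); nms <- character(); nss <- character()
  parents <- list()
  for (k in seq_along(stanza_starts)) {
    from <- stanza_starts[k] + 1L
    to <- bounds[k + 1L] - 1L
    cut <- other[other >= from & other <= to]
    if (length(cut)) to <- min(cut) - 1L
    if (to < from) next
    block <- lines[from:to]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), block,
                                                 value = TRUE))
      if (length(v)) v else NA_character_
    }
    if (!is.na(get1("is_obsolete")) && get1("is_obsolete")[1L] == "true") next
    id <- get1("id")[1L]
    if (is.na(id)) next
    isa <- sub(" *!.*$", "", sub("^is_a: *", "",
                                 grep("^is_a:", block, value = TRUE)))
    if (include_part_of) {
      po <- grep("^relationship: *part_of ", block, value = TRUE)
      po <- sub(" *!.*$", "", sub("^relationship: *part_of *", "", po))
      isa <- c(isa, po)
    }
    ids <- c(ids, id)
    nms <- c(nms, get1("name")[1L])
    nss <- c(nss, get1("namespace")[1L])
    parents[[id]] <- isa
  }
  if (anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    nms <- nms[keep]; nss <- nss[keep]; ids <- ids[keep]
  }
  nss[is.na(nss)] <- "default"
  # drop dangling parent references (e.g. edges into obsolete terms)
  parents <- lapply(parents[ids], function(p) p[p %in% ids])

  anc <- ancestor_closure(ids, parents)
  has_parent <- lengths(parents) > 0L
  roots <- vapply(split(ids, nss), function(g) {
    r <- g[!has_parent[match(g, ids)]]
    if (length(r) != 1L)
      warning("namespace with ", length(r), " roots; using the first")
    sort(r)[1L]
  }, character(1))

  structure(
    list(terms = data.frame(id = ids, name = nms, namespace = nss,
                            stringsAsFactors = FALSE),
         parents = parents, ancestors = anc, roots = roots),
    class = "ontology_index"
  )
}

# Kahn topological sort + transitive closure; errors on cycles, naming them.
ancestor_closure <- function(ids, parents) {
  n_parents <- lengths(parents)
  children <- list()
  for (id in ids)
    for (p in parents[[id]])
      children[[p]] <- c(children[[p]], id)
  remaining <- stats::setNames(n_parents, ids)
  queue <- ids[n_parents == 0L]
  order <- character(0)
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, t)
    for (ch in children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids))
    stop("is_a cycle detected involving: ",
         paste(ids[!ids %in% order], collapse = ", "))
  anc <- list()
  for (t in order) {
    up <- unique(unlist(anc[parents[[t]]], use.names = FALSE))
    anc[[t]] <- c(t, up)
  }
  anc[ids]
}

#' @export
print.ontology_index <- function(x, ...) {
  cat(sprintf("ontology_index: %d terms, %d namespaces (%s)\n",
              nrow(x$terms), length(x$roots),
              paste(names(x$roots), collapse = ", ")))
  invisible(x)
}

#' Ancestors of a term (including itself)
#' @param ont an `ontology_index`.
#' @param term term ID.
#' @return character vector of ancestor term IDs.
#' @export
term_ancestors <- function(ont, term) {
  a <- ont$ancestors[[term]]
  if (is.null(a)) stop("unknown term: ", term)
  a
}

#' Load gene -> GO annotations
#'
#' Accepts GAF 2.1/2.2 (column 2 = gene ID, column 5 = term, column 7 =
#' evidence code) or a headerless two-column TSV (gene, term). Annotations are
#' restricted to one namespace, propagated to all ancestors (true-path rule),
#' and per-term annotated-gene counts are computed. Genes with no resolvable
#' annotation in the namespace are excluded from the corpus.
#'
#' @param path annotation file (GAF if any line has >= 15 tab fields,
#'   two-column TSV otherwise).
#' @param ont an `ontology_index`.
#' @param namespace which namespace to keep: `"BP"`, `"MF"`, `"CC"`, a full
#'   namespace name such as `"biological_process"`, or `NULL` for all.
#' @param exclude_iea drop GAF rows with evidence code IEA.
#' @return an `annotation_index`: `$direct` and `$propagated` gene -> term-set
#'   lists, `$term_count` named counts, `$corpus_size`, `$namespace`,
#'   `$ontology` (the `ontology_index`, kept for similarity computations),
#'   `$skipped` data.frame of rows referencing unknown/out-of-namespace terms.
#' @export
load_annotations <- function(path, ont, namespace = "BP",
                             exclude_iea = FALSE) {
  stopifnot(inherits(ont, "ontology_index"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_gaf <- length(fields) > 0L && any(lengths(fields) >= 15L)
  if (is_gaf) {
    fields <- fields[lengths(fields) >= 9L]
    gene <- vapply(fields, `[[`, character(1), 2L)
    term <- vapply(fields, `[[`, character(1), 5L)
    evid <- vapply(fields, `[[`, character(1), 7L)
    if (exclude_iea) {
      keep <- evid != "IEA"
      gene <- gene[keep]; term <- term[keep]
    }
  } else {
    fields <- fields[lengths(fields) >= 2L]
    gene <- vapply(fields, `[[`, character(1), 1L)
    term <- vapply(fields, `[[`, character(1), 2L)
  }

  ns_full <- switch(namespace %||% "all",
                    BP = "biological_process", MF = "molecular_function",
                    CC = "cellular_component", all = NULL, namespace)
  known <- term %in% ont$terms$id
  in_ns <- known
  if (!is.null(ns_full)) {
    ns_of <- ont$terms$namespace[match(term, ont$terms$id)]
    in_ns <- known & ns_of == ns_full
  }
  skipped <- data.frame(gene = gene[!in_ns], term = term[!in_ns],
                        reason = ifelse(known[!in_ns], "other_namespace",
                                        "unknown_term"),
                        stringsAsFactors = FALSE)
  if (any(!known))
    warning(sum(!known), " annotation row(s) reference unknown terms; skipped")
  gene <- gene[in_ns]; term <- term[in_ns]

  direct <- lapply(split(term, gene), unique)
  propagated <- lapply(direct, function(ts)
    sort(unique(unlist(ont$ancestors[ts], use.names = FALSE))))
  counts <- table(unlist(propagated, use.names = FALSE))
  term_count <- stats::setNames(as.integer(counts), names(counts))

  structure(
    list(direct = direct, propagated = propagated, term_count = term_count,
         corpus_size = length(propagated), namespace = ns_full %||% "all",
         ontology = ont, skipped = skipped),
    class = "annotation_index"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index: %d genes, %d terms with counts (namespace %s)\n",
              x$corpus_size, length(x$term_count), x$namespace))
  invisible(x)
}

#' Information content of ontology terms
#'
#' `Ic(t) = -log2(term_count(t) / corpus_size)`: the negative log frequency
#' of genes annotated at or below the term under the true-path rule. The
#' namespace root covers the whole corpus, so `Ic(root) = 0`. Terms
#' annotating no gene have undefined (missing) information content.
#'
#' @param terms character vector of term IDs.
#' @param ann an `annotation_index`.
#' @return numeric vector of Ic values in bits; `NA` where undefined.
#' @export
information_content <- function(terms, ann) {
  stopifnot(inherits(ann, "annotation_index"))
  if (ann$corpus_size == 0L) stop("empty annotation corpus")
  cnt <- ann$term_count[terms]
  ic <- -log2(as.numeric(cnt) / ann$corpus_size) + 0   # +0 normalizes -0
  ic[is.na(cnt) | cnt == 0L] <- NA_real_
  stats::setNames(ic, terms)
}

#' Lin semantic similarity between two terms
#'
#' `sim(t1, t2) = 2 * Ic(MICA) / (Ic(t1) + Ic(t2))`, where the MICA is the
#' common ancestor of the two terms with maximal information content. The
#' score is 1 for an identical informative term and 0 when the only shared
#' ancestor is the (zero-Ic) root; two roots compare as 0 by convention.
#'
#' @param t1,t2 term IDs in the same namespace.
#' @param ann an `annotation_index` (carries its ontology).
#' @return similarity in \[0, 1\], or `NA` if either Ic is undefined.
#' @export
lin_similarity <- function(t1, t2, ann) {
  stopifnot(inherits(ann, "annotation_index"))
  ont <- ann$ontology
  ns <- ont$terms$namespace[match(c(t1, t2), ont$terms$id)]
  if (anyNA(ns)) stop("unknown term: ", paste(c(t1, t2)[is.na(ns)], collapse = ", "))
  if (ns[1L] != ns[2L])
    stop("cross-namespace comparison: ", t1, " (", ns[1L], ") vs ",
         t2, " (", ns[2L], ")")
  ic <- information_content(c(t1, t2), ann)
  if (anyNA(ic)) return(NA_real_)
  if (sum(ic) == 0) return(0)
  common <- intersect(ont$ancestors[[t1]], ont$ancestors[[t2]])
  mica_ic <- if (length(common)) {
    ca_ic <- information_content(common, ann)
    max(c(ca_ic[!is.na(ca_ic)], 0))
  } else 0
  min(1, 2 * mica_ic / sum(ic))
}

#' Gene-level semantic similarity matrix
#'
#' Scores each gene pair by combining Lin term similarities over the two
#' genes' direct annotation sets. The default combine rule is the best-match
#' average (BMA): each term is matched to its best counterpart in the other
#' gene's set and the matches are averaged over both directions;
#' `combine = "max"` takes the single best term pair instead.
#'
#' Genes with no resolvable annotation are excluded (with a warning, listed
#' in `attr(, "excluded")`). Genes annotated only to the root participate but
#' score 0 against everything including themselves, matching the invariant
#' that the diagonal is 1 exactly for genes with at least one informative
#' (Ic > 0) annotation.
#'
#' @param genes character vector of gene IDs.
#' @param ann an `annotation_index`.
#' @param combine `"bma"` (default) or `"max"`.
#' @return a `semantic_matrix`: symmetric `$scores` in \[0, 1\] over the
#'   retained genes, `$combine_rule`.
#' @export
gene_semantic_matrix <- function(genes, ann, combine = c("bma", "max")) {
  combine <- match.arg(combine)
  stopifnot(inherits(ann, "annotation_index"))
  genes <- unique(genes)
  term_sets <- ann$direct[genes]
  names(term_sets) <- genes
  annotated <- !vapply(term_sets, is.null, logical(1))
  if (any(!annotated))
    warning(sum(!annotated), " gene(s) without ", ann$namespace,
            " annotations excluded from the semantic matrix")
  excluded <- genes[!annotated]
  genes <- genes[annotated]
  if (length(genes) < 1L) stop("no annotated genes to compare")
  term_sets <- term_sets[genes]

  all_terms <- unique(unlist(term_sets, use.names = FALSE))
  term_sim <- matrix(NA_real_, length(all_terms), length(all_terms),
                     dimnames = list(all_terms, all_terms))
  for (i in seq_along(all_terms))
    for (j in i:length(all_terms))
      term_sim[i, j] <- term_sim[j, i] <-
        lin_similarity(all_terms[i], all_terms[j], ann)

  n <- length(genes)
  scores <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m <- term_sim[term_sets[[i]], term_sets[[j]], drop = FALSE]
      if (all(is.na(m))) next
      s <- if (combine == "max") max(m, na.rm = TRUE) else {
        rmax <- apply(m, 1L, max, na.rm = TRUE)
        cmax <- apply(m, 2L, max, na.rm = TRUE)
        (sum(rmax) + sum(cmax)) / (length(rmax) + length(cmax))
      }
      scores[i, j] <- scores[j, i] <- min(1, s)
    }
  }
  out <- structure(list(scores = scores, combine_rule = combine),
                   class = "semantic_matrix")
  attr(out, "excluded") <- excluded
  out
}

#' @export
print.semantic_matrix <- function(x, ...) {
  cat(sprintf("semantic_matrix: %d genes (combine = %s)\n",
              nrow(x$scores), x$combine_rule))
  invisible(x)
}
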