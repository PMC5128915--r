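#' Run the full module-extraction and gene-prioritization workflow
#'
#' Executes preprocess -> similarity -> threshold-decrement extraction ->
#' border pool -> variance ranking / ID mapping -> semantic matrix ->
#' beta filter -> per-module enrichment, and optionally writes every table
#' plus a JSON run manifest to `out_dir`. The run is deterministic given
#' (inputs, config): no stage draws random numbers.
#'
#' @param expr an `expr_matrix`, or a path to an expression TSV.
#' @param ann an `annotation_index`, or `NULL` to stop after extraction.
#' @param config a `thd_config`.
#' @param k top-variance cut for the border pool (default 2000).
#' @param mapping optional ID mapping (see [map_ids()]).
#' @param measure similarity measure (see [expression_similarity()]).
#' @param combine,rule semantic combine rule and interesting-gene rule.
#' @param class_file optional sample-class sidecar, used when `expr` is a
#'   path.
#' @param out_dir optional output directory; created if absent.
#' @param log if `TRUE`, print per-threshold module counts and stage
#'   summaries.
#' @return a `coexmod_run`: `expr` (preprocessed), `similarity`, `modules`,
#'   `interesting` (an `interesting_report`, or `NULL` when `ann` is `NULL`
#'   or no border genes exist), `enrichment` (list of per-module tables, or
#'   `NULL`), `manifest` (list).
#' @export
run_pipeline <- function(expr, ann = NULL, config = thd_config(),
                         k = 2000L, mapping = NULL,
                         measure = "abspearson", combine = "bma",
                         rule = "any", class_file = NULL, out_dir = NULL,
                         log = FALSE) {
  say <- function(...) if (log) message(sprintf(...))
  input_digest <- NA_character_
  if (is.character(expr) && length(expr) == 1L) {
    input_digest <- unname(tools::md5sum(expr))
    expr <- read_expression(expr, class_file = class_file)
  }
  stopifnot(inherits(expr, "expr_matrix"), inherits(config, "thd_config"))

  n_in <- nrow(expr$values)
  expr <- preprocess_expression(expr)
  say("preprocess: %d -> %d genes (removed %d unformatted, %d all-missing, %d duplicate)",
      n_in, nrow(expr$values), expr$report$unformatted,
      expr$report$all_missing, expr$report$duplicate)

  sim <- similarity_matrix(expr, measure = measure)
  say("similarity: %s pair evaluations (%s)",
      format(attr(sim, "n_evaluations"), big.mark = ","), measure)

  modules <- extract_modules(sim, config)
  if (log)
    for (i in seq_along(modules$delta_counts))
      say("delta %s: %d module(s)", names(modules$delta_counts)[i],
          modules$delta_counts[i])
  say("extracted %d module(s); %d gene(s) unassigned",
      length(modules$modules), length(modules$unassigned))

  interesting <- NULL
  enrichment <- NULL
  if (!is.null(ann)) {
    stopifnot(inherits(ann, "annotation_index"))
    if (nrow(border_pool(modules)) >= 2L) {
      interesting <- find_interesting_genes(modules, expr, ann,
                                            mapping = mapping, k = k,
                                            combine = combine, rule = rule)
      say("beta = %.4f; %d interesting gene(s)", interesting$beta,
          length(interesting$interesting))
    } else say("fewer than 2 border genes; skipping prioritization")
    enrichment <- lapply(modules$modules, enrich_module, ann = ann)
    names(enrichment) <- vapply(modules$modules, function(m)
      paste0("module_", m$module_id), character(1))
  }

  manifest <- list(
    tool = paste0("coexmod ", as.character(utils::packageVersion("coexmod"))),
    input_digest = input_digest,
    config = unclass(config), k = k,
    measure = measure, combine = combine, rule = rule,
    counts = list(
      genes_in = n_in, genes_used = nrow(expr$values),
      modules = length(modules$modules),
      unassigned = length(modules$unassigned),
      border_pool = nrow(border_pool(modules)),
      interesting = if (is.null(interesting)) NA_integer_
                    else length(interesting$interesting)),
    beta = if (is.null(interesting)) NA_real_ else interesting$beta)

  run <- structure(list(expr = expr, similarity = sim, modules = modules,
                        interesting = interesting, enrichment = enrichment,
                        manifest = manifest),
                   class = "coexmod_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.coexmod_run <- function(x, ...) {
  m <- x$manifest$counts
  cat(sprintf("coexmod_run: %d genes -> %d modules (%d border genes)",
              m$genes_used, m$modules, m$border_pool))
  if (!is.na(x$manifest$beta))
    cat(sprintf("; beta = %.4f, %d interesting", x$manifest$beta,
                m$interesting))
  cat("\n")
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits `modules.tsv` (module_id, gene_id, role, delta), `interesting.tsv`
#' (per-gene semantic summary), per-module `enrichment_module_<i>.tsv`, and
#' `manifest.json`.
#'
#' @param run a `coexmod_run`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "coexmod_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(module_table(run$modules, include_unassigned = TRUE),
                     file.path(out_dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$interesting))
    utils::write.table(run$interesting$per_gene,
                       file.path(out_dir, "interesting.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(run$enrichment))
    utils::write.table(run$enrichment[[nm]],
                       file.path(out_dir, paste0("enrichment_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(out_dir)
}
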