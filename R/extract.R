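#' Configuration for threshold-decrement module extraction
#'
#' The extractor sweeps the similarity threshold `delta` downwards from
#' `delta_start` to `delta_end` in steps of `alpha` (defaults visit
#' 0.9, 0.8, 0.7, 0.6, 0.5). At each threshold it repeatedly seeds a module
#' at the highest-degree unassigned gene whose degree is at least `rho`, the
#' minimum neighborhood threshold.
#'
#' @param delta_start,delta_end sweep bounds, `0 < delta_end <= delta_start <= 1`.
#' @param alpha per-iteration decrement (> 0).
#' @param rho minimum neighborhood threshold (>= 1); a gene qualifies as a
#'   module core only with at least `rho` direct neighbors, and a member with
#'   fewer than `rho` neighbors is a border gene.
#' @param degree_scope `"unassigned"` (default) computes degrees on the graph
#'   restricted to still-unassigned genes; `"full"` uses the whole network.
#' @return a `thd_config` list.
#' @export
thd_config <- function(delta_start = 0.9, delta_end = 0.5, alpha = 0.1,
                       rho = 3L, degree_scope = c("unassigned", "full")) {
  degree_scope <- match.arg(degree_scope)
  if (!(delta_start > 0 && delta_start <= 1) || delta_end <= 0 ||
      delta_end > delta_start)
    stop("need 0 < delta_end <= delta_start <= 1")
  if (alpha <= 0) stop("`alpha` must be > 0")
  rho <- as.integer(rho)
  if (rho < 1L) stop("`rho` must be >= 1")
  structure(list(delta_start = delta_start, delta_end = delta_end,
                 alpha = alpha, rho = rho, degree_scope = degree_scope),
            class = "thd_config")
}

#' Threshold schedule of a configuration
#' @param cfg a `thd_config`.
#' @return decreasing vector of thresholds visited by [extract_modules()].
#' @export
delta_schedule <- function(cfg) {
  n_steps <- floor((cfg$delta_start - cfg$delta_end) / cfg$alpha + 1e-9)
  cfg$delta_start - cfg$alpha * (0:n_steps)
}

degrees_within <- function(net, genes) {
  sub <- net$adjacency[genes, genes, drop = FALSE]
  rowSums(sub)
}

#' Select a module core gene
#'
#' The core is the unassigned gene of maximum degree (ties broken by
#' lexicographically smallest gene ID), provided that degree is at least
#' `rho`; degrees are counted on the subgraph induced by `unassigned`, so
#' edges to already-assigned genes do not inflate a candidate.
#'
#' @param net a `coexpr_network`.
#' @param unassigned character vector of candidate gene IDs.
#' @param rho minimum neighborhood threshold.
#' @return the core gene ID, or `NULL` when no candidate reaches `rho`.
#' @export
select_core <- function(net, unassigned, rho) {
  stopifnot(inherits(net, "coexpr_network"))
  if (!length(unassigned)) return(NULL)
  deg <- degrees_within(net, unassigned)
  if (max(deg) < rho) return(NULL)
  cand <- names(deg)[deg == max(deg)]
  sort(cand)[1L]
}

#' Grow a module from its core
#'
#' Members are the connected component of the subgraph induced on unassigned
#' genes that contains the core: any gene reachable from the core through a
#' chain of above-threshold similarities joins, so membership is multi-hop.
#'
#' @param net a `coexpr_network`.
#' @param core core gene ID; must belong to `unassigned`.
#' @param unassigned character vector of gene IDs still available.
#' @return character vector of member gene IDs (includes the core), in
#'   gene-ID order.
#' @export
grow_module <- function(net, core, unassigned) {
  stopifnot(inherits(net, "coexpr_network"))
  if (!core %in% unassigned) stop("core gene is not in the unassigned set")
  sub <- net$adjacency[unassigned, unassigned, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  comp <- igraph::components(g)
  members <- unassigned[comp$membership == comp$membership[[core]]]
  sort(members)
}

#' Mark border genes of a module
#'
#' A border gene is a member whose direct-neighbor count at the extraction
#' threshold is below `rho`: it joined the module through above-threshold
#' similarity to some member, but is only loosely connected. By default
#' degrees are counted within `scope_genes` (the unassigned set at extraction
#' time; since members form a connected component of that induced subgraph
#' this equals the within-module degree). `scope_genes = NULL` uses the full
#' network.
#'
#' @param net a `coexpr_network` at the module's extraction delta.
#' @param members character vector of module member gene IDs.
#' @param rho minimum neighborhood threshold.
#' @param scope_genes genes defining the degree context (default `members`);
#'   `NULL` means the full network.
#' @return character vector of border gene IDs (possibly empty).
#' @export
mark_border <- function(net, members, rho, scope_genes = members) {
  stopifnot(inherits(net, "coexpr_network"))
  deg <- if (is.null(scope_genes)) net$degrees[members]
         else degrees_within(net, scope_genes)[members]
  sort(members[deg < rho])
}

#' Extract co-expressed modules by threshold decrement
#'
#' For each threshold of [delta_schedule()] the network over still-unassigned
#' genes is rebuilt from the same similarity matrix and modules are peeled
#' off: select the highest-degree core (degree >= `rho`), grow its connected
#' component, mark low-degree members as border genes, remove the members
#' from play, and repeat until no core qualifies; then decrement the
#' threshold. Modules are pairwise disjoint, each records the threshold it
#' was extracted at, and genes never claimed by the time `delta_end` is
#' passed are reported as unassigned.
#'
#' @param s a `sim_matrix`.
#' @param cfg a `thd_config`.
#' @return a `thd_modules` object: `$modules` is a list of `gene_module`s
#'   (fields `module_id`, `core_gene`, `core_degree`, `members`,
#'   `border_genes`, `delta`), `$unassigned` the leftover gene IDs, `$config`
#'   the configuration, and `$delta_counts` the number of modules found per
#'   threshold.
#' @export
extract_modules <- function(s, cfg = thd_config()) {
  stopifnot(inherits(s, "sim_matrix"), inherits(cfg, "thd_config"))
  genes <- rownames(s$scores)
  unassigned <- genes
  modules <- list()
  deltas <- delta_schedule(cfg)
  delta_counts <- stats::setNames(integer(length(deltas)),
                                  formatC(deltas, format = "g"))

  for (di in seq_along(deltas)) {
    delta <- deltas[di]
    if (length(unassigned) < cfg$rho + 1L) break
    net <- build_network(s, delta)
    repeat {
      core <- select_core(net, unassigned, cfg$rho)
      if (is.null(core)) break
      members <- grow_module(net, core, unassigned)
      scope <- if (cfg$degree_scope == "unassigned") unassigned else NULL
      border <- mark_border(net, members, cfg$rho, scope_genes = scope)
      core_degree <- as.integer(degrees_within(net, unassigned)[core])
      modules[[length(modules) + 1L]] <- structure(
        list(module_id = length(modules) + 1L,
             core_gene = core,
             core_degree = core_degree,
             members = members,
             border_genes = setdiff(border, core),
             delta = delta),
        class = "gene_module"
      )
      delta_counts[di] <- delta_counts[di] + 1L
      unassigned <- setdiff(unassigned, members)
    }
  }

  structure(list(modules = modules, unassigned = unassigned, config = cfg,
                 delta_counts = delta_counts),
            class = "thd_modules")
}

#' @export
print.thd_modules <- function(x, ...) {
  cat(sprintf("thd_modules: %d modules, %d genes unassigned\n",
              length(x$modules), length(x$unassigned)))
  for (m in x$modules)
    cat(sprintf("  module %d (delta %.2f): core %s (degree %d), %d members, %d border\n",
                m$module_id, m$delta, m$core_gene, m$core_degree,
                length(m$members), length(m$border_genes)))
  invisible(x)
}

#' Tabulate module membership
#'
#' @param x a `thd_modules` object.
#' @param include_unassigned if `TRUE`, append unassigned genes with
#'   `module_id = NA` and role `"unassigned"`.
#' @return data.frame with columns `module_id`, `gene_id`,
#'   `role` (`core` / `member` / `border`), `delta`.
#' @export
module_table <- function(x, include_unassigned = FALSE) {
  stopifnot(inherits(x, "thd_modules"))
  rows <- lapply(x$modules, function(m) {
    role <- ifelse(m$members == m$core_gene, "core",
                   ifelse(m$members %in% m$border_genes, "border", "member"))
    data.frame(module_id = m$module_id, gene_id = m$members, role = role,
               delta = m$delta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out))
    out <- data.frame(module_id = integer(), gene_id = character(),
                      role = character(), delta = numeric(),
                      stringsAsFactors = FALSE)
  if (include_unassigned && length(x$unassigned))
    out <- rbind(out, data.frame(module_id = NA_integer_,
                                 gene_id = x$unassigned, role = "unassigned",
                                 delta = NA_real_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Pool border genes across modules
#'
#' @param x a `thd_modules` object.
#' @return data.frame with columns `gene_id`, `module_id` (first module a
#'   gene was marked border in; modules are disjoint so each gene appears
#'   once).
#' @export
border_pool <- function(x) {
  stopifnot(inherits(x, "thd_modules"))
  rows <- lapply(x$modules, function(m)
    if (length(m$border_genes))
      data.frame(gene_id = m$border_genes, module_id = m$module_id,
                 stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), module_id = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
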