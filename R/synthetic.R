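# Run code under a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  code
}

#' Specification for synthetic expression data
#'
#' Describes a planted-structure benchmark: `n_modules` gene modules whose
#' members are affine transforms (`a * base + b`, exercising shifting,
#' scaling and shifting-and-scaling patterns, negative `a` included) of a
#' module base profile plus Gaussian noise; uncorrelated background genes;
#' and a two-class (normal/disease) sample design in which differentially
#' expressed modules and background genes receive a class-mean shift.
#'
#' @param n_modules number of planted modules.
#' @param module_sizes integer vector of module sizes (recycled to
#'   `n_modules`).
#' @param n_background number of background genes (i.i.d. standard normal).
#' @param n_samples_per_class samples per class; the design has two classes.
#' @param noise_sigma standard deviation of additive Gaussian noise on
#'   module members (0 = exact affine patterns).
#' @param scale_range magnitude range for scale factors `a`; the sign of `a`
#'   is random, so negative scaling is exercised.
#' @param shift_range range for shifts `b`.
#' @param de_fraction expected fraction of differentially expressed genes; a
#'   whole module is DE or not (the class shift enters its base profile, so
#'   affine relatedness within the module is preserved), background genes are
#'   flagged individually.
#' @param de_shift class-mean shift added to disease samples of DE genes.
#' @param seed RNG seed; every generator is a pure function of (spec, seed).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_modules = 2L, module_sizes = c(6L, 5L),
                           n_background = 20L, n_samples_per_class = 14L,
                           noise_sigma = 0.1, scale_range = c(0.5, 2),
                           shift_range = c(-1, 1), de_fraction = 0.3,
                           de_shift = 2, seed = 1L) {
  module_sizes <- rep_len(as.integer(module_sizes), n_modules)
  if (any(module_sizes < 1L) || n_background < 0L || n_samples_per_class < 1L)
    stop("sizes must be positive")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (min(scale_range) <= 0) stop("`scale_range` magnitudes must exclude 0")
  if (de_fraction < 0 || de_fraction > 1) stop("`de_fraction` must be in [0, 1]")
  structure(list(n_modules = as.integer(n_modules),
                 module_sizes = module_sizes,
                 n_background = as.integer(n_background),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 noise_sigma = noise_sigma, scale_range = scale_range,
                 shift_range = shift_range, de_fraction = de_fraction,
                 de_shift = de_shift, seed = as.integer(seed)),
            class = "synthetic_spec")
}

synthetic_gene_ids <- function(spec) {
  mod <- unlist(lapply(seq_len(spec$n_modules), function(i)
    sprintf("m%d_g%02d", i, seq_len(spec$module_sizes[i]))))
  bg <- if (spec$n_background)
    sprintf("bg_g%03d", seq_len(spec$n_background)) else character(0)
  list(module = mod, background = bg,
       module_of = rep(seq_len(spec$n_modules), spec$module_sizes))
}

#' Generate a planted-module expression matrix
#'
#' @param spec a `synthetic_spec`.
#' @return list with `expr` (an `expr_matrix`; samples `n1..` labelled
#'   `normal`, `d1..` labelled `disease`) and `truth` (data.frame `gene_id`,
#'   `module` — 0 for background — and logical `is_de`). Identical specs
#'   (including seed) give bit-identical output.
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n_s <- 2L * spec$n_samples_per_class
    disease <- c(rep(FALSE, spec$n_samples_per_class),
                 rep(TRUE, spec$n_samples_per_class))
    ids <- synthetic_gene_ids(spec)
    module_de <- stats::runif(spec$n_modules) < spec$de_fraction
    bg_de <- stats::runif(spec$n_background) < spec$de_fraction

    rows <- list()
    for (mi in seq_len(spec$n_modules)) {
      base <- stats::rnorm(n_s)
      if (module_de[mi]) base <- base + spec$de_shift * disease
      for (gi in seq_len(spec$module_sizes[mi])) {
        a <- stats::runif(1, spec$scale_range[1], spec$scale_range[2]) *
          sample(c(-1, 1), 1L)
        b <- stats::runif(1, spec$shift_range[1], spec$shift_range[2])
        rows[[length(rows) + 1L]] <-
          a * base + b + stats::rnorm(n_s, sd = spec$noise_sigma)
      }
    }
    for (gi in seq_len(spec$n_background)) {
      v <- stats::rnorm(n_s)
      if (bg_de[gi]) v <- v + spec$de_shift * disease
      rows[[length(rows) + 1L]] <- v
    }
    vals <- do.call(rbind, rows)
    rownames(vals) <- c(ids$module, ids$background)
    colnames(vals) <- c(sprintf("n%02d", seq_len(spec$n_samples_per_class)),
                        sprintf("d%02d", seq_len(spec$n_samples_per_class)))
    expr <- expr_matrix(vals, sample_class = ifelse(disease, "disease",
                                                    "normal"))
    truth <- data.frame(
      gene_id = rownames(vals),
      module = c(ids$module_of, rep(0L, spec$n_background)),
      is_de = c(module_de[ids$module_of], bg_de),
      stringsAsFactors = FALSE)
    list(expr = expr, truth = truth)
  })
}

#' Generate a toy ontology mirroring planted modules
#'
#' Builds a small biological_process DAG with one subtree per planted
#' module: a branch term under the root with two leaf terms each. Module
#' members are annotated alternately to their module's leaves (so
#' within-module gene pairs share an informative ancestor), background genes
#' are annotated to the root only. The emitted OBO and GAF texts use the
#' dialects [load_obo()] and [load_annotations()] consume.
#'
#' @param spec a `synthetic_spec` (only the module structure is used; the
#'   output is deterministic and does not draw random numbers).
#' @return list with `obo` and `gaf` character vectors (file lines) and
#'   `write(dir)`-style helper fields `obo_path`/`gaf_path` left `NULL`; use
#'   [writeLines()] to persist.
#' @export
generate_toy_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ids <- synthetic_gene_ids(spec)
  root <- "GO:0000001"
  term_id <- function(k) sprintf("GO:%07d", k)
  obo <- c("format-version: 1.2", "ontology: toy", "",
           "[Term]", paste0("id: ", root), "name: biological_process",
           "namespace: biological_process", "")
  ann_gene <- character(); ann_term <- character()
  k <- 1L
  for (mi in seq_len(spec$n_modules)) {
    branch <- term_id(k + 1L)
    leaves <- c(term_id(k + 2L), term_id(k + 3L))
    k <- k + 3L
    obo <- c(obo,
             "[Term]", paste0("id: ", branch),
             sprintf("name: module %d process", mi),
             "namespace: biological_process",
             paste0("is_a: ", root, " ! biological_process"), "")
    for (li in 1:2)
      obo <- c(obo,
               "[Term]", paste0("id: ", leaves[li]),
               sprintf("name: module %d subprocess %d", mi, li),
               "namespace: biological_process",
               sprintf("is_a: %s ! module %d process", branch, mi), "")
    members <- ids$module[ids$module_of == mi]
    ann_gene <- c(ann_gene, members)
    ann_term <- c(ann_term, leaves[(seq_along(members) - 1L) %% 2L + 1L])
  }
  ann_gene <- c(ann_gene, ids$background)
  ann_term <- c(ann_term, rep(root, length(ids$background)))

  gaf <- c("!gaf-version: 2.2",
           vapply(seq_along(ann_gene), function(i)
             paste(c("TOY", ann_gene[i], ann_gene[i], "", ann_term[i],
                     "TOY:0001", "EXP", "", "P", "", "", "protein",
                     "taxon:0000", "20160101", "TOY", "", ""),
                   collapse = "\t"),
             character(1)))
  list(obo = obo, gaf = gaf)
}

# n-1 mean-zero orthonormal columns for exact designed correlations
helmert_basis <- function(n, k) {
  if (k > n - 1L) stop("need at least ", k + 1L, " samples for ", k,
                       " orthonormal directions")
  q <- qr.Q(qr(cbind(1, stats::contr.helmert(n))))
  q[, 1L + seq_len(k), drop = FALSE]
}

#' Construct an exact core/border benchmark module
#'
#' Builds an expression matrix whose Pearson correlations are exactly the
#' designed values (profiles are linear combinations of mean-zero
#' orthonormal basis vectors): a clique of `rho + 1` mutually-adjacent dense
#' genes at threshold `delta`, plus border genes `b_j` (j = 1..rho-1)
#' connected to exactly `j` dense members, plus orthogonal background genes.
#' The expected role of every gene (core = maximum degree with
#' lexicographic tie-break, border = degree below `rho`) is derived from the
#' designed adjacency and returned.
#'
#' @param rho minimum neighborhood threshold the scenario targets (>= 1;
#'   feasible at `delta = 0.9` up to about 6).
#' @param delta similarity threshold the design is exact for.
#' @param n_background number of orthogonal background genes.
#' @return list with `expr` (an `expr_matrix` with two dummy classes),
#'   `roles` (data.frame `gene_id`, `role` in core/member/border/background,
#'   `degree`), `adjacency` (the designed module adjacency), `delta`, `rho`.
#' @export
generate_border_scenario <- function(rho = 3L, delta = 0.9,
                                     n_background = 4L) {
  rho <- as.integer(rho)
  if (rho < 1L) stop("`rho` must be >= 1")
  if (delta <= 0 || delta >= 1) stop("`delta` must be in (0, 1)")
  n_dense <- rho + 1L
  n_border <- max(rho - 1L, 0L)
  w2 <- (1 / delta - 1) / 2        # dense-dense cor = 1/(1+w2) >= delta
  A <- 1 + w2
  h2 <- numeric(n_border)
  for (j in seq_len(n_border)) {
    lo <- max(1 / (delta^2 * A) - 1 - j * w2, 0)
    hi <- A / delta^2 - 1 - j * w2
    if (hi <= lo)
      stop("border design infeasible for rho = ", rho, " at delta = ", delta)
    h2[j] <- (lo + hi) / 2
  }

  n_dir <- 1L + n_dense + n_border + n_background
  n_s <- n_dir + 1L + (n_dir + 1L) %% 2L   # even, for two dummy classes
  V <- helmert_basis(n_s, n_dir)
  v0 <- V[, 1L]
  v_dense <- V[, 1L + seq_len(n_dense), drop = FALSE]
  v_border <- V[, 1L + n_dense + seq_len(n_border), drop = FALSE]
  v_bg <- V[, 1L + n_dense + n_border + seq_len(n_background), drop = FALSE]

  profiles <- list(); ids <- character()
  for (i in seq_len(n_dense)) {
    profiles[[length(profiles) + 1L]] <- v0 + sqrt(w2) * v_dense[, i]
    ids <- c(ids, sprintf("d%02d", i))
  }
  for (j in seq_len(n_border)) {
    # attach b_j to dense members 2..(j+1)
    att <- rowSums(v_dense[, 1L + seq_len(j), drop = FALSE])
    profiles[[length(profiles) + 1L]] <-
      v0 + sqrt(w2) * att + sqrt(h2[j]) * v_border[, j]
    ids <- c(ids, sprintf("b%02d", j))
  }
  for (g in seq_len(n_background)) {
    profiles[[length(profiles) + 1L]] <- v_bg[, g]
    ids <- c(ids, sprintf("bg%02d", g))
  }
  vals <- do.call(rbind, profiles)
  rownames(vals) <- ids
  colnames(vals) <- sprintf("s%02d", seq_len(n_s))
  cls <- rep(c("normal", "disease"), each = n_s / 2L)
  expr <- expr_matrix(vals, sample_class = cls)

  # designed adjacency over module genes
  n_mod <- n_dense + n_border
  adj <- matrix(FALSE, n_mod, n_mod,
                dimnames = list(ids[seq_len(n_mod)], ids[seq_len(n_mod)]))
  adj[seq_len(n_dense), seq_len(n_dense)] <- TRUE
  diag(adj) <- FALSE
  for (j in seq_len(n_border))
    for (i in 1L + seq_len(j)) {
      adj[n_dense + j, i] <- TRUE
      adj[i, n_dense + j] <- TRUE
    }

  # self-check: realized correlations reproduce the designed adjacency
  realized <- abs(suppressWarnings(stats::cor(t(vals))))
  realized_adj <- realized[seq_len(n_mod), seq_len(n_mod)] >= delta
  diag(realized_adj) <- FALSE
  stopifnot(identical(unname(realized_adj), unname(adj)))
  bg_block <- realized[seq_len(n_mod), n_mod + seq_len(n_background),
                       drop = FALSE]
  stopifnot(all(bg_block < delta))

  deg <- rowSums(adj)
  core <- sort(names(deg)[deg == max(deg)])[1L]
  role <- ifelse(names(deg) == core, "core",
                 ifelse(deg < rho, "border", "member"))
  roles <- data.frame(
    gene_id = ids,
    role = c(role, rep("background", n_background)),
    degree = c(as.integer(deg), rep(0L, n_background)),
    stringsAsFactors = FALSE)
  list(expr = expr, roles = roles, adjacency = adj, delta = delta, rho = rho)
}
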