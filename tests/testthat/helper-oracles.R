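# Independent brute-force oracles used to cross-check the implementation.

# Pearson magnitude from the explicit sum formula, pairwise-complete.
bf_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  mx <- sum(x) / n; my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2)); sy <- sqrt(sum((y - my)^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  min(1, abs(sum((x - mx) * (y - my)) / (sx * sy)))
}

# All-pairs double loop over bf_pearson.
bf_similarity_matrix <- function(vals) {
  n <- nrow(vals)
  s <- matrix(NA_real_, n, n, dimnames = list(rownames(vals), rownames(vals)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      s[i, j] <- if (i == j) {
        v <- vals[i, ][is.finite(vals[i, ])]
        if (length(v) >= 2L && stats::sd(v) > 0) 1 else NA_real_
      } else bf_pearson(vals[i, ], vals[j, ])
  s
}

# Breadth-first connected component containing `start`.
bf_component <- function(adj, start) {
  visited <- start
  frontier <- start
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier,
                               function(v) colnames(adj)[adj[v, ]])))
    frontier <- setdiff(nb, visited)
    visited <- c(visited, frontier)
  }
  sort(visited)
}

# Border filter by explicit per-gene degree count within `scope`.
bf_border <- function(adj, members, rho, scope = members) {
  deg <- vapply(members, function(v) sum(adj[v, scope]), numeric(1))
  sort(members[deg < rho])
}

# Exact hypergeometric upper tail by combinatorial enumeration.
bf_hyper_tail <- function(hits, module_size, term_size, population) {
  i <- hits:min(module_size, term_size)
  sum(choose(term_size, i) * choose(population - term_size, module_size - i)) /
    choose(population, module_size)
}

# Direct BH step-up formula.
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Transitive closure of a parent map by iterated expansion
# (Floyd-Warshall-style fixed point), independent of the package's
# topological-sort closure.
bf_ancestors <- function(ids, parents) {
  anc <- lapply(ids, function(t) t)
  names(anc) <- ids
  repeat {
    changed <- FALSE
    for (t in ids) {
      up <- unique(c(anc[[t]], unlist(anc[parents[[t]]], use.names = FALSE)))
      if (length(up) > length(anc[[t]])) {
        anc[[t]] <- up
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  anc
}

# Random symmetric adjacency fixture with gene names.
random_adjacency <- function(n, p_edge = 0.25) {
  ids <- sprintf("g%02d", seq_len(n))
  adj <- matrix(stats::runif(n * n) < p_edge, n, n,
                dimnames = list(ids, ids))
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  adj
}

# Wrap an adjacency fixture as a sim_matrix/network pair for the extractor
# API: scores 1 where adjacent, 0 elsewhere.
network_from_adjacency <- function(adj, delta = 0.9) {
  s <- structure(list(scores = ifelse(adj, 1, 0), measure = "abspearson"),
                 class = "sim_matrix")
  diag(s$scores) <- 1
  build_network(s, delta)
}
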