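test_that("the default schedule visits 0.9 down to 0.5 in steps of 0.1", {
  expect_equal(delta_schedule(thd_config()), c(0.9, 0.8, 0.7, 0.6, 0.5))
  expect_equal(delta_schedule(thd_config(0.8, 0.6, 0.05)),
               seq(0.8, 0.6, by = -0.05))
  expect_error(thd_config(delta_start = 0.4, delta_end = 0.5), "delta")
  expect_error(thd_config(alpha = 0), "alpha")
  expect_error(thd_config(rho = 0), "rho")
})

star_adjacency <- function() {
  ids <- c("hub", "l1", "l2", "l3", "l4")
  adj <- matrix(FALSE, 5, 5, dimnames = list(ids, ids))
  adj["hub", c("l1", "l2", "l3", "l4")] <- TRUE
  adj[, "hub"] <- adj["hub", ]
  adj
}

test_that("core selection maximizes degree with the rho gate", {
  net <- network_from_adjacency(star_adjacency())
  expect_equal(select_core(net, rownames(net$adjacency), rho = 3), "hub")
  # path of 4 nodes: max degree 2 < rho = 3
  ids <- paste0("p", 1:4)
  path <- matrix(FALSE, 4, 4, dimnames = list(ids, ids))
  path[cbind(1:3, 2:4)] <- TRUE
  path <- path | t(path)
  expect_null(select_core(network_from_adjacency(path), ids, rho = 3))
  expect_null(select_core(net, character(0), rho = 1))
})

test_that("core selection matches the exhaustive degree oracle", {
  set.seed(5)
  for (rep in 1:30) {
    adj <- random_adjacency(8, 0.4)
    net <- network_from_adjacency(adj)
    unassigned <- sample(rownames(adj), sample(4:8, 1))
    deg <- vapply(unassigned, function(v) sum(adj[v, unassigned]), numeric(1))
    expected <- if (max(deg) < 2) NULL else
      sort(unassigned[deg == max(deg)])[1]   # lexicographic tie-break
    expect_identical(select_core(net, unassigned, rho = 2), expected)
  }
})

test_that("modules grow as connected components, multi-hop included", {
  ids <- c("a", "b", "c", "x", "y")
  adj <- matrix(FALSE, 5, 5, dimnames = list(ids, ids))
  adj["a", "b"] <- adj["b", "a"] <- TRUE
  adj["b", "c"] <- adj["c", "b"] <- TRUE
  adj["x", "y"] <- adj["y", "x"] <- TRUE
  net <- network_from_adjacency(adj)
  expect_equal(grow_module(net, "a", ids), c("a", "b", "c"))  # chain: 2 hops
  expect_equal(grow_module(net, "x", ids), c("x", "y"))
  expect_error(grow_module(net, "a", c("x", "y")), "unassigned")
  # restriction: removing the bridge gene cuts the component
  expect_equal(grow_module(net, "a", c("a", "c", "x", "y")), "a")
})

test_that("component growth agrees with a breadth-first oracle", {
  set.seed(8)
  for (rep in 1:30) {
    adj <- random_adjacency(sample(5:30, 1), 0.15)
    net <- network_from_adjacency(adj)
    start <- sample(rownames(adj), 1)
    expect_equal(grow_module(net, start, rownames(adj)),
                 bf_component(adj, start))
  }
})

test_that("border marking selects exactly the low-degree members", {
  net <- network_from_adjacency(star_adjacency())
  members <- rownames(net$adjacency)
  expect_equal(mark_border(net, members, rho = 3),
               c("l1", "l2", "l3", "l4"))
  # 4-clique: all degrees 3, no border at rho = 3
  ids <- paste0("k", 1:4)
  clique <- matrix(TRUE, 4, 4, dimnames = list(ids, ids))
  diag(clique) <- FALSE
  expect_equal(mark_border(network_from_adjacency(clique), ids, rho = 3),
               character(0))
  set.seed(13)
  for (rep in 1:30) {
    adj <- random_adjacency(sample(5:20, 1), 0.3)
    netr <- network_from_adjacency(adj)
    members <- sample(rownames(adj), sample(3:nrow(adj), 1))
    rho <- sample(1:4, 1)
    expect_equal(mark_border(netr, members, rho), bf_border(adj, members, rho))
  }
})

test_that("planted affine modules are recovered exactly at delta 0.9", {
  spec <- synthetic_spec(noise_sigma = 0, de_fraction = 0, seed = 20)
  gen <- generate_expression(spec)
  mods <- extract_modules(similarity_matrix(gen$expr))
  expect_length(mods$modules, 2L)
  expect_equal(vapply(mods$modules, `[[`, numeric(1), "delta"), c(0.9, 0.9))
  got <- lapply(mods$modules, `[[`, "members")
  planted <- split(gen$truth$gene_id, gen$truth$module)
  expect_setequal(got[[1]], planted[["1"]])
  expect_setequal(got[[2]], planted[["2"]])
  expect_setequal(mods$unassigned, planted[["0"]])
  expect_true(all(vapply(mods$modules, `[[`, integer(1), "core_degree") >= 3))
})

test_that("an edgeless similarity matrix yields zero modules", {
  ids <- paste0("g", 1:6)
  s <- structure(list(scores = matrix(0, 6, 6, dimnames = list(ids, ids)),
                      measure = "abspearson"), class = "sim_matrix")
  mods <- extract_modules(s, thd_config())
  expect_length(mods$modules, 0L)
  expect_setequal(mods$unassigned, ids)
})

test_that("extraction invariants hold on random similarity structures", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    ids <- sprintf("g%02d", 1:n)
    s <- matrix(runif(n * n), n, n)
    s <- (s + t(s)) / 2
    diag(s) <- 1
    dimnames(s) <- list(ids, ids)
    sm <- structure(list(scores = s, measure = "abspearson"),
                    class = "sim_matrix")
    cfg <- thd_config(rho = sample(2:4, 1))
    mods <- extract_modules(sm, cfg)
    members <- lapply(mods$modules, `[[`, "members")
    all_assigned <- unlist(members)
    # disjointness and full accounting
    expect_false(anyDuplicated(all_assigned) > 0)
    expect_setequal(c(all_assigned, mods$unassigned), ids)
    deltas <- vapply(mods$modules, `[[`, numeric(1), "delta")
    # genes claimed at higher delta are never reassigned below
    expect_true(all(diff(deltas) <= 1e-12))
    for (m in mods$modules) {
      expect_true(m$core_gene %in% m$members)
      expect_false(m$core_gene %in% m$border_genes)
      expect_true(all(m$border_genes %in% m$members))
      expect_gte(m$core_degree, cfg$rho)
      # role/degree consistency within the module at its delta
      net <- build_network(sm, m$delta)
      deg <- vapply(m$members, function(v) sum(net$adjacency[v, m$members]),
                    numeric(1))
      expect_setequal(m$border_genes,
                      setdiff(m$members[deg < cfg$rho], m$core_gene))
      expect_true(all(deg[setdiff(m$members,
                                  c(m$border_genes, m$core_gene))] >= cfg$rho))
    }
  }
})

test_that("core degree snapshot is maximal among unassigned at selection", {
  set.seed(77)
  n <- 25
  ids <- sprintf("g%02d", 1:n)
  s <- matrix(runif(n * n, 0.3, 1), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(ids, ids)
  sm <- structure(list(scores = s, measure = "abspearson"),
                  class = "sim_matrix")
  mods <- extract_modules(sm, thd_config())
  # replay the extraction, asserting maximality at each selection
  unassigned <- ids
  for (m in mods$modules) {
    net <- build_network(sm, m$delta)
    deg <- vapply(unassigned, function(v) sum(net$adjacency[v, unassigned]),
                  numeric(1))
    expect_equal(unname(deg[m$core_gene]), max(deg))
    unassigned <- setdiff(unassigned, m$members)
  }
})

test_that("module tables and border pools expose roles consistently", {
  spec <- synthetic_spec(noise_sigma = 0, de_fraction = 0, seed = 20)
  mods <- extract_modules(similarity_matrix(generate_expression(spec)$expr))
  tab <- module_table(mods, include_unassigned = TRUE)
  expect_setequal(unique(tab$role), c("core", "member", "unassigned"))
  expect_equal(sum(tab$role == "core"), length(mods$modules))
  pool <- border_pool(mods)
  expect_equal(nrow(pool), sum(tab$role == "border"))
})
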