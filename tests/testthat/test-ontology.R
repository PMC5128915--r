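test_that("a toy OBO loads with terms, edges and namespace roots", {
  fx <- toy_go_fixture()
  expect_equal(nrow(fx$ont$terms), 5L)
  expect_equal(sum(lengths(fx$ont$parents)), 4L)
  expect_equal(unname(fx$ont$roots["biological_process"]), "GO:0000001")
  expect_setequal(term_ancestors(fx$ont, "GO:0000003"),
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
})

test_that("obsolete terms are dropped and cycles are fatal", {
  dir <- withr_tempdir()
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0000001", "name: root",
           "namespace: biological_process", "",
           "[Term]", "id: GO:0000002", "name: live",
           "namespace: biological_process", "is_a: GO:0000001", "",
           "[Term]", "id: GO:0000009", "name: dead",
           "namespace: biological_process", "is_a: GO:0000001",
           "is_obsolete: true", "")
  p <- file.path(dir, "obs.obo")
  writeLines(obo, p)
  ont <- load_obo(p)
  expect_false("GO:0000009" %in% ont$terms$id)

  cyc <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0000001", "name: a",
           "namespace: biological_process", "is_a: GO:0000002", "",
           "[Term]", "id: GO:0000002", "name: b",
           "namespace: biological_process", "is_a: GO:0000001", "")
  pc <- file.path(dir, "cycle.obo")
  writeLines(cyc, pc)
  expect_error(load_obo(pc), "cycle.*GO:0000001")
})

test_that("ancestor sets equal the fixed-point closure oracle", {
  set.seed(21)
  for (rep in 1:10) {
    # random DAG: term i may have parents among terms < i
    n <- sample(5:15, 1)
    ids <- sprintf("GO:%07d", 1:n)
    parents <- list()
    lines <- c("format-version: 1.2", "")
    for (i in seq_len(n)) {
      par <- if (i == 1) character(0) else
        ids[sample(seq_len(i - 1), sample(0:min(2, i - 1), 1))]
      parents[[ids[i]]] <- par
      lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
                 paste0("name: t", i), "namespace: biological_process",
                 paste0("is_a: ", par), "")
    }
    p <- tempfile(fileext = ".obo")
    writeLines(lines, p)
    ont <- suppressWarnings(load_obo(p))  # multiple roots possible
    oracle <- bf_ancestors(ids, parents)
    for (t in ids)
      expect_setequal(ont$ancestors[[t]], oracle[[t]])
  }
})

test_that("annotations propagate under the true-path rule with counts", {
  fx <- toy_go_fixture()
  ann <- fx$ann
  expect_setequal(ann$propagated$g1,
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  expect_equal(unname(ann$term_count["GO:0000002"]), 4L)   # g1..g4
  expect_equal(unname(ann$term_count["GO:0000001"]), 8L)
  expect_equal(ann$corpus_size, 8L)
  # child counts never exceed the parent's
  for (t in names(fx$ont$parents))
    for (p in fx$ont$parents[[t]])
      expect_lte(ann$term_count[[t]], ann$term_count[[p]])
})

test_that("unknown terms are skipped with a warning, empty corpus errors", {
  fx <- toy_go_fixture()
  dir <- withr_tempdir()
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("g1\tGO:0000003", "gX\tGO:9999999"), bad)
  expect_warning(ann <- load_annotations(bad, fx$ont), "unknown")
  expect_equal(ann$corpus_size, 1L)
  expect_equal(ann$skipped$term, "GO:9999999")

  empty <- file.path(dir, "empty.tsv")
  writeLines(character(0), empty)
  ann0 <- load_annotations(empty, fx$ont)
  expect_equal(ann0$corpus_size, 0L)
  expect_error(information_content("GO:0000001", ann0), "empty")
})

test_that("information content matches closed-form values in bits", {
  fx <- toy_go_fixture()
  ic <- information_content(paste0("GO:000000", 1:5), fx$ann)
  expect_equal(unname(ic), c(0, 1, 3, 3, 1), tolerance = 1e-9)
  # anti-monotone along is_a edges
  for (t in names(fx$ont$parents))
    for (p in fx$ont$parents[[t]])
      expect_gte(ic[[t]], ic[[p]])
  expect_true(is.na(information_content("GO:0000042", fx$ann)))
})

test_that("Lin similarity follows the MICA formula", {
  fx <- toy_go_fixture()
  ann <- fx$ann
  expect_equal(lin_similarity("GO:0000003", "GO:0000003", ann), 1)
  # siblings with Ic 3 under a parent with Ic 1: 2*1/(3+3)
  expect_equal(lin_similarity("GO:0000003", "GO:0000004", ann), 1 / 3,
               tolerance = 1e-9)
  # only shared ancestor is the zero-Ic root
  expect_equal(lin_similarity("GO:0000003", "GO:0000005", ann), 0)
  expect_equal(lin_similarity("GO:0000001", "GO:0000001", ann), 0)
  expect_equal(lin_similarity("GO:0000004", "GO:0000003", ann),
               lin_similarity("GO:0000003", "GO:0000004", ann))
})

test_that("cross-namespace term comparison is a hard error", {
  dir <- withr_tempdir()
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0000001", "name: bp root",
           "namespace: biological_process", "",
           "[Term]", "id: GO:0000006", "name: mf root",
           "namespace: molecular_function", "")
  p <- file.path(dir, "two-ns.obo")
  writeLines(obo, p)
  ont <- load_obo(p)
  ann_p <- file.path(dir, "ann.tsv")
  writeLines(c("g1\tGO:0000001", "g2\tGO:0000006"), ann_p)
  ann <- load_annotations(ann_p, ont, namespace = NULL)
  expect_error(lin_similarity("GO:0000001", "GO:0000006", ann),
               "cross-namespace")
})

test_that("gene semantic scores combine term sims by best-match average", {
  fx <- toy_go_fixture()
  ann <- fx$ann
  # identical term sets score 1
  sem <- gene_semantic_matrix(c("g3", "g4"), ann)
  expect_equal(sem$scores["g3", "g4"], 1)
  # root-only style: g5 (branch B) vs g1 (leaf A1) share only the root
  sem2 <- gene_semantic_matrix(c("g1", "g5"), ann)
  expect_equal(sem2$scores["g1", "g5"], 0)
  # BMA equals the exhaustive double-loop oracle on a 3-gene fixture
  genes <- c("g1", "g2", "g3")
  sem3 <- gene_semantic_matrix(genes, ann)
  for (i in 1:2) for (j in (i + 1):3) {
    S <- ann$direct[[genes[i]]]; T <- ann$direct[[genes[j]]]
    m <- outer(S, T, Vectorize(function(a, b) lin_similarity(a, b, ann)))
    bma <- (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) /
      (length(S) + length(T))
    expect_equal(sem3$scores[genes[i], genes[j]], bma, tolerance = 1e-12)
  }
  # invariance to gene ordering
  sem4 <- gene_semantic_matrix(rev(genes), ann)
  expect_equal(sem4$scores[genes, genes], sem3$scores[genes, genes])
})

test_that("unannotated genes are excluded with a warning", {
  fx <- toy_go_fixture()
  expect_warning(sem <- gene_semantic_matrix(c("g1", "g2", "nope"), fx$ann),
                 "excluded")
  expect_equal(rownames(sem$scores), c("g1", "g2"))
  expect_equal(attr(sem, "excluded"), "nope")
  expect_error(suppressWarnings(gene_semantic_matrix("nope", fx$ann)),
               "no annotated genes")
})

test_that("diagonal is 1 exactly for genes with informative annotations", {
  fx <- toy_go_fixture()
  sem <- gene_semantic_matrix(c("g1", "g5"), fx$ann)
  expect_equal(sem$scores["g1", "g1"], 1)   # leaf annotation, Ic 3
  expect_equal(sem$scores["g5", "g5"], 1)   # branch B, Ic 1 > 0
})

test_that("a gene annotated only to the root scores 0 against a leaf gene", {
  fx <- toy_go_fixture()
  dir <- withr_tempdir()
  p <- file.path(dir, "rootonly.tsv")
  writeLines(c("r1\tGO:0000001", "g1\tGO:0000003"), p)
  ann <- load_annotations(p, fx$ont)
  sem <- gene_semantic_matrix(c("r1", "g1"), ann)
  expect_equal(sem$scores["r1", "g1"], 0)
  expect_equal(sem$scores["r1", "r1"], 0)   # no informative annotation
})
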