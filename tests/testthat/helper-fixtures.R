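# Fixture builders shared across test files.

# Small expression matrix with hand-set values.
make_expr <- function(vals, classes = NULL) {
  expr_matrix(vals, sample_class = classes)
}

# Hand-built 8-gene / 5-term biological_process fixture with closed-form
# information contents: root (8/8 -> 0 bits), two mid terms covering 4/8
# (1 bit), two leaves covering 1/8 (3 bits).
toy_go_fixture <- function(dir = withr_tempdir()) {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: branch A",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf A1",
    "namespace: biological_process", "is_a: GO:0000002 ! branch A", "",
    "[Term]", "id: GO:0000004", "name: leaf A2",
    "namespace: biological_process", "is_a: GO:0000002 ! branch A", "",
    "[Term]", "id: GO:0000005", "name: branch B",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "")
  ann <- c("g1\tGO:0000003", "g2\tGO:0000004", "g3\tGO:0000002",
           "g4\tGO:0000002", "g5\tGO:0000005", "g6\tGO:0000005",
           "g7\tGO:0000005", "g8\tGO:0000005")
  obo_path <- file.path(dir, "toy.obo")
  ann_path <- file.path(dir, "toy.tsv")
  writeLines(obo, obo_path)
  writeLines(ann, ann_path)
  ont <- load_obo(obo_path)
  list(ont = ont,
       ann = load_annotations(ann_path, ont, namespace = "BP"),
       obo_path = obo_path, ann_path = ann_path)
}

withr_tempdir <- function() {
  d <- tempfile("coexmod-fixture-")
  dir.create(d)
  d
}

# Extracted-vs-planted partition labels for ARI checks: unassigned and
# background both carry label 0.
extraction_labels <- function(mods, truth) {
  ext <- stats::setNames(rep(0L, nrow(truth)), truth$gene_id)
  for (m in mods$modules) ext[m$members] <- m$module_id
  ext
}
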