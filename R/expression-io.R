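#' Expression matrix container
#'
#' An `expr_matrix` is a light S3 wrapper around a numeric genes x samples
#' matrix. Row names are gene identifiers (unique after preprocessing), column
#' names are sample identifiers, and an optional per-sample class label
#' (e.g. `"normal"` / `"disease"`) is carried alongside. Missing expression
#' values are stored as `NA`, never as zero.
#'
#' @param values numeric matrix (genes x samples) with row and column names.
#' @param sample_class optional character vector of class labels, one per
#'   sample, or `NULL` when the design has no class structure.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, sample_class = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene row names and sample column names")
  if (ncol(values) < 2L)
    stop("an expression matrix needs at least 2 samples")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!is.null(sample_class)) {
    if (length(sample_class) != ncol(values))
      stop("`sample_class` must have one label per sample")
    sample_class <- stats::setNames(as.character(sample_class), colnames(values))
  }
  structure(
    list(values = values, sample_class = sample_class, report = NULL),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$sample_class)) {
    tab <- table(x$sample_class)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  if (!is.null(x$report))
    cat(sprintf("  preprocessed (removed: %d unformatted, %d all-missing, %d duplicate)\n",
                x$report$unformatted, x$report$all_missing, x$report$duplicate))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param m an `expr_matrix`.
#' @return character vector of gene IDs in row order.
#' @export
gene_ids <- function(m) rownames(m$values)

#' Read a tab-delimited expression matrix
#'
#' Expects a UTF-8 TSV whose first row is `GENE<TAB>sample1<TAB>...` and whose
#' remaining rows hold one gene each: identifier in column 1 followed by
#' numeric expression values. Cells equal to `NA`, `NaN` or empty are treated
#' as missing. Any other non-numeric cell marks the row as unformatted; such
#' rows are dropped later by [preprocess_expression()].
#'
#' @param path path to the expression TSV.
#' @param class_file optional path to a two-column TSV (sample_id, class) with
#'   no header, assigning a class label to each sample.
#' @param sample_class optional character vector of class labels (one per
#'   sample), an in-memory alternative to `class_file`.
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` to the values (many
#'   public matrices are already log-scale; the default leaves values as-is).
#' @return an `expr_matrix`. Rows with unparseable value cells are retained
#'   (cells as `NA`) but flagged for removal during preprocessing.
#' @export
read_expression <- function(path, class_file = NULL, sample_class = NULL,
                            log2_transform = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)

  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  n_col <- length(header)
  if (n_col < 3L) stop("header must name at least 2 samples")
  samples <- header[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample IDs in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))

  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  lens <- lengths(body)
  bad <- which(lens != n_col)
  if (length(bad))
    stop(sprintf("malformed row at line %d: expected %d columns, found %d",
                 bad[1L] + 1L, n_col, lens[bad[1L]]))

  ids <- vapply(body, `[[`, character(1), 1L)
  cells <- t(vapply(body, function(r) r[-1L], character(n_col - 1L)))
  cells[cells %in% c("", "NA", "NaN", "nan", "na")] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  # cells that were present but failed numeric parsing => unformatted rows
  unformatted <- which(apply(is.na(vals) & !is.na(cells), 1L, any))
  vals[is.nan(vals)] <- NA_real_

  dimnames(vals) <- list(ids, samples)
  if (log2_transform) vals <- log2(vals + 1)

  cls <- sample_class
  if (!is.null(class_file)) {
    cls_tab <- utils::read.table(class_file, sep = "\t", header = FALSE,
                                 colClasses = "character", quote = "")
    if (ncol(cls_tab) < 2L) stop("class file must have two columns")
    cls <- cls_tab[[2L]][match(samples, cls_tab[[1L]])]
    if (anyNA(cls))
      stop("class file missing labels for samples: ",
           paste(samples[is.na(cls)], collapse = ", "))
  }

  m <- expr_matrix(vals, sample_class = cls)
  attr(m, "unformatted_rows") <- unformatted
  m
}

#' Preprocess an expression matrix
#'
#' Applies the three standard hygiene rules before similarity computation:
#' rows with an empty/whitespace gene ID or unparseable value cells are
#' removed ("unlabeled or unformatted"), rows whose values are all missing are
#' removed, and duplicate gene IDs are collapsed to a single row. Partially
#' missing rows are kept; downstream similarity uses pairwise-complete values.
#'
#' Duplicate collapse keeps the row with the fewest missing values, breaking
#' ties by first occurrence, so the result is deterministic.
#'
#' @param m an `expr_matrix` (typically from [read_expression()]).
#' @return an `expr_matrix` with unique gene IDs; `$report` lists the number
#'   of rows removed per rule (`unformatted`, `all_missing`, `duplicate`).
#'   The sample dimension is never changed. Errors if nothing survives.
#' @export
preprocess_expression <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  vals <- m$values
  ids <- rownames(vals)
  keep <- rep(TRUE, nrow(vals))

  unf <- attr(m, "unformatted_rows")
  bad_id <- !nzchar(trimws(ids))
  bad_id[is.na(ids)] <- TRUE
  if (!is.null(unf) && length(unf)) bad_id[unf] <- TRUE
  n_unformatted <- sum(bad_id & keep)
  keep <- keep & !bad_id

  all_missing <- rowSums(!is.na(vals)) == 0L
  n_all_missing <- sum(all_missing & keep)
  keep <- keep & !all_missing

  idx <- which(keep)
  n_missing <- rowSums(is.na(vals))
  dup_removed <- 0L
  if (anyDuplicated(ids[idx])) {
    # stable: order by (fewest NAs, first occurrence), keep first per ID
    ord <- idx[order(n_missing[idx], idx)]
    chosen <- ord[!duplicated(ids[ord])]
    dup_removed <- length(idx) - length(chosen)
    idx <- sort(chosen)
  }

  if (!length(idx)) stop("empty after preprocessing")
  out <- expr_matrix(vals[idx, , drop = FALSE], sample_class = m$sample_class)
  out$report <- list(unformatted = n_unformatted,
                     all_missing = n_all_missing,
                     duplicate = dup_removed)
  out
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: header `GENE` followed by sample IDs,
#' missing values written as `NA`.
#'
#' @param m an `expr_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(GENE = rownames(m$values), m$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
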