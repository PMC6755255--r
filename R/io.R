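#' Read a delimited count table
#'
#' Reads a CSV/TSV count matrix with an identifier header row and an
#' identifier first column, and orients it internally to samples x features
#' regardless of the file's orientation.
#'
#' @param path file path. Delimiter is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `delimiter` is given.
#' @param orientation `"samples_as_rows"` (default) or `"samples_as_cols"`
#'   describing the file layout.
#' @param delimiter optional single character field separator.
#' @param unit unit tag for the resulting table (default `"raw_count"`).
#' @return a [count_table] with samples as rows.
#' @export
read_count_table <- function(path,
                             orientation = c("samples_as_rows",
                                             "samples_as_cols"),
                             delimiter = NULL,
                             unit = "raw_count") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- delimiter %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!apply(df, 2L, function(col) {
      all(!is.na(suppressWarnings(as.numeric(col))))
    }))
    stopf("non-numeric cells in column(s): %s",
          paste(colnames(df)[bad], collapse = ", "))
  }
  if (orientation == "samples_as_cols") m <- t(m)
  count_table(m, unit = unit)
}

#' Read a sparse Matrix Market count table
#'
#' Single-cell scale input: an `.mtx` file plus two plain-text id files
#' (one id per line) for the rows and columns of the sparse matrix.
#'
#' @param mtx_path Matrix Market file (features x samples or samples x
#'   features, see `orientation`).
#' @param row_ids_path,col_ids_path text files with one identifier per line
#'   for the matrix rows and columns.
#' @param orientation layout of the `.mtx` file, as in [read_count_table].
#' @param unit unit tag.
#' @return a [count_table].
#' @export
read_count_table_mtx <- function(mtx_path, row_ids_path, col_ids_path,
                                 orientation = c("samples_as_rows",
                                                 "samples_as_cols"),
                                 unit = "raw_count") {
  orientation <- match.arg(orientation)
  for (p in c(mtx_path, row_ids_path, col_ids_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(row_ids_path)
  colnames(m) <- readLines(col_ids_path)
  if (orientation == "samples_as_cols") m <- t(m)
  count_table(m, unit = unit)
}

#' Read a sample annotation table
#'
#' First column is taken as the sample identifier; a `group` column is
#' required (configurable name); all remaining columns become covariates.
#'
#' @param path CSV/TSV path.
#' @param group_col name of the column holding the group label.
#' @param delimiter optional separator override.
#' @param t optional `count_table` to validate against.
#' @return a [sample_annotation].
#' @export
read_annotation <- function(path, group_col = "group", delimiter = NULL,
                            t = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- delimiter %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!group_col %in% names(df)) {
    stopf("annotation column '%s' not found (columns: %s)", group_col,
          paste(names(df), collapse = ", "))
  }
  names(df)[1L] <- "sample_id"
  names(df)[names(df) == group_col] <- "group"
  sample_annotation(df, t = t)
}

#' Stack two count tables sample-wise ("row join")
#'
#' Vertical multi-omics integration: a second omics layer measured on the
#' same features is treated as additional samples, with the source recorded
#' as a covariate so downstream models can contrast the layers.
#'
#' @param a,b `count_table`s sharing an identical feature set (order in `b`
#'   may differ; it is reordered to match `a`).
#' @param source_labels length-2 character vector labelling the origin of
#'   `a`'s and `b`'s samples.
#' @return list with elements `table` (stacked [count_table]) and
#'   `annotation` (a [sample_annotation] whose `group` and `source` record
#'   the origin).
#' @export
row_join <- function(a, b, source_labels = c("a", "b")) {
  stopifnot(inherits(a, "count_table"), inherits(b, "count_table"))
  fa <- feature_ids(a)
  fb <- feature_ids(b)
  if (!setequal(fa, fb)) {
    only_a <- setdiff(fa, fb)
    only_b <- setdiff(fb, fa)
    stopf("feature sets differ; only in first: {%s}; only in second: {%s}",
          paste(utils::head(only_a, 5L), collapse = ","),
          paste(utils::head(only_b, 5L), collapse = ","))
  }
  if (any(sample_ids(a) %in% sample_ids(b))) {
    stopf("sample ids overlap between the two tables")
  }
  vb <- b$values[, fa, drop = FALSE]
  v <- rbind(a$values, vb)
  out <- count_table(v, unit = a$unit)
  ann <- sample_annotation(data.frame(
    sample_id = c(sample_ids(a), sample_ids(b)),
    group = rep(source_labels, c(nrow(a$values), nrow(b$values))),
    source = rep(source_labels, c(nrow(a$values), nrow(b$values))),
    stringsAsFactors = FALSE
  ), t = out)
  list(table = out, annotation = ann)
}

#' Write a table to delimited text
#'
#' Count and log-ratio tables are written samples x features with an `id`
#' header column; pair result tables are written long-format with pair ids
#' sorted lexicographically.
#'
#' @param t a `count_table`, `lr_table`, or `data.frame` (pair results).
#' @param path destination; `.tsv` extension selects tab separation.
#' @param header_lines optional character vector written as `#`-prefixed
#'   comment lines before the table (provenance metadata).
#' @return `path`, invisibly.
#' @export
write_table <- function(t, path, header_lines = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  if (inherits(t, "count_table") || inherits(t, "lr_table")) {
    m <- t$values
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else if (is.data.frame(t)) {
    df <- t
    if (all(c("g", "h") %in% names(df))) {
      df <- df[order(df$g, df$h), , drop = FALSE]
    }
  } else {
    stopf("cannot write object of class %s", paste(class(t), collapse = "/"))
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
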