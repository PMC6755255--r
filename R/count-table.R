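#' Count table container
#'
#' A `count_table` holds a nonnegative numeric matrix with samples as rows
#' and features as columns, together with a unit tag. Sequencing counts only
#' carry relative information: each row is a composition whose total was
#' fixed by the sequencer, not by the input material, so all downstream
#' analyses in this package are ratio-based.
#'
#' @param values numeric matrix, samples x features, with unique row and
#'   column names. All entries must be finite and nonnegative.
#' @param unit one of `"raw_count"`, `"tpm_like"`, `"pseudo_count"`,
#'   `"proportion"`. Defaults to `"raw_count"`.
#' @return an object of class `count_table` with elements `values`, `unit`.
#' @export
count_table <- function(values, unit = c("raw_count", "tpm_like",
                                         "pseudo_count", "proportion")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("count table values must be numeric")
  if (nrow(values) < 1L || ncol(values) < 2L) {
    stopf("a count table needs >= 1 sample and >= 2 features (got %d x %d)",
          nrow(values), ncol(values))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("feature_", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stopf("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate feature ids")
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("negative or non-finite entry at sample '%s', feature '%s'",
          rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]])
  }
  structure(list(values = values, unit = unit), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d features [unit: %s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$values)

#' Sample identifiers of a count table
#' @param t a `count_table`
#' @return character vector
#' @export
sample_ids <- function(t) rownames(t$values)

#' Feature identifiers of a count table
#' @param t a `count_table`
#' @return character vector
#' @export
feature_ids <- function(t) colnames(t$values)

#' Sample annotation table
#'
#' Validates a per-sample annotation `data.frame` against a count table:
#' one row per sample, same order, a `sample_id` column and a categorical
#' `group` column; any further columns are kept as covariates.
#'
#' @param df data.frame with columns `sample_id` and `group` (plus
#'   arbitrary covariate columns such as time or omics source).
#' @param t optional `count_table` to validate ids and order against.
#' @return the validated data.frame, with `group` coerced to factor, class
#'   `sample_annotation` prepended.
#' @export
sample_annotation <- function(df, t = NULL) {
  df <- as.data.frame(df)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stopf("annotation needs 'sample_id' and 'group' columns")
  }
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids in annotation")
  df$sample_id <- as.character(df$sample_id)
  if (!is.factor(df$group)) df$group <- factor(df$group)
  if (nlevels(droplevels(df$group)) < 1L) stopf("group needs >= 1 level")
  if (!is.null(t)) {
    if (!identical(df$sample_id, sample_ids(t))) {
      stopf("annotation sample ids must match the count table, same order")
    }
  }
  class(df) <- c("sample_annotation", "data.frame")
  df
}

# Check a two-group annotation for the two-sample operations.
check_two_groups <- function(ann) {
  g <- droplevels(factor(ann$group))
  if (nlevels(g) != 2L) {
    stopf("this analysis needs exactly 2 groups (got %d); use the design-matrix interface for more complex layouts",
          nlevels(g))
  }
  if (any(table(g) < 2L)) stopf("each group needs >= 2 samples")
  g
}
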