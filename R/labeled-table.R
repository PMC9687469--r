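#' Labeled feature table
#'
#' The container used throughout the package: a numeric feature matrix
#' (samples in rows) together with a class label per sample. At most two
#' distinct labels are allowed; operations that need both classes (training,
#' stratified splitting) check for exactly two.
#'
#' Internally the classifier works with a \{-1, +1\} encoding: the
#' lexicographically first label maps to -1 (class B, the "negative" class)
#' and the second to +1 (class A); the original labels are kept and restored
#' on output.
#'
#' @param features numeric matrix, one row per sample; column names are used
#'   as feature names (defaults `f1..fn` are filled in when absent).
#' @param labels vector of class labels, one per row of `features`.
#' @return An object of class `labeled_table` with elements `features`,
#'   `labels` and `feature_names`.
#' @examples
#' tab <- labeled_table(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' n_samples(tab)
#' @export
labeled_table <- function(features, labels) {
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("`features` must be a numeric matrix", call. = FALSE)
  }
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) {
    stop("row count of `features` must equal length of `labels`",
         call. = FALSE)
  }
  if (anyNA(features) || anyNA(labels)) {
    stop("labeled table must not contain missing values", call. = FALSE)
  }
  if (length(unique(labels)) > 2L) {
    stop("more than two distinct labels found; only binary tables are supported",
         call. = FALSE)
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  structure(
    list(features = features, labels = labels,
         feature_names = colnames(features)),
    class = "labeled_table"
  )
}

#' @export
print.labeled_table <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<labeled_table> %d samples x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @rdname labeled_table
#' @param table a `labeled_table`.
#' @export
n_samples <- function(table) nrow(table$features)

#' @rdname labeled_table
#' @export
n_features <- function(table) ncol(table$features)

#' Sorted distinct class labels of a table
#'
#' @param table a `labeled_table`.
#' @return Character vector of the (up to two) class labels, sorted; the
#'   second is the default positive class and "class A" of the classifier.
#' @export
class_levels <- function(table) sort(unique(table$labels))

# rows of one class, as a plain feature matrix
class_features <- function(table, label) {
  table$features[table$labels == label, , drop = FALSE]
}

subset_table <- function(table, idx) {
  labeled_table(table$features[idx, , drop = FALSE], table$labels[idx])
}

#' Write a labeled table to CSV
#'
#' The label column is written last under the name `label`; quoting follows
#' RFC 4180 (via [utils::write.csv()]), encoding UTF-8.
#'
#' @param table a `labeled_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_table <- function(table, path) {
  df <- as.data.frame(table$features)
  df$label <- table$labels
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
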