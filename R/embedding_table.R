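#' Multimodal embedding tables
#'
#' An `embedding_table` is the interchange container used throughout the
#' package: a data frame with one row per sample, a `sample_id` column, two or
#' more named blocks of numeric embedding columns (one block per modality), a
#' `label` column (factor for classification, numeric for regression), and —
#' for temporal tables — integer `time_index` and `group_id` columns.
#'
#' Block membership is encoded in the column names as `<block>__<i>`
#' (double underscore), which is also the on-disk CSV dialect used by
#' [write_embedding_table()] and [read_embedding_table()].
#'
#' @param df A data frame containing `sample_id`, the block columns, `label`,
#'   and optionally `time_index` and `group_id`.
#' @param blocks Named list mapping block (modality) name to the character
#'   vector of its column names in `df`.
#' @return An object of class `embedding_table` (a data frame with a
#'   `blocks` attribute).
#' @examples
#' tab <- generate_classification(synthetic_spec(n_samples = 20, seed = 1))
#' modality_blocks(tab)
#' @export
embedding_table <- function(df, blocks) {
  stopifnot(is.data.frame(df), is.list(blocks), !is.null(names(blocks)))
  if (length(blocks) < 2L) {
    stop("an embedding_table needs at least two modality blocks", call. = FALSE)
  }
  if (!"sample_id" %in% names(df)) stop("missing 'sample_id' column", call. = FALSE)
  if (!"label" %in% names(df)) stop("missing 'label' column", call. = FALSE)
  for (bn in names(blocks)) {
    cols <- blocks[[bn]]
    if (!all(cols %in% names(df))) {
      stop(sprintf("block '%s' references columns absent from the table", bn),
           call. = FALSE)
    }
    x <- as.matrix(df[, cols, drop = FALSE])
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
      stop(sprintf("block '%s' contains missing or non-numeric values", bn),
           call. = FALSE)
    }
  }
  if (anyDuplicated(df$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  if ("time_index" %in% names(df)) {
    if (!"group_id" %in% names(df)) {
      stop("temporal tables need a 'group_id' column", call. = FALSE)
    }
    key <- paste(df$group_id, df$time_index)
    if (anyDuplicated(key)) {
      stop("(group_id, time_index) pairs must be unique", call. = FALSE)
    }
  }
  structure(df, blocks = blocks,
            class = c("embedding_table", "data.frame"))
}

#' @describeIn embedding_table Named list of block-column names.
#' @param table An `embedding_table`.
#' @export
modality_blocks <- function(table) {
  attr(table, "blocks")
}

#' Extract one modality block as a numeric matrix
#'
#' @param table An `embedding_table`.
#' @param block Block name (see [modality_blocks()]).
#' @return Numeric matrix, one row per sample.
#' @export
block_matrix <- function(table, block) {
  blocks <- modality_blocks(table)
  if (!block %in% names(blocks)) {
    stop(sprintf("unknown block '%s'; available: %s", block,
                 paste(names(blocks), collapse = ", ")), call. = FALSE)
  }
  as.matrix(as.data.frame(table)[, blocks[[block]], drop = FALSE])
}

#' @export
print.embedding_table <- function(x, ...) {
  blocks <- modality_blocks(x)
  temporal <- "time_index" %in% names(x)
  cat(sprintf("<embedding_table> %d samples, %d modality blocks%s\n",
              nrow(x), length(blocks), if (temporal) " (temporal)" else ""))
  for (bn in names(blocks)) {
    cat(sprintf("  block '%s': %d dims\n", bn, length(blocks[[bn]])))
  }
  lab <- x$label
  if (is.factor(lab)) {
    cat("  label: factor with levels", paste(levels(lab), collapse = ", "), "\n")
  } else {
    cat(sprintf("  label: numeric in [%.3g, %.3g]\n", min(lab), max(lab)))
  }
  if (temporal) {
    cat(sprintf("  groups: %d, weeks: %d..%d\n",
                length(unique(x$group_id)), min(x$time_index),
                max(x$time_index)))
  }
  invisible(x)
}

#' Write an embedding table to CSV
#'
#' The on-disk dialect is a plain UTF-8 CSV with header
#' `sample_id,<block>__<i>,...,label[,time_index,group_id]`; block membership
#' is carried by the double-underscore column-name prefix.
#'
#' @param table An `embedding_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  df <- as.data.frame(table)
  blocks <- modality_blocks(table)
  extra <- intersect(c("time_index", "group_id"), names(df))
  df <- df[, c("sample_id", unlist(blocks, use.names = FALSE), "label", extra)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an embedding table from CSV
#'
#' @param path CSV file in the dialect written by [write_embedding_table()].
#' @return An `embedding_table`.
#' @export
read_embedding_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  if (!"label" %in% nm) {
    stop(sprintf("'%s': required column 'label' not found in header", path),
         call. = FALSE)
  }
  if (!"sample_id" %in% nm) {
    stop(sprintf("'%s': required column 'sample_id' not found in header", path),
         call. = FALSE)
  }
  emb_cols <- grep("__", nm, value = TRUE)
  if (length(emb_cols) == 0L) {
    stop(sprintf("'%s': no '<block>__<i>' embedding columns found", path),
         call. = FALSE)
  }
  for (cn in emb_cols) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop(sprintf("'%s': non-numeric embedding cell at row %d, column '%s'",
                   path, if (is.na(bad)) 1L else bad, cn), call. = FALSE)
    }
    if (anyNA(col)) {
      stop(sprintf("'%s': missing embedding value at row %d, column '%s'",
                   path, which(is.na(col))[1L], cn), call. = FALSE)
    }
  }
  block_of <- sub("__.*$", "", emb_cols)
  blocks <- split(emb_cols, factor(block_of, levels = unique(block_of)))
  if (is.character(df$label)) df$label <- factor(df$label)
  embedding_table(df, blocks = as.list(blocks))
}
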