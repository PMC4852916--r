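#' Read a delimited expression table
#'
#' Reads a numeric samples-by-features matrix from CSV/TSV, optionally with
#' a binary label column inside the table or a separate label file.
#' Orientation (samples in rows vs features in rows) can be forced or
#' auto-detected: a table with a label column is taken as samples-in-rows;
#' otherwise, when a label file with sample ids is given, the axis whose ids
#' overlap the label ids wins.
#'
#' Two-level labels are mapped to 0/1 by lexicographic order of the levels
#' (e.g. `"Normal"` -> 0, `"Tumor"` -> 1) and the mapping is reported via a
#' message and stored in the result. Labels already coded 0/1 are kept.
#'
#' @param path delimited text file; first column may hold row ids.
#' @param label_column name of the label column inside the table, if any.
#' @param labels_path separate label file: either two columns (id, label) or
#'   a single label column aligned with the samples.
#' @param delimiter field separator; default inferred from the extension
#'   (`","` for `.csv`, tab otherwise).
#' @param orientation `"auto"`, `"samples_in_rows"` or `"features_in_rows"`.
#' @return a list of class `"expression_table"`: numeric matrix `X`
#'   (samples x features), labels `y` (0/1 integer or `NULL`), `label_map`.
#' @export
read_expression_table <- function(path, label_column = NULL,
                                  labels_path = NULL, delimiter = NULL,
                                  orientation = c("auto", "samples_in_rows",
                                                  "features_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = delimiter, header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  row_ids <- NULL
  if (ncol(df) > 1 && !is.numeric(df[[1]]) &&
      (is.null(label_column) || names(df)[1] != label_column)) {
    row_ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  y_raw <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df))
      stop("label column `", label_column, "` not found", call. = FALSE)
    y_raw <- df[[label_column]]
    df <- df[, setdiff(names(df), label_column), drop = FALSE]
    orientation <- "samples_in_rows"
  }
  for (cn in names(df)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) && !all(is.na(df[[cn]])))
      stop(sprintf("non-numeric value in column `%s` (row %d)", cn,
                   which(is.na(v))[1]), call. = FALSE)
    df[[cn]] <- v
  }
  X <- as.matrix(df)
  rownames(X) <- row_ids

  label_df <- NULL
  if (!is.null(labels_path)) {
    label_df <- read.delim(labels_path,
                           sep = if (grepl("\\.csv$", labels_path,
                                           ignore.case = TRUE)) "," else "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  }
  if (orientation == "auto") {
    orientation <- "samples_in_rows"
    if (!is.null(label_df) && ncol(label_df) >= 2) {
      ids <- as.character(label_df[[1]])
      row_hit <- length(intersect(ids, rownames(X)))
      col_hit <- length(intersect(ids, colnames(X)))
      if (col_hit > row_hit) orientation <- "features_in_rows"
    }
  }
  if (orientation == "features_in_rows") X <- t(X)
  if (!is.null(label_df)) {
    if (ncol(label_df) >= 2) {
      ids <- as.character(label_df[[1]])
      m <- match(rownames(X), ids)
      if (anyNA(m))
        stop("label file ids do not cover all samples", call. = FALSE)
      y_raw <- label_df[[2]][m]
    } else {
      if (nrow(label_df) != nrow(X))
        stop("label file length does not match sample count", call. = FALSE)
      y_raw <- label_df[[1]]
    }
  }
  y <- NULL
  label_map <- NULL
  if (!is.null(y_raw)) {
    if (is.numeric(y_raw) && all(y_raw %in% c(0, 1))) {
      y <- as.integer(y_raw)
    } else {
      lev <- sort(unique(as.character(y_raw)))
      if (length(lev) != 2)
        stop("labels must have exactly 2 levels, found ", length(lev),
             call. = FALSE)
      y <- as.integer(as.character(y_raw) == lev[2])
      label_map <- stats::setNames(c(0L, 1L), lev)
      message(sprintf("label mapping: %s -> 0, %s -> 1", lev[1], lev[2]))
    }
  }
  if (!is.null(y) && length(y) != nrow(X))
    stop("label length does not match sample count", call. = FALSE)
  if (anyDuplicated(colnames(X)))
    stop("duplicate feature ids", call. = FALSE)
  structure(list(X = X, y = y, label_map = label_map,
                 orientation = orientation),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d samples x %d features%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$y)) "" else sprintf(", labels (%d positive)",
                                                sum(x$y))))
  invisible(x)
}
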