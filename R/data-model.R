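#' Read a feature-by-sample expression matrix
#'
#' Reads a delimited text file whose first column holds feature identifiers
#' (proteins, genes) and whose header row holds sample identifiers. Empty
#' cells or a missing-value sentinel (case-insensitive `"NA"` by default)
#' become `NA`.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter. `NULL` (default) infers `","` for `.csv`
#'   files and tab otherwise.
#' @param missing Character vector of sentinel tokens denoting a missing
#'   value, compared case-insensitively; the empty string is always treated
#'   as missing.
#' @param transpose If `TRUE` the file is sample-by-feature and is
#'   transposed on read so that rows are features.
#' @return A tibble with a `feature_id` character column followed by one
#'   numeric column per sample; row and column order follow the file.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\ts1\ts2", "F1\t1.5\t2.0", "F2\t\t0.3"), tf)
#' read_expression(tf)
read_expression <- function(path, delim = NULL, missing = c("", "NA"),
                            transpose = FALSE) {
  stopifnot(file.exists(path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           na = character(), trim_ws = TRUE,
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) < 2 || ncol(raw) < 2) {
    stop("expression file needs a header row, an id column and at least one data cell",
         call. = FALSE)
  }
  sample_ids <- as.character(raw[1, -1])
  feature_ids <- as.character(raw[[1]][-1])
  cells <- as.matrix(raw[-1, -1, drop = FALSE])
  if (transpose) {
    cells <- t(cells)
    tmp <- sample_ids; sample_ids <- feature_ids; feature_ids <- tmp
  }
  check_no_duplicates(feature_ids, "feature id")
  check_no_duplicates(sample_ids, "sample id")

  sentinels <- tolower(c(missing, ""))
  is_missing <- matrix(tolower(trimws(cells)) %in% sentinels | is.na(cells),
                       nrow = nrow(cells))
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values) & !is_missing, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s' (row %d, column %d)",
                 cells[bad[1, 1], bad[1, 2]], feature_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]], bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  values[is_missing] <- NA_real_
  dimnames(values) <- list(feature_ids, sample_ids)
  expr_as_tibble(values)
}

#' Read two-class sample labels
#'
#' @param path Two-column delimited text file: sample id, class label. A
#'   header row named `sample_id`/`class` is detected and skipped.
#' @param delim Field delimiter; inferred as in [read_expression()].
#' @return A tibble with columns `sample_id` and `class`. The order of
#'   first appearance of the class labels defines the "first" class used in
#'   deterministic tie-breaks downstream.
#' @export
read_labels <- function(path, delim = NULL) {
  stopifnot(file.exists(path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           trim_ws = TRUE, progress = FALSE,
                           show_col_types = FALSE)
  if (ncol(raw) != 2) stop("label file must have exactly two columns", call. = FALSE)
  if (nrow(raw) > 0 && tolower(raw[[1]][1]) %in% c("sample_id", "sample") &&
      tolower(raw[[2]][1]) %in% c("class", "label", "group")) {
    raw <- raw[-1, , drop = FALSE]
  }
  labels <- tibble::tibble(sample_id = as.character(raw[[1]]),
                           class = as.character(raw[[2]]))
  validate_labels(labels)
  labels
}

#' Write (and read back) an ERI result table
#'
#' Writes the per-feature table of ERI scores as tab-separated text with
#' columns `feature_id`, `eri`, `rank`, `significant`, sorted by rank.
#'
#' @param table A tibble as produced by [eri_scores()] or [call_significant()].
#' @param path Output path.
#' @return `write_eri_table()` returns `path` invisibly; `read_eri_table()`
#'   returns the tibble.
#' @export
write_eri_table <- function(table, path) {
  stopifnot(all(c("feature_id", "eri", "rank", "significant") %in% names(table)))
  out <- dplyr::arrange(table[c("feature_id", "eri", "rank", "significant")],
                        .data$rank)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_eri_table
#' @export
read_eri_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    feature_id = "c", eri = "d", rank = "i", significant = "l"
  ), progress = FALSE)
}

#' Write an expression tibble to delimited text
#'
#' @param expr Expression tibble (`feature_id` column plus sample columns).
#' @param path Output path; `.csv` extension selects comma delimiting.
#' @param missing Token written for `NA` cells (default empty cell).
#' @export
write_expression <- function(expr, path, missing = "") {
  validate_expression(expr)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(expr, path, delim = delim, na = missing, progress = FALSE)
  invisible(path)
}

# ---- internal representation helpers ---------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

check_no_duplicates <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s: %s", what, paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Validate the expression-tibble contract
#'
#' Checks the shape used throughout the package: a character `feature_id`
#' first column with no duplicates, unique sample columns, numeric values
#' that are finite wherever not `NA`.
#' @param expr Expression tibble.
#' @return `expr`, invisibly.
#' @export
validate_expression <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  if (names(expr)[1] != "feature_id") {
    stop("first column must be 'feature_id'", call. = FALSE)
  }
  check_no_duplicates(expr$feature_id, "feature id")
  check_no_duplicates(names(expr)[-1], "sample id")
  vals <- expr_as_matrix(expr)
  if (any(!is.finite(vals) & !is.na(vals))) {
    stop("non-finite expression values present", call. = FALSE)
  }
  invisible(expr)
}

validate_labels <- function(labels) {
  stopifnot(is.data.frame(labels),
            all(c("sample_id", "class") %in% names(labels)))
  check_no_duplicates(labels$sample_id, "sample id")
  cls <- unique(labels$class)
  if (length(cls) != 2) {
    stop(sprintf("exactly 2 classes required, found %d (%s)", length(cls),
                 paste(cls, collapse = ", ")), call. = FALSE)
  }
  invisible(labels)
}

# class labels in order of first appearance; element 1 is the tie-break class
class_levels <- function(labels) unique(labels$class)

#' Bind labels to an expression tibble
#'
#' Aligns a label table to the sample columns of an expression tibble.
#' Every sample column must be labeled; no sample is ever silently dropped.
#'
#' @param expr Expression tibble.
#' @param labels Label tibble from [read_labels()] or built in code.
#' @return The labels reordered to match the expression sample columns.
#' @export
bind_labels <- function(expr, labels) {
  validate_expression(expr)
  validate_labels(labels)
  samples <- names(expr)[-1]
  missing <- setdiff(samples, labels$sample_id)
  if (length(missing) > 0) {
    stop(sprintf("samples in matrix but absent from labels: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- labels[match(samples, labels$sample_id), , drop = FALSE]
  # preserve the original file's class order for tie-breaking, not the
  # reordered subset's
  attr(out, "class_levels") <- attr(labels, "class_levels") %||%
    class_levels(labels)
  out
}

expr_as_matrix <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$feature_id
  m
}

expr_as_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)), out)
}
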