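#' Read a gene-expression matrix from delimited text
#'
#' Expects genes in rows and samples in columns: the first row holds
#' sample ids, the first column gene ids. The delimiter is auto-detected
#' (tab or comma) unless given. Duplicate ids, non-numeric cells and
#' ragged rows are errors naming the offender; missing values are not
#' supported.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter `NULL` (auto-detect), `"\t"` or `","`.
#' @param transpose If `TRUE`, the file is sample-major and is transposed
#'   after reading.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, delimiter = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  nf <- utils::count.fields(path, sep = delimiter, quote = "\"",
                            comment.char = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop_invalid(sprintf(
      "ragged file: line %d has %d fields, expected %d", bad, nf[bad], nf[1]))
  }
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  gene_ids <- as.character(df[[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop_invalid("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  sample_ids <- colnames(df)[-1]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    stop_invalid("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop_invalid(sprintf(
        "non-numeric value in column '%s' (data line %d): '%s'",
        sample_ids[j], bad, vals[bad, j]))
    }
  }
  X <- as.matrix(vals)
  dimnames(X) <- list(gene_ids, sample_ids)
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop_invalid(sprintf(
      "missing value at gene '%s', sample '%s' (missing values are not supported)",
      gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  if (transpose) X <- t(X)
  if (ncol(X) < 2) stop_invalid("expression matrix needs at least 2 samples")
  X
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop_invalid("empty file: ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Write a gene-expression matrix as delimited text
#'
#' Values are written with 17 significant digits so a write/read
#' round-trip reproduces doubles exactly.
#'
#' @param X Numeric matrix with gene rownames and sample colnames (names
#'   are generated when absent).
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @export
write_expression <- function(X, path, delimiter = "\t") {
  if (!is.matrix(X)) X <- as.matrix(X)
  check_finite_matrix(X, "X")
  if (is.null(rownames(X))) rownames(X) <- paste0("gene_", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("sample_", seq_len(ncol(X)))
  df <- data.frame(gene_id = rownames(X),
                   format(X, digits = 17, trim = TRUE, scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample class labels
#'
#' Two-column delimited text: sample id, class label. A header line is
#' skipped when its first field is `sample_id` or `sample`
#' (case-insensitive).
#'
#' @param path Path to the label file.
#' @param delimiter `NULL` (auto-detect), `"\t"` or `","`.
#' @return Character vector of class labels named by sample id.
#' @export
read_labels <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (nrow(df) == 0) stop_invalid("empty label file: ", path)
  if (ncol(df) != 2) stop_invalid("label file must have exactly 2 columns")
  if (tolower(df[1, 1]) %in% c("sample_id", "sample")) {
    df <- df[-1, , drop = FALSE]
  }
  if (nrow(df) == 0) stop_invalid("label file has a header but no data: ", path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_invalid("duplicate sample id(s) in labels: ",
                 paste(unique(dup), collapse = ", "))
  }
  labels <- as.character(df[[2]])
  names(labels) <- ids
  labels
}

#' Write sample class labels
#'
#' @param labels Character vector of class labels named by sample id.
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @export
write_labels <- function(labels, path, delimiter = "\t") {
  if (is.null(names(labels))) stop_invalid("'labels' must be named by sample id")
  df <- data.frame(sample_id = names(labels), label = as.character(labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align labels to an expression matrix by sample id
#'
#' Joins a named label vector to the columns of an expression matrix,
#' order-insensitively; samples missing from either side are an error
#' listing every offender.
#'
#' @param X Expression matrix with sample colnames.
#' @param labels Named label vector from [read_labels()].
#' @return Character labels in the column order of `X`.
#' @export
align_labels <- function(X, labels) {
  if (is.null(colnames(X))) stop_invalid("'X' has no sample ids (colnames)")
  if (is.null(names(labels))) stop_invalid("'labels' must be named by sample id")
  missing <- setdiff(colnames(X), names(labels))
  if (length(missing)) {
    stop_invalid("no label for sample(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(labels), colnames(X))
  if (length(extra)) {
    stop_invalid("label(s) for unknown sample(s): ",
                 paste(extra, collapse = ", "))
  }
  out <- labels[colnames(X)]
  names(out) <- colnames(X)
  out
}

#' Write predictions as TSV or JSON
#'
#' TSV columns: sample id, predicted class, one residual column per
#' class. The JSON form carries the same fields.
#'
#' @param pred A [predict.srclatlrr()] result.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_predictions <- function(pred, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(pred, "srclatlrr_prediction"))
  ids <- rownames(pred$residuals)
  if (is.null(ids)) ids <- as.character(seq_along(pred$class))
  df <- data.frame(sample_id = ids, predicted = pred$class,
                   pred$residuals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' Write / read a cross-validation report
#'
#' JSON serialization of an [cross_validate()] report (full double
#' precision); reading restores the `"srclatlrr_cv"` class and values
#' exactly up to JSON number printing.
#'
#' @param report A `"srclatlrr_cv"` object.
#' @param path Output path.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "srclatlrr_cv"))
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_cv_report
#' @export
read_cv_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$predictions <- as.data.frame(obj$predictions,
                                   stringsAsFactors = FALSE)
  structure(obj, class = "srclatlrr_cv")
}

#' Write a lambda sweep table as TSV
#'
#' Columns `lambda`, `accuracy`, `mean_E_l1`, ready for a two-axis
#' accuracy/noise plot.
#'
#' @param sweep A [lambda_sweep()] table.
#' @param path Output path.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "srclatlrr_sweep"))
  utils::write.table(as.data.frame(sweep), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
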