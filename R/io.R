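# Readers and writers: confusion matrices from delimited text, label files,
# and JSON/TSV report serialisation.

.inferSep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a confusion matrix from a delimited text file
#'
#' Expects a square numeric block, rows = true class, columns = predicted
#' class. A leading header row and/or a leading label column are
#' auto-detected: if the first cell of a row or column is non-numeric it is
#' treated as labels. The delimiter is inferred from the extension (.csv
#' means comma, anything else tab) unless given explicitly.
#'
#' @param path file path.
#' @param sep optional field delimiter overriding the inference.
#' @return a [ConfusionMatrix-class].
#' @export
readConfusionMatrix <- function(path, sep = NULL) {
  if (!file.exists(path)) inputError(paste("no such file:", path))
  sep <- .inferSep(path, sep)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) inputError("empty confusion matrix file")
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) inputError("ragged rows in matrix file")
  grid <- do.call(rbind, lapply(cells, trimws))
  isNum <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  labels <- NULL
  if (!isNum(grid[1, ncol(grid)])) {        # header row present
    header <- grid[1, ]
    grid <- grid[-1, , drop = FALSE]
    labels <- header[(length(header) - nrow(grid) + 1):length(header)]
  }
  if (nrow(grid) > 0 && !isNum(grid[1, 1])) {  # label column present
    if (is.null(labels)) labels <- grid[, 1]
    grid <- grid[, -1, drop = FALSE]
  }
  if (nrow(grid) == 0L || ncol(grid) == 0L)
    inputError("no numeric block in matrix file")
  if (any(!isNum(grid))) inputError("non-numeric entry in matrix block")
  m <- matrix(as.numeric(grid), nrow(grid), ncol(grid))
  if (nrow(m) != ncol(m)) inputError("confusion matrix block must be square")
  confusionMatrix(m, labels = labels)
}

#' Write a confusion matrix as delimited text
#'
#' @param x a [ConfusionMatrix-class] or square matrix.
#' @param path output path; delimiter inferred from the extension unless
#'   \code{sep} is given.
#' @param sep optional delimiter.
#' @param labels include the class labels as header row and label column.
#' @export
writeConfusionMatrix <- function(x, path, sep = NULL, labels = TRUE) {
  sep <- .inferSep(path, sep)
  if (!is(x, "ConfusionMatrix")) x <- confusionMatrix(.asCountMatrix(x))
  m <- x@counts
  fmt <- function(v) sprintf("%.12g", v)
  body <- apply(m, 1, function(r) paste(vapply(r, fmt, ""), collapse = sep))
  if (labels) {
    body <- paste(x@labels, body, sep = sep)
    body <- c(paste(c("", x@labels), collapse = sep), body)
  }
  writeLines(body, path)
}

#' Read a two-column label file
#'
#' One sample per line: true label, then predicted label, tab-separated.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return a list with components \code{true} and \code{predicted}.
#' @export
readLabelFile <- function(path, sep = "\t") {
  if (!file.exists(path)) inputError(paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) inputError("empty label file")
  cells <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(cells) != 2L))
    inputError("label file must have exactly 2 columns per line")
  grid <- do.call(rbind, lapply(cells, trimws))
  list(true = grid[, 1], predicted = grid[, 2])
}

.reportAsList <- function(report) {
  if (is(report, "MetricsReport"))
    return(list(acc = report@acc, mcc = report@mcc, cen = report@cen,
                tmcc = report@tmcc, n_classes = report@nClasses,
                total = report@total))
  if (is(report, "ComparisonReport"))
    return(list(n_items = report@nItems, discriminancy = report@discriminancy,
                consistency = report@consistency, pearson = report@pearson,
                mean_ratio = report@meanRatio,
                ratio_ci = list(low = report@ratioCI[1],
                                high = report@ratioCI[2]),
                n_boot = report@nBoot))
  inputError("unsupported report type")
}

.sig12 <- function(x) {
  rapply(x, function(v) if (is.numeric(v)) signif(v, 12) else v,
         how = "replace")
}

#' Write a report to disk
#'
#' [MetricsReport-class] and [ComparisonReport-class] objects are written as
#' a single JSON object (or an aligned two-line TSV); a [StudyReport-class]
#' becomes a directory holding \code{per_matrix_table.tsv} and
#' \code{summary.json}. Numbers are written with 12 significant digits, so
#' a JSON round trip reproduces them to well below 1e-12 relative error.
#'
#' @param report the report object.
#' @param path output file (or directory for a StudyReport).
#' @param format \code{"json"} or \code{"tsv"} (scalar reports only).
#' @export
writeReport <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (is(report, "StudyReport")) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report@table, file.path(path, "per_matrix_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(.sig12(.reportAsList(report@summary)),
                         file.path(path, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  lst <- .reportAsList(report)
  if (format == "json") {
    jsonlite::write_json(.sig12(lst), path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  } else {
    flat <- unlist(lst)
    vals <- vapply(flat, function(v) sprintf("%.12g", as.numeric(v)), "")
    writeLines(c(paste(names(flat), collapse = "\t"),
                 paste(vals, collapse = "\t")), path)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path a JSON file written by [writeReport()].
#' @return a named list.
#' @export
readReport <- function(path) {
  if (!file.exists(path)) inputError(paste("no such file:", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
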