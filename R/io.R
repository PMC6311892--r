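# Readers and writers for association tables and ranked predictions.
# Edge lists are the canonical input (pair-table exports such as
# CircR2Disease); the dense format exists mainly for round-trip tests.

#' Read a binary association matrix
#'
#' Two formats are supported. `edge_list`: one association per line,
#' `row_id<TAB>col_id`; duplicate pairs collapse to a single 1; row and
#' column order is first-appearance order, which makes the resulting matrix
#' reproducible from the same file. `dense`: a TSV with a header row of
#' column identifiers and the row identifier in the first column; every cell
#' must be 0 or 1.
#'
#' Identifiers are opaque case-sensitive strings; no alias normalization is
#' attempted.
#'
#' @param path file path.
#' @param format `"edge_list"` or `"dense"`.
#' @param header for `edge_list`, whether the first line is a header to skip.
#' @return an [assoc_matrix()].
#' @export
read_associations <- function(path, format = c("edge_list", "dense"),
                              header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edge_list") {
    lines <- readLines(path, warn = FALSE)
    offset <- if (header) 1L else 0L
    if (header && length(lines)) lines <- lines[-1]
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty association file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 2)) {
      bad <- which(nf < 2)[1]
      stop(sprintf("malformed edge list line %d (need >= 2 tab-separated fields): %s",
                   bad + offset, lines[bad]))
    }
    rows <- vapply(parts, `[[`, "", 1L)
    cols <- vapply(parts, `[[`, "", 2L)
    row_ids <- unique(rows)
    col_ids <- unique(cols)
    Y <- matrix(0, length(row_ids), length(col_ids),
                dimnames = list(row_ids, col_ids))
    Y[cbind(match(rows, row_ids), match(cols, col_ids))] <- 1
    assoc_matrix(Y)
  } else {
    df <- utils::read.delim(path, header = TRUE, row.names = 1,
                            check.names = FALSE, colClasses = NA)
    if (!nrow(df) || !ncol(df)) stop("empty association file: ", path)
    Y <- as.matrix(df)
    if (!is.numeric(Y) || !all(Y %in% c(0, 1))) {
      stop("dense association matrix is not binary (entries must be 0 or 1)")
    }
    assoc_matrix(Y)
  }
}

#' Write an association matrix
#'
#' `edge_list` writes one `row_id<TAB>col_id` line per nonzero entry in
#' row-major first-appearance order; `dense` writes the full labelled 0/1
#' table. `read_associations()` of a `dense` dump reproduces labels and
#' values exactly.
#'
#' @param Y an [assoc_matrix()] (binary).
#' @param path output file path.
#' @param format `"edge_list"` or `"dense"`.
#' @export
write_associations <- function(Y, path, format = c("edge_list", "dense")) {
  format <- match.arg(format)
  if (format == "edge_list") {
    idx <- which(t(Y) != 0)  # row-major traversal
    j <- (idx - 1L) %% ncol(Y) + 1L
    i <- (idx - 1L) %/% ncol(Y) + 1L
    writeLines(paste(rownames(Y)[i], colnames(Y)[j], sep = "\t"), path)
  } else {
    df <- data.frame(id = rownames(Y), as.data.frame(unclass(Y)[, , drop = FALSE]),
                     check.names = FALSE)
    names(df)[1] <- ""
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Rank prediction scores and write them as a TSV
#'
#' Rows are `(row_id, col_id, score, rank)` sorted by score descending with
#' ties broken lexicographically by `(row_id, col_id)`, so output is fully
#' deterministic. Known training positives can be excluded, which mirrors the
#' candidate-ranking setting where only novel pairs are of interest.
#'
#' @param scores numeric prediction matrix with dimnames.
#' @param path output path, or `NULL` to return the data frame only.
#' @param top_k optional number of top rows to keep.
#' @param exclude optional binary matrix of the same shape; pairs with
#'   `exclude == 1` (training positives) are dropped before ranking.
#' @return invisibly, the ranked data frame.
#' @export
write_predictions <- function(scores, path = NULL, top_k = NULL, exclude = NULL) {
  if (any(!is.finite(scores))) stop("prediction scores must be finite")
  df <- data.frame(
    row_id = rep(rownames(scores), times = ncol(scores)),
    col_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(unclass(scores)),
    stringsAsFactors = FALSE
  )
  if (!is.null(exclude)) {
    stopifnot(all(dim(exclude) == dim(scores)))
    df <- df[as.vector(unclass(exclude)) == 0, , drop = FALSE]
  }
  ord <- order(-df$score, df$row_id, df$col_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  if (!is.null(top_k)) df <- utils::head(df, top_k)
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
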