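# Suppression-aware tabular output. Every analytics module returns a
# result_table: a tibble whose count columns (and any percentage column
# derived from them) can be masked by small-cell suppression. A masked cell
# is NA in the data with a parallel suppression flag, so no recoverable
# count survives into any serialization.

#' Construct a result table
#'
#' @param df tibble of results.
#' @param count_cols names of columns holding disclosure-relevant counts.
#' @param pct_map named character vector mapping a count column to the
#'   percentage column derived from it (masked together).
#' @return an object of class `result_table`.
#' @export
result_table <- function(df, count_cols = character(), pct_map = character()) {
  df <- as_tibble(df)
  stopifnot(all(count_cols %in% names(df)), all(pct_map %in% names(df)),
            all(names(pct_map) %in% count_cols))
  flags <- as.data.frame(matrix(FALSE, nrow(df), length(count_cols)))
  names(flags) <- count_cols
  structure(df, count_cols = count_cols, pct_map = pct_map,
            suppressed = flags, threshold = NA_real_,
            class = c("result_table", class(df)))
}

#' Mask small counts in a result table
#'
#' Every count `c` with `0 < c < threshold` is replaced by `NA` and flagged;
#' a percentage column derived from a masked count is masked with it. Zero
#' counts are not masked (zero reveals only absence). The operation is
#' idempotent and monotone in `threshold`: re-applying, or applying a higher
#' threshold, never unmasks a cell.
#'
#' @param table a [result_table()].
#' @param threshold positive integer; counts in `1..threshold-1` are masked.
#' @return the suppressed `result_table`.
#' @export
suppress_small_counts <- function(table, threshold) {
  stopifnot(inherits(table, "result_table"), threshold >= 1)
  flags <- attr(table, "suppressed")
  pct_map <- attr(table, "pct_map")
  for (cc in attr(table, "count_cols")) {
    x <- table[[cc]]
    mask <- !is.na(x) & x > 0 & x < threshold
    flags[[cc]] <- flags[[cc]] | mask
    x[flags[[cc]]] <- NA_real_
    table[[cc]] <- x
    pc <- pct_map[cc]
    if (!is.na(pc) && nzchar(pc)) {
      p <- table[[pc]]
      p[flags[[cc]]] <- NA_real_
      table[[pc]] <- p
    }
  }
  attr(table, "suppressed") <- flags
  prev <- attr(table, "threshold")
  attr(table, "threshold") <- max(threshold, prev, na.rm = TRUE)
  table
}

#' @export
as_tibble.result_table <- function(x, ...) {
  for (a in c("count_cols", "pct_map", "suppressed", "threshold")) {
    attr(x, a) <- NULL
  }
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Suppression status of a result table
#' @param table a [result_table()].
#' @return list with `threshold` and the logical flag frame `flags`.
#' @export
suppression_info <- function(table) {
  list(threshold = attr(table, "threshold"), flags = attr(table, "suppressed"))
}

format_cell <- function(x, suppressed, threshold, digits = 2) {
  out <- ifelse(suppressed, paste0("<", threshold),
                ifelse(is.na(x), "", format(round(x, digits), trim = TRUE)))
  out
}

#' Render a result table with suppression markers
#'
#' @param x a [result_table()].
#' @param digits digits for non-count cells.
#' @param ... unused.
#' @return character data frame; masked count cells show `"<threshold"`.
#' @export
format.result_table <- function(x, digits = 2, ...) {
  flags <- attr(x, "suppressed")
  thr <- attr(x, "threshold")
  out <- as.data.frame(lapply(names(x), function(nm) {
    col <- x[[nm]]
    cc <- names(flags)[match(nm, names(flags))]
    pct_of <- names(attr(x, "pct_map"))[match(nm, attr(x, "pct_map"))]
    if (!is.na(cc)) {
      format_cell(col, flags[[nm]], thr, digits = 0)
    } else if (!is.na(pct_of)) {
      format_cell(col, flags[[pct_of]], thr, digits = digits)
    } else if (is.numeric(col)) {
      ifelse(is.na(col), "", format(round(col, digits), trim = TRUE))
    } else {
      ifelse(is.na(col), "", as.character(col))
    }
  }), stringsAsFactors = FALSE)
  names(out) <- names(x)
  out
}

#' @export
print.result_table <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat("<result_table>", nrow(x), "row(s)",
      if (!is.na(thr)) sprintf("(small cells < %g suppressed)", thr) else "", "\n")
  print(format(x), row.names = FALSE)
  invisible(x)
}

#' Serialize a result table
#'
#' CSV renders masked cells as `"<threshold"`; JSON carries the cell values
#' (`null` where masked) together with the suppression flags and threshold.
#'
#' @param table a [result_table()].
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path, format = c("csv", "json")) {
  format <- arg_match(format)
  if (format == "csv") {
    utils::write.csv(format(table), path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(threshold = attr(table, "threshold"),
           columns = as.list(as_tibble(table)),
           suppressed = attr(table, "suppressed")),
      path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}
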