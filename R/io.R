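#' Read a contingency table from a CSV file
#'
#' Reads a square grid of nonnegative integer counts. Row/column labels and
#' an appended marginal-totals row/column (common in published agreement
#' tables) are detected automatically: a leading non-numeric column or
#' header line is taken as labels, and a trailing row and column that both
#' equal the marginal sums of the remaining grid (with the grand total in
#' the corner) are validated and stripped. Totals that do not match the
#' counts raise an error naming the offending row or column. A row or
#' column labelled "Total" (case-insensitive) is always treated as a totals
#' margin and must validate.
#'
#' @param path path to the CSV file (or a connection).
#' @param sep field separator, default comma.
#' @return a \code{contingency_table}.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("40,5", "3,2"), tf)
#' read_contingency_csv(tf)
#' @export
read_contingency_csv <- function(path, sep = ",") {
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      stringsAsFactors = FALSE,
                      colClasses = "character",
                      strip.white = TRUE, blank.lines.skip = TRUE),
    error = function(e) {
      stop("malformed (ragged?) CSV grid: ", conditionMessage(e))
    }
  )
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop("empty file: no contingency table found")
  }
  raw <- as.matrix(raw)
  is_num <- function(v) !anyNA(suppressWarnings(as.numeric(v))) &&
    all(nzchar(trimws(v)))

  row_labels <- col_labels <- NULL
  # a non-numeric first row is a header; a non-numeric first column, labels
  if (!is_num(raw[1, ])) {
    col_labels <- raw[1, ]
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) == 0) stop("no numeric rows found")
  if (!is_num(raw[, 1])) {
    row_labels <- raw[, 1]
    raw <- raw[, -1, drop = FALSE]
    if (!is.null(col_labels)) {
      col_labels <- col_labels[-1]
    }
  }
  if (any(!apply(raw, 1, is_num))) {
    bad <- which(!apply(raw, 1, is_num))
    stop("non-numeric or ragged entries in row ", paste(bad, collapse = ", "))
  }
  counts <- matrix(as.numeric(raw), nrow(raw), ncol(raw))

  labelled_total <- function(labs) {
    !is.null(labs) && grepl("^total$", trimws(labs[length(labs)]),
                            ignore.case = TRUE)
  }
  # totals margins: a labelled "Total" row/column must validate; unlabelled
  # margins are detected when they exactly reproduce the marginal sums
  strip_totals_row <- function(counts) {
    r <- nrow(counts)
    core <- counts[-r, , drop = FALSE]
    if (!all(counts[r, ] == colSums(core))) {
      bad <- which(counts[r, ] != colSums(core))
      stop("totals row does not match the counts in column ",
           paste(bad, collapse = ", "))
    }
    core
  }
  if (labelled_total(row_labels)) {
    counts <- strip_totals_row(counts)
    row_labels <- row_labels[-length(row_labels)]
  }
  if (labelled_total(col_labels)) {
    counts <- t(strip_totals_row(t(counts)))
    col_labels <- col_labels[-length(col_labels)]
  }

  r <- nrow(counts); cc <- ncol(counts)
  if (r == cc + 1 && all(counts[r, ] == colSums(counts[-r, , drop = FALSE]))) {
    counts <- counts[-r, , drop = FALSE]
    if (!is.null(row_labels)) row_labels <- row_labels[-r]
  } else if (cc == r + 1 &&
             all(counts[, cc] == rowSums(counts[, -cc, drop = FALSE]))) {
    counts <- counts[, -cc, drop = FALSE]
    if (!is.null(col_labels)) col_labels <- col_labels[-cc]
  } else if (r == cc && r >= 3) {
    m <- r
    core <- counts[-m, -m, drop = FALSE]
    if (all(counts[m, -m] == colSums(core)) &&
        all(counts[-m, m] == rowSums(core)) &&
        counts[m, m] == sum(core)) {
      counts <- core
      if (!is.null(row_labels)) row_labels <- row_labels[-m]
      if (!is.null(col_labels)) col_labels <- col_labels[-m]
    }
  }

  if (nrow(counts) != ncol(counts)) {
    stop("grid is not square (", nrow(counts), "x", ncol(counts),
         "); a contingency table needs equal numbers of rows and columns")
  }
  labels <- if (!is.null(row_labels)) row_labels else col_labels
  contingency_table(counts, labels = labels)
}

#' Write a contingency table to CSV
#'
#' Inverse of \code{\link{read_contingency_csv}}: writes the bare counts
#' (with labels when present), so that reading the file back reproduces the
#' table exactly.
#'
#' @param table a contingency table.
#' @param path output file path.
#' @param sep field separator.
#' @return invisibly, the path.
#' @export
write_contingency_csv <- function(table, path, sep = ",") {
  table <- .ct(table)
  counts <- unclass(table)
  has_labels <- !is.null(rownames(counts))
  utils::write.table(counts, path, sep = sep,
                     row.names = has_labels,
                     col.names = if (has_labels) NA else FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Render an agreement report as text or JSON
#'
#' The text format is the human-readable rendering of the report's print
#' method, with a 3-decimal display. The JSON format serialises every field
#' at full double precision, so \code{\link{parse_report}} reproduces the
#' report exactly; undefined indices are carried as nulls together with
#' their validity flags, never as fabricated numbers.
#'
#' @param report an \code{agreement_report}.
#' @param format \code{"text"} or \code{"json"}.
#' @param path optional file to write to; when missing, the rendering is
#'   returned as a character string only.
#' @return the rendering, invisibly when written to a file.
#' @export
write_report <- function(report, format = c("text", "json"), path = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  format <- match.arg(format)
  out <- if (format == "text") {
    paste(utils::capture.output(print(report)), collapse = "\n")
  } else {
    # 17 significant digits: doubles survive the round trip bit-exactly
    jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = I(17),
                     null = "null", na = "null")
  }
  if (!is.null(path)) {
    writeLines(as.character(out), path)
    return(invisible(out))
  }
  as.character(out)
}

#' @rdname write_report
#' @param text a JSON rendering produced by \code{write_report}, or a path
#'   to a file containing one.
#' @export
parse_report <- function(text) {
  parsed <- jsonlite::fromJSON(text)
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  parsed$kappa <- num_or_na(parsed$kappa)
  parsed$ia <- num_or_na(parsed$ia)
  if (is.null(parsed$kappa_band)) parsed$kappa_band <- NA_character_
  structure(parsed, class = "agreement_report")
}
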