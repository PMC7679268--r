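#' Construct a validated contingency table of paired ratings
#'
#' A contingency table holds the cross-tabulated counts of two raters scoring
#' the same N subjects on a common ordered q-level scale: entry (i, j) is the
#' number of subjects rated i by the row rater and j by the column rater.
#' It is the universal input of all agreement computations in this package.
#'
#' Counts must be nonnegative whole numbers: all downstream probabilities are
#' plug-in relative frequencies n(x, y) / N, so fractional "weights" have no
#' meaning here and are rejected.
#'
#' @param counts a square numeric matrix (q >= 2) of nonnegative integers, or
#'   an object coercible to one.
#' @param labels optional character vector of category names, length q, applied
#'   to both dimensions.
#' @return an object of class \code{"contingency_table"}: an integer matrix
#'   with both raters' categories in the same order.
#' @examples
#' ct <- contingency_table(matrix(c(40, 3, 5, 2), 2))
#' sum(ct)            # N = 50
#' rowSums(ct)        # row rater marginal counts
#' @export
contingency_table <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("counts must be numeric")
  }
  if (nrow(counts) != ncol(counts)) {
    stop("counts must be a square matrix (got ", nrow(counts), "x", ncol(counts), ")")
  }
  q <- nrow(counts)
  if (q < 2) {
    stop("at least two rating categories are required (q >= 2)")
  }
  if (anyNA(counts)) {
    stop("counts must not contain missing values")
  }
  if (any(counts < 0)) {
    stop("counts must be nonnegative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be whole numbers; fractional weights are not supported")
  }
  if (sum(counts) <= 0) {
    stop("empty table: total count must be positive")
  }
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  if (!is.null(labels)) {
    if (length(labels) != q) {
      stop("labels must have length q = ", q)
    }
    dimnames(counts) <- list(labels, labels)
  }
  structure(counts, class = c("contingency_table", "matrix"))
}

#' Test or coerce to a contingency table
#'
#' @param x an object.
#' @return \code{is_contingency_table} returns a logical scalar;
#'   \code{as_contingency_table} returns a validated table.
#' @export
is_contingency_table <- function(x) inherits(x, "contingency_table")

#' @rdname is_contingency_table
#' @export
as_contingency_table <- function(x) {
  if (is_contingency_table(x)) x else contingency_table(x)
}

# Validate-or-coerce used at the top of every operation taking a table.
.ct <- function(table) {
  if (!is_contingency_table(table)) {
    table <- contingency_table(table)
  }
  table
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table of paired ratings (q = ", nrow(x),
      ", N = ", sum(x), ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Transpose a contingency table
#'
#' Swaps the roles of the two raters. Both Cohen's kappa and the informational
#' agreement are invariant under this operation; the channel transition matrix
#' and sensitivity/specificity are not.
#'
#' @param x a contingency table.
#' @return the transposed \code{contingency_table}.
#' @export
t.contingency_table <- function(x) {
  contingency_table(t(unclass(x)), labels = rownames(x))
}

#' Joint rating distribution of a contingency table
#'
#' Converts counts to the plug-in joint probability distribution
#' p(x, y) = n(x, y) / N together with its two marginals. The row marginal is
#' the distribution of the row rater's scores, the column marginal that of the
#' column rater.
#'
#' @param table a contingency table (or matrix coercible to one).
#' @return an object of class \code{"joint_distribution"}: a list with
#'   elements \code{probs} (q x q matrix summing to 1), \code{marginal_row}
#'   and \code{marginal_col} (probability vectors).
#' @examples
#' j <- joint_from_table(contingency_table(matrix(c(40, 3, 5, 2), 2)))
#' j$probs
#' j$marginal_row
#' @export
joint_from_table <- function(table) {
  table <- .ct(table)
  n <- sum(table)
  joint_distribution(unclass(table) / n)
}

#' Construct a joint distribution from a probability matrix
#'
#' @param probs a square matrix of joint probabilities summing to 1.
#' @return an object of class \code{"joint_distribution"}.
#' @export
joint_distribution <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) {
    stop("joint probability matrix must be square")
  }
  if (any(probs < 0)) {
    stop("joint probabilities must be nonnegative")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("joint probabilities must sum to 1 (got ", format(sum(probs)), ")")
  }
  structure(
    list(
      probs = probs,
      marginal_row = rowSums(probs),
      marginal_col = colSums(probs)
    ),
    class = "joint_distribution"
  )
}

#' @export
print.joint_distribution <- function(x, digits = 4, ...) {
  cat("Joint rating distribution (q = ", nrow(x$probs), ")\n", sep = "")
  print(round(x$probs, digits))
  cat("row marginal: ", paste(round(x$marginal_row, digits), collapse = " "), "\n")
  cat("col marginal: ", paste(round(x$marginal_col, digits), collapse = " "), "\n")
  invisible(x)
}

# Validate a probability vector; returns it unchanged.
.pv <- function(p, what = "probability vector") {
  if (!is.numeric(p) || length(p) < 2) {
    stop(what, " must be a numeric vector of length >= 2")
  }
  if (any(p < 0)) {
    stop(what, " must have nonnegative entries")
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop(what, " must sum to 1 (got ", format(sum(p)), ")")
  }
  p
}
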