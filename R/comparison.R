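#' Agreement matrix of two classifiers' correctness patterns
#'
#' Two trained classifiers scored on the same labelled data set each mark
#' every entry as correctly (C) or wrongly (W) classified. Tallying the four
#' combinations gives a 2 x 2 agreement matrix whose first row/column counts
#' the entries the first/second model got right -- the same object as a
#' two-rater contingency table, so kappa and IA apply directly to
#' classifier-agreement analysis.
#'
#' @param a logical vector: model A correct per entry.
#' @param b logical vector: model B correct per entry, same length.
#' @return a 2 x 2 \code{contingency_table} with categories C, W; rows are
#'   model A, columns model B.
#' @examples
#' correctness_table(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
#' @export
correctness_table <- function(a, b) {
  if (!is.logical(a) || !is.logical(b)) {
    stop("correctness vectors must be logical")
  }
  if (length(a) != length(b)) {
    stop("correctness vectors must have the same length (",
         length(a), " vs ", length(b), ")")
  }
  if (length(a) == 0 || anyNA(a) || anyNA(b)) {
    stop("correctness vectors must be nonempty and complete")
  }
  counts <- matrix(c(
    sum(a & b), sum(!a & b),
    sum(a & !b), sum(!a & !b)
  ), 2, 2)
  contingency_table(counts, labels = c("C", "W"))
}

#' Pearson product-moment correlation with validation
#'
#' Thin wrapper over \code{stats::cor} that enforces the preconditions used
#' when correlating sequences of agreement indices: at least three pairs and
#' nonzero variance in each sequence (a constant sequence has no defined
#' correlation and yields \code{NA} with a warning).
#'
#' @param xs,ys numeric vectors of equal length >= 3.
#' @return Pearson's rho in [-1, 1], or \code{NA} for degenerate input.
#' @export
pearson <- function(xs, ys) {
  .check_cor_input(xs, ys)
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    warning("Pearson correlation undefined: a sequence has zero variance")
    return(NA_real_)
  }
  stats::cor(xs, ys, method = "pearson")
}

#' Spearman rank correlation with average ranks for ties
#'
#' Pearson correlation of the rank transforms, with tied values receiving
#' their average rank (the \code{stats::cor} convention). On tie-free data
#' this equals the classical 1 - 6 sum(d^2) / (n (n^2 - 1)) formula.
#'
#' @param xs,ys numeric vectors of equal length >= 3.
#' @return Spearman's r_s in [-1, 1], or \code{NA} for degenerate input.
#' @export
spearman <- function(xs, ys) {
  .check_cor_input(xs, ys)
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    warning("Spearman correlation undefined: a sequence is constant")
    return(NA_real_)
  }
  stats::cor(xs, ys, method = "spearman")
}

.check_cor_input <- function(xs, ys) {
  if (!is.numeric(xs) || !is.numeric(ys)) {
    stop("correlation inputs must be numeric")
  }
  if (length(xs) != length(ys)) {
    stop("sequences must have equal length")
  }
  if (length(xs) < 3) {
    stop("at least 3 pairs are required")
  }
  if (anyNA(xs) || anyNA(ys)) {
    stop("sequences must not contain missing values")
  }
  invisible(TRUE)
}

#' Compare agreement indices across all pairs of classifiers
#'
#' Given per-entry correctness flags for several models (one logical column
#' per model), builds the 2 x 2 agreement matrix for every model pair,
#' evaluates Cohen's kappa and the informational agreement on each, and
#' correlates the resulting kappa and IA sequences with Pearson's rho and
#' Spearman's r_s. A high rho with a lower r_s indicates the two indices
#' track each other numerically but rank the model pairs differently.
#'
#' @param flags a logical matrix or data frame; rows are data set entries,
#'   columns are models (>= 3 model pairs, i.e. >= 3 models, are needed for
#'   the correlations).
#' @return an object of class \code{"agreement_comparison"}: a list with
#'   \code{pairs} (data frame with columns \code{model_a}, \code{model_b},
#'   \code{kappa}, \code{ia}), \code{rho}, \code{r_s} and \code{n_pairs}.
#' @examples
#' set.seed(1)
#' flags <- matrix(runif(300) > 0.3, ncol = 3,
#'                 dimnames = list(NULL, c("rf", "knn", "nb")))
#' agreement_comparison(flags)
#' @export
agreement_comparison <- function(flags) {
  flags <- as.matrix(flags)
  if (!is.logical(flags)) {
    stop("flags must be logical (TRUE = correctly classified)")
  }
  m <- ncol(flags)
  if (m < 2) {
    stop("at least two models are required")
  }
  names <- colnames(flags)
  if (is.null(names)) names <- paste0("M", seq_len(m))
  combos <- utils::combn(m, 2)
  n_pairs <- ncol(combos)
  kappa <- ia <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    ct <- correctness_table(flags[, combos[1, k]], flags[, combos[2, k]])
    kappa[k] <- suppressWarnings(cohen_kappa(ct))
    ia[k] <- suppressWarnings(informational_agreement(ct))
  }
  pairs <- data.frame(
    model_a = names[combos[1, ]],
    model_b = names[combos[2, ]],
    kappa = kappa,
    ia = ia
  )
  ok <- !is.na(kappa) & !is.na(ia)
  rho <- r_s <- NA_real_
  if (sum(ok) >= 3) {
    rho <- suppressWarnings(pearson(ia[ok], kappa[ok]))
    r_s <- suppressWarnings(spearman(ia[ok], kappa[ok]))
  }
  structure(
    list(pairs = pairs, rho = rho, r_s = r_s, n_pairs = n_pairs),
    class = "agreement_comparison"
  )
}

#' @export
print.agreement_comparison <- function(x, digits = 3, ...) {
  cat("Classifier agreement comparison (", x$n_pairs, " model pairs)\n",
      sep = "")
  df <- x$pairs
  df$kappa <- round(df$kappa, digits)
  df$ia <- round(df$ia, digits)
  print(df, row.names = FALSE)
  cat("IA vs kappa: Pearson rho =", round(x$rho, digits),
      "| Spearman r_s =", round(x$r_s, digits), "\n")
  invisible(x)
}
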