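#' Channel transition matrix of a contingency table
#'
#' The agreement between two raters can be viewed as information flowing
#' through a virtual channel connecting their rating variables. The channel
#' is characterised by the column-stochastic transition matrix Gamma whose
#' entry (y, x) is the conditional probability p(Y = y | X = x). By
#' convention the conditioning variable X is the column rater of the table
#' (categories across the top), so Gamma is obtained by normalising each
#' column of the counts by its column total; set \code{transpose = TRUE} to
#' condition on the row rater instead. Gamma captures the "nucleus of
#' agreement" between the raters, free of the prevalence of the condition,
#' which enters only through the marginal distribution of X.
#'
#' @param table a contingency table with every conditioning-category total
#'   positive.
#' @param transpose if \code{TRUE}, condition on the row rater.
#' @return an object of class \code{"transition_matrix"}: a q x q
#'   column-stochastic matrix.
#' @examples
#' ct <- contingency_table(matrix(c(40, 3, 5, 2), 2))
#' transition_matrix(ct)   # columns 40/43, 3/43 and 5/7, 2/7
#' @export
transition_matrix <- function(table, transpose = FALSE) {
  table <- .ct(table)
  counts <- unclass(table)
  if (transpose) counts <- t(counts)
  totals <- colSums(counts)
  empty <- which(totals == 0)
  if (length(empty) > 0) {
    stop("conditioning category ", paste(empty, collapse = ", "),
         " has no observations; transition matrix undefined")
  }
  probs <- sweep(counts, 2, totals, "/")
  storage.mode(probs) <- "double"
  structure(probs, class = c("transition_matrix", "matrix"))
}

#' Validate and construct a transition matrix from raw probabilities
#'
#' @param probs a square matrix whose columns each sum to 1.
#' @return an object of class \code{"transition_matrix"}.
#' @export
as_transition_matrix <- function(probs) {
  if (inherits(probs, "transition_matrix")) return(probs)
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) {
    stop("transition matrix must be square")
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  bad <- which(abs(colSums(probs) - 1) > 1e-12)
  if (length(bad) > 0) {
    stop("column ", paste(bad, collapse = ", "),
         " of the transition matrix does not sum to 1")
  }
  structure(probs, class = c("transition_matrix", "matrix"))
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Channel transition matrix (column-stochastic, q = ", nrow(x), ")\n",
      sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Mutual information from the channel decomposition
#'
#' Computes MI directly from the input distribution P_X and the transition
#' matrix Gamma, without forming the joint:
#' MI = sum_{x,y} p_X(x) Gamma(y, x) log( Gamma(y, x) / p_Y(y) ), where
#' p_Y(y) = sum_z p_X(z) Gamma(y, z) is the induced output distribution.
#' This factorisation shows MI depends only on (P_X, Gamma): the prevalence
#' of the condition acts through P_X alone while Gamma is the
#' prevalence-free relation between the raters. The result equals
#' \code{\link{mutual_information}} of the induced joint.
#'
#' @param p_x input (conditioning-rater) probability vector, length q.
#' @param gamma a q x q \code{transition_matrix} (or column-stochastic
#'   matrix).
#' @param base logarithm base > 1; defaults to q.
#' @return MI >= 0 in units of the chosen base.
#' @export
mi_from_channel <- function(p_x, gamma, base = length(p_x)) {
  p_x <- .pv(p_x, "p_x")
  gamma <- as_transition_matrix(gamma)
  if (nrow(gamma) != length(p_x)) {
    stop("dimension mismatch: p_x has length ", length(p_x),
         " but gamma is ", nrow(gamma), "x", ncol(gamma))
  }
  .check_base(base)
  p_y <- as.vector(gamma %*% p_x)
  mi <- 0
  for (x in seq_along(p_x)) {
    if (p_x[x] <= 0) next
    for (y in seq_along(p_y)) {
      g <- gamma[y, x]
      if (g > 0) {
        mi <- mi + p_x[x] * g * log(g / p_y[y], base = base)
      }
    }
  }
  max(mi, 0)
}

#' Informational agreement from the channel decomposition
#'
#' IA of the joint distribution induced by an input distribution P_X and a
#' transition matrix Gamma. Since IA is fully determined by (P_X, Gamma),
#' this enables prevalence sweeps: holding the channel fixed and varying P_X
#' shows how much of an agreement value is marginal (prevalence) structure
#' rather than rater concordance.
#'
#' @inheritParams mi_from_channel
#' @return IA in [0, 1], or \code{NA} with a warning when an induced
#'   marginal is degenerate.
#' @export
ia_from_channel <- function(p_x, gamma) {
  p_x <- .pv(p_x, "p_x")
  gamma <- as_transition_matrix(gamma)
  if (nrow(gamma) != length(p_x)) {
    stop("dimension mismatch: p_x has length ", length(p_x),
         " but gamma is ", nrow(gamma), "x", ncol(gamma))
  }
  p_y <- as.vector(gamma %*% p_x)
  h_x <- entropy(p_x)
  h_y <- entropy(p_y)
  h_min <- min(h_x, h_y)
  if (h_min <= 0) {
    warning("IA undefined: a marginal of the induced joint is degenerate")
    return(NA_real_)
  }
  min(mi_from_channel(p_x, gamma) / h_min, 1)
}

#' Sensitivity and specificity of a binary channel
#'
#' For a dichotomous scale with category 1 = condition present, the
#' sensitivity of the output rater is Gamma(1, 1) -- the probability of
#' rating "present" when the conditioning rater says present -- and the
#' specificity is Gamma(2, 2).
#'
#' @param gamma a 2 x 2 transition matrix.
#' @return named numeric vector \code{c(sensitivity = , specificity = )}.
#' @examples
#' sensitivity_specificity(diag(2))   # perfect rater: (1, 1)
#' @export
sensitivity_specificity <- function(gamma) {
  gamma <- as_transition_matrix(gamma)
  if (nrow(gamma) != 2) {
    stop("sensitivity/specificity require a dichotomous (q = 2) channel")
  }
  c(sensitivity = gamma[1, 1], specificity = gamma[2, 2])
}

#' Simulate paired ratings through an agreement channel
#'
#' Generates a contingency table by drawing n subjects: for each, the
#' conditioning rater's score x is drawn from \code{p_x} and the other
#' rater's score y from column x of \code{gamma}. The tallied table has the
#' package's channel orientation (conditioning rater across the columns), so
#' \code{transition_matrix(simulate_ratings(p, g, n))} converges to \code{g}
#' at the usual root-n Monte Carlo rate. Sampling uses R's default
#' Mersenne-Twister generator; the same seed reproduces the same table on
#' any platform with that default.
#'
#' @param p_x input probability vector, length q.
#' @param gamma q x q column-stochastic transition matrix.
#' @param n number of subjects, >= 1.
#' @param seed integer seed; the caller's random-number state is left
#'   untouched.
#' @return a \code{contingency_table} with total count n.
#' @examples
#' g <- matrix(c(0.93, 0.07, 0.71, 0.29), 2)
#' simulate_ratings(c(0.9, 0.1), g, n = 1000, seed = 1)
#' @export
simulate_ratings <- function(p_x, gamma, n, seed) {
  p_x <- .pv(p_x, "p_x")
  gamma <- as_transition_matrix(gamma)
  q <- length(p_x)
  if (nrow(gamma) != q) {
    stop("dimension mismatch between p_x and gamma")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  x <- sample.int(q, n, replace = TRUE, prob = p_x)
  y <- integer(n)
  for (k in seq_len(q)) {
    idx <- which(x == k)
    if (length(idx) > 0) {
      y[idx] <- sample.int(q, length(idx), replace = TRUE, prob = gamma[, k])
    }
  }
  counts <- table(factor(y, levels = seq_len(q)),
                  factor(x, levels = seq_len(q)))
  contingency_table(matrix(as.integer(counts), q, q))
}
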