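#' Shannon entropy of a discrete distribution
#'
#' H(X) = -sum_x p(x) log_base p(x), with the continuity convention
#' 0 log 0 = 0. The default logarithm base is q, the number of categories, so
#' that entropy is normalised to [0, 1] regardless of the scale length; use
#' \code{base = 2} for bits.
#'
#' @param p a probability vector (nonnegative, sums to 1).
#' @param base logarithm base, a real > 1. Defaults to \code{length(p)}.
#' @return the entropy in units of the chosen base; lies in
#'   [0, log_base(length(p))].
#' @examples
#' entropy(c(0.5, 0.5), base = 2)   # 1 bit: uniform coin
#' entropy(c(1, 0), base = 2)       # 0: degenerate
#' @export
entropy <- function(p, base = length(p)) {
  p <- .pv(p)
  .check_base(base)
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}

.check_base <- function(base) {
  if (!is.numeric(base) || length(base) != 1 || !is.finite(base) || base <= 1) {
    stop("logarithm base must be a single real > 1")
  }
  invisible(base)
}

#' Conditional entropy of one rater's score given the other's
#'
#' H(Y/X) = -sum_{x,y} p(x, y) log_base( p(x, y) / p_X(x) ), quantifying the
#' information left in Y once X is known. Cells with p(x, y) = 0 contribute
#' nothing (0 log 0 = 0), and empty conditioning categories (p_X(x) = 0, which
#' forces all their joint cells to 0) contribute nothing either -- the
#' continuity policy matching the right-limit behaviour of x log x at 0.
#'
#' @param joint a \code{joint_distribution}; the conditioning variable X is
#'   the one named by \code{conditioning}.
#' @param base logarithm base > 1; defaults to q.
#' @param conditioning \code{"row"} (default) to condition on the row
#'   marginal, \code{"col"} to condition on the column marginal.
#' @return H(Y/X), in [0, H(Y)].
#' @examples
#' j <- joint_distribution(diag(2) / 2)
#' conditional_entropy(j, base = 2)   # 0: Y determined by X
#' @export
conditional_entropy <- function(joint, base = nrow(joint$probs),
                                conditioning = c("row", "col")) {
  stopifnot(inherits(joint, "joint_distribution"))
  .check_base(base)
  conditioning <- match.arg(conditioning)
  probs <- joint$probs
  px <- if (conditioning == "row") joint$marginal_row else joint$marginal_col
  if (conditioning == "col") probs <- t(probs)
  h <- 0
  for (x in seq_along(px)) {
    if (px[x] <= 0) next
    row <- probs[x, ]
    nz <- row > 0
    h <- h - sum(row[nz] * log(row[nz] / px[x], base = base))
  }
  h
}

#' Mutual information between the two raters' scores
#'
#' MI(X, Y) = sum_{x,y} p(x, y) log_base( p(x, y) / (p_X(x) p_Y(y)) ), the
#' stochastic dependence between the two rating variables: zero if and only
#' if the raters score independently, and bounded above by the smaller of the
#' two marginal entropies. Zero-probability cells contribute nothing.
#'
#' The identity MI = H(Y) - H(Y/X) = H(X) - H(X/Y) holds to within floating
#' round-off, as does symmetry under transposition of the joint.
#'
#' @param joint a \code{joint_distribution}.
#' @param base logarithm base > 1; defaults to q.
#' @return MI >= 0 in units of the chosen base.
#' @examples
#' j <- joint_distribution(diag(2) / 2)
#' mutual_information(j, base = 2)    # 1 bit: perfect dependence
#' @export
mutual_information <- function(joint, base = nrow(joint$probs)) {
  stopifnot(inherits(joint, "joint_distribution"))
  .check_base(base)
  probs <- joint$probs
  px <- joint$marginal_row
  py <- joint$marginal_col
  terms <- probs * log(probs / outer(px, py), base = base)
  terms <- terms[probs > 0]
  # summing in a canonical order makes MI bit-identical under transposition
  max(sum(sort(terms)), 0)
}

#' Epsilon-limit probe for zero cells in the informational agreement
#'
#' The package computes IA on tables containing empty cells by the continuity
#' convention 0 log 0 = 0. An equivalent construction replaces every zero
#' count with a small positive epsilon, renormalises, and lets epsilon tend
#' to 0 from the right. This probe evaluates that construction at a concrete
#' epsilon, so the convention can be checked numerically: as epsilon shrinks,
#' the probe converges to \code{\link{informational_agreement}} of the same
#' table. It is a validation device, not the recommended estimator.
#'
#' @param table a contingency table (may contain zero cells).
#' @param epsilon positive pseudo-count in (0, 1e-3] substituted for each
#'   zero cell.
#' @return IA of the epsilon-regularised table.
#' @examples
#' ct <- contingency_table(matrix(c(10, 0, 0, 40), 2))
#' ia_epsilon_probe(ct, 1e-9)
#' informational_agreement(ct)
#' @export
ia_epsilon_probe <- function(table, epsilon) {
  table <- .ct(table)
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon > 1e-3) {
    stop("epsilon must be a single value in (0, 1e-3]")
  }
  counts <- unclass(table)
  storage.mode(counts) <- "double"
  counts[counts == 0] <- epsilon
  probs <- counts / sum(counts)
  joint <- joint_distribution(probs)
  hx <- entropy(joint$marginal_row)
  hy <- entropy(joint$marginal_col)
  if (min(hx, hy) <= 0) {
    stop("degenerate marginal after regularisation; IA undefined")
  }
  mutual_information(joint) / min(hx, hy)
}
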