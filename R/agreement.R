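#' Observed agreement probability
#'
#' The global probability of a match between the two raters: the fraction of
#' subjects lying on the main diagonal of the contingency table,
#' p_o = sum_i n(i, i) / N.
#'
#' @param table a contingency table.
#' @return p_o in [0, 1].
#' @examples
#' observed_agreement(contingency_table(matrix(c(21, 3, 5, 21), 2)))  # 0.84
#' @export
observed_agreement <- function(table) {
  table <- .ct(table)
  sum(diag(unclass(table))) / sum(table)
}

#' Expected (chance) agreement probability
#'
#' The probability of a match explained by chance alone, under independence
#' of the two raters with their observed marginals:
#' p_e = sum_i (n_i. / N)(n_.i / N).
#'
#' @param table a contingency table.
#' @return p_e in [0, 1].
#' @export
expected_agreement <- function(table) {
  table <- .ct(table)
  n <- sum(table)
  sum((rowSums(table) / n) * (colSums(table) / n))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed and p_e the expected agreement. Ranges in [-1, 1] and is
#' invariant under transposing the table (swapping the raters). When both
#' raters put all subjects in the same single category, p_e = 1 and kappa is
#' undefined; \code{NA} is returned with a warning.
#'
#' @param table a contingency table.
#' @return kappa in [-1, 1], or \code{NA} when p_e = 1.
#' @examples
#' cohen_kappa(contingency_table(matrix(c(40, 3, 5, 2), 2)))   # 0.245...
#' @export
cohen_kappa <- function(table) {
  table <- .ct(table)
  po <- observed_agreement(table)
  pe <- expected_agreement(table)
  if (1 - pe <= .Machine$double.eps) {
    warning("kappa undefined: expected agreement is 1 ",
            "(both raters constant on the same category)")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Informational agreement (IA)
#'
#' The mutual information between the two raters' rating variables,
#' normalised by the smaller of their marginal entropies:
#' IA = MI(X, Y) / min(H(X), H(Y)). IA ranges in [0, 1]; it is 0 if and only
#' if the raters score independently, 1 when either rater's score determines
#' the other's, and invariant both to the logarithm base and to transposing
#' the table. Unlike kappa, it weighs the full joint distribution, not just
#' its diagonal, and is therefore insulated from the marginal-imbalance
#' (prevalence) paradoxes that afflict kappa.
#'
#' Zero cells are handled by the continuity convention 0 log 0 = 0,
#' equivalent to the right limit of replacing zeros by a vanishing
#' pseudo-count (see \code{\link{ia_epsilon_probe}}). If either rater uses
#' only a single category its marginal entropy is 0, the ratio is 0/0, and
#' IA is undefined: \code{NA} is returned with a warning.
#'
#' @param table a contingency table.
#' @return IA in [0, 1], or \code{NA} when a marginal entropy is 0.
#' @examples
#' informational_agreement(contingency_table(matrix(c(40, 3, 5, 2), 2)))
#' informational_agreement(contingency_table(diag(c(10, 40))))  # 1
#' @export
informational_agreement <- function(table) {
  table <- .ct(table)
  joint <- joint_from_table(table)
  h_row <- entropy(joint$marginal_row)
  h_col <- entropy(joint$marginal_col)
  h_min <- min(h_row, h_col)
  if (h_min <= 0) {
    warning("IA undefined: a rater used a single category ",
            "(marginal entropy is 0)")
    return(NA_real_)
  }
  mi <- mutual_information(joint)
  min(mi / h_min, 1)
}

#' Verbal interpretation band for Cohen's kappa
#'
#' Maps kappa onto the conventional linear scale: [0, 0.2) none-to-slight,
#' [0.2, 0.4) fair, [0.4, 0.6) moderate, [0.6, 0.8) substantial,
#' [0.8, 1] almost-perfect. Bands are half-open with the top band closed, so
#' every kappa falls in exactly one band. Negative kappa (below-chance
#' agreement) maps to none-to-slight, with attribute
#' \code{below_chance = TRUE}. This scale is conventional for kappa only and
#' is not applicable to IA, whose information-theoretic range compresses
#' values differently.
#'
#' @param kappa a value in [-1, 1].
#' @return one of \code{"none-to-slight"}, \code{"fair"}, \code{"moderate"},
#'   \code{"substantial"}, \code{"almost-perfect"}; for negative input the
#'   result carries attribute \code{below_chance = TRUE}.
#' @examples
#' interpret_kappa(0.681)  # "substantial"
#' interpret_kappa(0.245)  # "fair"
#' @export
interpret_kappa <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) ||
      kappa < -1 || kappa > 1) {
    stop("kappa must be a single value in [-1, 1]")
  }
  if (kappa < 0) {
    return(structure("none-to-slight", below_chance = TRUE))
  }
  bands <- c("none-to-slight", "fair", "moderate", "substantial",
             "almost-perfect")
  idx <- findInterval(kappa, c(0, 0.2, 0.4, 0.6, 0.8), rightmost.closed = FALSE)
  bands[min(idx, 5L)]
}

#' Full agreement report for a contingency table
#'
#' One pass producing every agreement quantity the package computes for a
#' table: marginal and conditional entropies, mutual information, observed
#' and expected agreement, Cohen's kappa with its verbal band, and the
#' informational agreement. Undefined indices (a constant rater) are carried
#' as \code{NA} with explicit validity flags rather than raised as errors, so
#' a report can always be produced.
#'
#' @param table a contingency table.
#' @param base logarithm base for the entropies and MI: \code{"q"} (default,
#'   entropy normalised by the number of categories) or \code{"2"} (bits).
#'   IA itself is base-invariant.
#' @return an object of class \code{"agreement_report"}: a list with fields
#'   \code{q}, \code{n}, \code{base}, \code{H_row}, \code{H_col},
#'   \code{H_cond}, \code{MI}, \code{p_o}, \code{p_e}, \code{kappa},
#'   \code{kappa_band}, \code{ia}, \code{kappa_defined}, \code{ia_defined}.
#' @examples
#' agreement_report(contingency_table(matrix(c(40, 3, 5, 2), 2)))
#' @export
agreement_report <- function(table, base = c("q", "2")) {
  table <- .ct(table)
  base <- match.arg(as.character(base), c("q", "2"))
  q <- nrow(table)
  b <- if (base == "q") q else 2
  joint <- joint_from_table(table)

  h_row <- entropy(joint$marginal_row, base = b)
  h_col <- entropy(joint$marginal_col, base = b)
  h_cond <- conditional_entropy(joint, base = b, conditioning = "col")
  mi <- mutual_information(joint, base = b)
  po <- observed_agreement(table)
  pe <- expected_agreement(table)

  kappa_defined <- (1 - pe) > .Machine$double.eps
  kappa <- if (kappa_defined) (po - pe) / (1 - pe) else NA_real_
  kappa_band <- if (kappa_defined) as.character(interpret_kappa(kappa)) else NA_character_

  h_min <- min(h_row, h_col)
  ia_defined <- h_min > 0
  ia <- if (ia_defined) min(mi / h_min, 1) else NA_real_

  structure(
    list(
      q = q, n = sum(table), base = b,
      H_row = h_row, H_col = h_col, H_cond = h_cond, MI = mi,
      p_o = po, p_e = pe,
      kappa = kappa, kappa_band = kappa_band,
      ia = ia,
      kappa_defined = kappa_defined, ia_defined = ia_defined
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  cat("Agreement report (q = ", x$q, ", N = ", x$n,
      ", log base ", x$base, ")\n", sep = "")
  cat("  entropies        H(row) = ", fmt(x$H_row),
      "   H(col) = ", fmt(x$H_col),
      "   H(row/col) = ", fmt(x$H_cond), "\n", sep = "")
  cat("  mutual info      MI = ", fmt(x$MI), "\n", sep = "")
  cat("  agreement        p_o = ", fmt(x$p_o),
      "   p_e = ", fmt(x$p_e), "\n", sep = "")
  if (x$kappa_defined) {
    cat("  Cohen's kappa    ", fmt(x$kappa), "  (", x$kappa_band, ")\n",
        sep = "")
  } else {
    cat("  Cohen's kappa    undefined (expected agreement is 1)\n")
  }
  if (x$ia_defined) {
    cat("  informational agreement IA = ", fmt(x$ia), "\n", sep = "")
  } else {
    cat("  informational agreement IA = undefined",
        " (a rater used a single category)\n", sep = "")
  }
  invisible(x)
}
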