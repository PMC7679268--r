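#' Collapse an ordered q-level table to a dichotomous one
#'
#' Dichotomises a multivalue ordered-categorical table at threshold t:
#' categories 1..t become class 1 ("not significant") and categories
#' t+1..q become class 2 ("significant"). Cell (1, 1) of the result sums the
#' block of cells with both ratings <= t, cell (2, 2) the block with both
#' ratings > t, and the off-diagonal cells the two mixed blocks; the total
#' count N is preserved. This is, for example, how a 5-grade BI-RADS scale
#' is reduced to "BI-RADS 1-2" versus "BI-RADS 3-4-5" at t = 2.
#'
#' @param table a contingency table with q >= 2 categories.
#' @param t threshold, an integer in 1..q-1: the last category of the lower
#'   class.
#' @return a 2 x 2 \code{contingency_table} with the same total count.
#' @examples
#' ct <- contingency_table(diag(c(5, 4, 3, 2, 1)))
#' collapse_table(ct, 2)
#' @export
collapse_table <- function(table, t) {
  table <- .ct(table)
  q <- nrow(table)
  if (!is.numeric(t) || length(t) != 1 || t != round(t) || t < 1 || t > q - 1) {
    stop("threshold t must be an integer in 1..", q - 1)
  }
  lo <- seq_len(t)
  hi <- seq.int(t + 1, q)
  counts <- unclass(table)
  collapsed <- matrix(c(
    sum(counts[lo, lo]), sum(counts[hi, lo]),
    sum(counts[lo, hi]), sum(counts[hi, hi])
  ), 2, 2)
  labels <- if (!is.null(rownames(table))) {
    c(paste(rownames(table)[lo], collapse = "+"),
      paste(rownames(table)[hi], collapse = "+"))
  } else {
    c(paste0("1-", t), paste0(t + 1, "-", q))
  }
  contingency_table(collapsed, labels = labels)
}

#' Scan all dichotomisation thresholds of an ordered table
#'
#' Collapses the table at every threshold t in 1..q-1, computes Cohen's
#' kappa and the informational agreement on each 2 x 2 result, and records
#' which threshold maximises each index. Thresholds where an index is
#' undefined (a collapsed class left empty for one rater) are reported as
#' \code{NA} and excluded from the argmax. Ties are broken toward the
#' smallest threshold, the more conservative split.
#'
#' @param table a contingency table with q >= 3 ordered categories.
#' @return an object of class \code{"threshold_scan"}: a list with
#'   \code{entries} (data frame with columns \code{threshold}, \code{kappa},
#'   \code{ia}), \code{best_kappa_t} and \code{best_ia_t}.
#' @examples
#' ct <- contingency_table(diag(c(5, 4, 3, 2, 1)))
#' threshold_scan(ct)
#' @export
threshold_scan <- function(table) {
  table <- .ct(table)
  q <- nrow(table)
  if (q < 3) {
    stop("threshold scanning needs q >= 3 categories")
  }
  thresholds <- seq_len(q - 1)
  kappa <- ia <- rep(NA_real_, length(thresholds))
  for (t in thresholds) {
    collapsed <- collapse_table(table, t)
    kappa[t] <- suppressWarnings(cohen_kappa(collapsed))
    ia[t] <- suppressWarnings(informational_agreement(collapsed))
  }
  argmax <- function(v) {
    if (all(is.na(v))) NA_integer_ else thresholds[which.max(v)]
  }
  structure(
    list(
      entries = data.frame(threshold = thresholds, kappa = kappa, ia = ia),
      best_kappa_t = argmax(kappa),
      best_ia_t = argmax(ia)
    ),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, digits = 3, ...) {
  cat("Dichotomisation threshold scan\n")
  df <- x$entries
  df$kappa <- round(df$kappa, digits)
  df$ia <- round(df$ia, digits)
  print(df, row.names = FALSE)
  cat("best threshold: kappa at t =", x$best_kappa_t,
      "| IA at t =", x$best_ia_t, "\n")
  invisible(x)
}
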