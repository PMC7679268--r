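#' Bundled example agreement tables
#'
#' A small library of published agreement matrices used throughout the
#' package's examples and tests:
#' \describe{
#'   \item{Scenario1 .. Scenario6}{six dichotomous scenarios chosen to
#'     exhibit the classical paradoxes of Cohen's kappa -- near-identical
#'     kappa for visibly different agreement patterns, and the symmetrically
#'     and asymmetrically unbalanced-marginal cases.}
#'   \item{ABVS_US_5x5}{186 breast MRI findings scored on the 5-grade
#'     BI-RADS malignancy scale by automated breast volume scanner (rows)
#'     and hand-held ultrasound (columns).}
#'   \item{ABVS_US_2x2}{the same data dichotomised at BI-RADS 1-2 versus
#'     3-4-5.}
#'   \item{KB_5a, FS_5b}{classifier-agreement matrices from the
#'     Tic-Tac-Toe endgame benchmark: kNN vs naive Bayes, and random forest
#'     vs stochastic gradient descent, each tallying correctly (C) and
#'     wrongly (W) classified entries.}
#' }
#'
#' Every fixture is self-validated on load: its Cohen's kappa is recomputed
#' and compared with the published value (3 decimals for the rating tables,
#' 2 for the classifier matrices), so a transcription error in the stored
#' counts cannot ship silently.
#'
#' @return a named list of \code{contingency_table} objects.
#' @examples
#' fx <- agreement_fixtures()
#' cohen_kappa(fx$Scenario5)
#' @export
agreement_fixtures <- function() {
  tables <- list(
    Scenario1 = contingency_table(matrix(c(3600, 65, 2595, 3740), 2)),
    Scenario2 = contingency_table(matrix(c(9901, 2, 64, 33), 2)),
    Scenario3 = contingency_table(matrix(c(9900, 1, 86, 13), 2)),
    Scenario4 = contingency_table(matrix(c(21, 3, 5, 21), 2)),
    Scenario5 = contingency_table(matrix(c(40, 3, 5, 2), 2)),
    Scenario6 = contingency_table(matrix(c(40, 3, 2, 5), 2)),
    ABVS_US_5x5 = contingency_table(
      matrix(c(
        51, 4, 0, 1, 1,
        3, 78, 1, 0, 0,
        0, 0, 13, 4, 0,
        0, 1, 1, 16, 7,
        0, 0, 0, 0, 5
      ), nrow = 5, byrow = TRUE),
      labels = paste0("BR", 1:5)
    ),
    ABVS_US_2x2 = contingency_table(
      matrix(c(136, 1, 3, 46), 2),
      labels = c("BR1-2", "BR3-4-5")
    ),
    KB_5a = contingency_table(matrix(c(547, 120, 134, 157), 2),
                              labels = c("C", "W")),
    FS_5b = contingency_table(matrix(c(903, 39, 6, 10), 2),
                              labels = c("C", "W"))
  )

  published_kappa <- c(
    Scenario1 = 0.500, Scenario2 = 0.497, Scenario3 = 0.228,
    Scenario4 = 0.681, Scenario5 = 0.245, Scenario6 = 0.608,
    ABVS_US_5x5 = 0.821, ABVS_US_2x2 = 0.944
  )
  for (name in names(published_kappa)) {
    got <- round_half_up(cohen_kappa(tables[[name]]), 3)
    if (got != published_kappa[[name]]) {
      stop("fixture ", name, " fails self-validation: recomputed kappa ",
           got, " != published ", published_kappa[[name]])
    }
  }
  published_kappa_2dp <- c(KB_5a = 0.36, FS_5b = 0.29)
  for (name in names(published_kappa_2dp)) {
    got <- round_half_up(cohen_kappa(tables[[name]]), 2)
    if (got != published_kappa_2dp[[name]]) {
      stop("fixture ", name, " fails self-validation: recomputed kappa ",
           got, " != published ", published_kappa_2dp[[name]])
    }
  }
  tables
}

#' Round half away from zero
#'
#' Decimal rounding as printed in most published tables: .5 always rounds
#' away from zero, unlike R's banker's rounding in \code{round}.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return \code{x} rounded to \code{digits} places.
#' @examples
#' round_half_up(0.0725, 3)   # 0.073
#' round(0.5, 0); round_half_up(0.5, 0)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
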