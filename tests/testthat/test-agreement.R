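test_that("observed and expected agreement match the printed diagonals", {
  s <- scenario_tables()
  expect_equal(observed_agreement(s$Scenario4), 0.84)
  expect_equal(observed_agreement(s$Scenario2), 0.9934)
  expect_equal(observed_agreement(contingency_table(diag(c(3, 4)))), 1)

  expect_equal(expected_agreement(matrix(1, 2, 2)), 0.5)
  expect_equal(expected_agreement(s$Scenario5), 0.9 * 0.86 + 0.1 * 0.14)
  expect_equal(expected_agreement(s$Scenario4), 0.52 * 0.48 + 0.48 * 0.52)
})

test_that("kappa reproduces published values and handles degeneracy", {
  s <- scenario_tables()
  expect_equal(round_half_up(cohen_kappa(s$Scenario5), 3), 0.245)
  expect_equal(round_half_up(cohen_kappa(s$Scenario3), 3), 0.228)
  expect_equal(cohen_kappa(contingency_table(diag(c(25, 25)))), 1)
  # both raters constant on the same category: p_e = 1
  expect_warning(k <- cohen_kappa(matrix(c(50, 0, 0, 0), 2)), "undefined")
  expect_true(is.na(k))
})

test_that("IA reproduces published values and flags degenerate raters", {
  s <- scenario_tables()
  expect_equal(round_half_up(informational_agreement(s$Scenario5), 3), 0.073)
  expect_equal(round_half_up(informational_agreement(s$Scenario2), 3), 0.651)
  expect_equal(informational_agreement(contingency_table(diag(c(10, 40)))), 1)
  expect_warning(ia <- informational_agreement(matrix(c(30, 20, 0, 0), 2)),
                 "undefined")
  expect_true(is.na(ia))
})

test_that("kappa bands partition [-1, 1] as the conventional scale", {
  expect_identical(interpret_kappa(0.681), "substantial")
  expect_identical(interpret_kappa(0.245), "fair")
  expect_identical(interpret_kappa(0), "none-to-slight")
  expect_identical(interpret_kappa(1), "almost-perfect")
  expect_identical(interpret_kappa(0.4), "moderate")   # band edges half-open
  expect_identical(as.character(interpret_kappa(-0.3)), "none-to-slight")
  expect_true(attr(interpret_kappa(-0.3), "below_chance"))
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")
})

test_that("agreement report is internally consistent", {
  s <- scenario_tables()
  r1 <- agreement_report(s$Scenario1)
  expect_equal(r1$p_o, 0.734)
  expect_equal(round_half_up(r1$kappa, 3), 0.500)
  expect_equal(round_half_up(r1$ia, 3), 0.309)

  r3 <- agreement_report(agreement_fixtures()$ABVS_US_2x2)
  expect_equal(round_half_up(r3$kappa, 3), 0.944)
  expect_equal(round_half_up(r3$ia, 3), 0.836)
  expect_identical(r3$kappa_band, "almost-perfect")

  # report invariants: IA * min entropy = MI, bound, chain rule
  set.seed(3)
  for (i in 1:50) {
    r <- agreement_report(random_table())
    expect_lte(r$MI, min(r$H_row, r$H_col) + 1e-12)
    if (r$ia_defined) {
      expect_equal(r$ia * min(r$H_row, r$H_col), r$MI, tolerance = 1e-10)
    }
    if (r$kappa_defined) expect_identical(r$kappa_band,
                                          as.character(interpret_kappa(r$kappa)))
  }

  # degenerate rater: report produced with flags, not an error
  r0 <- agreement_report(matrix(c(50, 0, 0, 0), 2))
  expect_false(r0$ia_defined)
  expect_true(is.na(r0$ia))
})

test_that("kappa and IA ranges and symmetries hold on random tables", {
  set.seed(19)
  for (i in 1:1000) {
    ct <- random_table()
    k <- suppressWarnings(cohen_kappa(ct))
    ia <- suppressWarnings(informational_agreement(ct))
    if (!is.na(k)) {
      expect_gte(k, -1)
      expect_lte(k, 1)
      expect_equal(suppressWarnings(cohen_kappa(t(ct))), k)
    }
    if (!is.na(ia)) {
      expect_gte(ia, 0)
      expect_lte(ia, 1)
      expect_equal(suppressWarnings(informational_agreement(t(ct))), ia)
    }
  }
})

test_that("independent raters give zero kappa and zero IA", {
  set.seed(23)
  for (i in 1:20) {
    q <- sample(2:4, 1)
    rows <- sample(1:9, q, replace = TRUE)
    cols <- sample(1:9, q, replace = TRUE)
    ct <- contingency_table(outer(rows, cols))
    expect_equal(cohen_kappa(ct), 0, tolerance = 1e-10)
    expect_equal(informational_agreement(ct), 0, tolerance = 1e-10)
  }
})

test_that("simultaneous relabeling preserves both indexes; one-sided only IA", {
  set.seed(29)
  for (i in 1:20) {
    ct <- random_table(q = 4)
    perm <- sample(4)
    both <- contingency_table(unclass(ct)[perm, perm])
    expect_equal(suppressWarnings(cohen_kappa(both)),
                 suppressWarnings(cohen_kappa(ct)), tolerance = 1e-12)
    expect_equal(suppressWarnings(informational_agreement(both)),
                 suppressWarnings(informational_agreement(ct)),
                 tolerance = 1e-12)
    rows_only <- contingency_table(unclass(ct)[perm, ])
    expect_equal(suppressWarnings(informational_agreement(rows_only)),
                 suppressWarnings(informational_agreement(ct)),
                 tolerance = 1e-12)
  }
  # a row-only permutation moves diagonal mass, so kappa generally changes
  s5 <- scenario_tables()$Scenario5
  flipped <- contingency_table(unclass(s5)[2:1, ])
  expect_false(isTRUE(all.equal(cohen_kappa(flipped), cohen_kappa(s5))))
  expect_equal(informational_agreement(flipped),
               informational_agreement(s5), tolerance = 1e-12)
})
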