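test_that("transition matrix normalises columns of counts", {
  expect_equal(unclass(transition_matrix(contingency_table(diag(c(5, 9))))),
               diag(2))
  s5 <- contingency_table(matrix(c(40, 3, 5, 2), 2))
  g <- transition_matrix(s5)
  expect_equal(unclass(g), matrix(c(40 / 43, 3 / 43, 5 / 7, 2 / 7), 2),
               tolerance = 1e-12)
  expect_equal(unname(colSums(g)), c(1, 1))
  # an empty conditioning category is named in the error
  expect_error(transition_matrix(matrix(c(3, 4, 0, 0), 2)),
               "category 2")
  # transpose flag conditions on the row rater instead
  gt <- transition_matrix(s5, transpose = TRUE)
  expect_equal(unclass(gt), matrix(c(40 / 45, 5 / 45, 3 / 5, 2 / 5), 2),
               tolerance = 1e-12)
})

test_that("channel-decomposed MI equals MI of the induced joint", {
  # noiseless channel at uniform input saturates at 1 (base q)
  expect_equal(mi_from_channel(c(0.5, 0.5), diag(2)), 1)
  # constant channel transmits nothing
  g_const <- matrix(c(0.7, 0.3, 0.7, 0.3), 2)
  expect_equal(mi_from_channel(c(0.2, 0.8), g_const), 0)
  # frozen cross-check on the unbalanced 2x2 (X = column rater)
  s5 <- contingency_table(matrix(c(40, 3, 5, 2), 2))
  expect_equal(mi_from_channel(c(0.86, 0.14), transition_matrix(s5), base = 2),
               0.03421125089930774, tolerance = 1e-10)

  set.seed(13)
  for (i in 1:1000) {
    q <- sample(2:4, 1)
    p_x <- random_pv(q)
    g <- random_gamma(q)
    joint <- joint_distribution(t(sweep(g, 2, p_x, "*")))
    expect_equal(mi_from_channel(p_x, g, base = q),
                 mutual_information(joint, base = q), tolerance = 1e-10)
  }
})

test_that("IA from the channel matches the table route and enables sweeps", {
  expect_equal(ia_from_channel(c(0.3, 0.7), diag(2)), 1)
  expect_equal(ia_from_channel(c(0.2, 0.8), matrix(c(0.7, 0.3, 0.7, 0.3), 2)), 0)
  s5 <- contingency_table(matrix(c(40, 3, 5, 2), 2))
  expect_equal(round_half_up(ia_from_channel(c(0.86, 0.14),
                                             transition_matrix(s5)), 3),
               0.073)
  # degenerate input distribution: undefined with a warning
  expect_warning(ia <- ia_from_channel(c(1, 0), diag(2)), "undefined")
  expect_true(is.na(ia))
})

test_that("prevalence sweep moves IA but the channel is recoverable exactly", {
  set.seed(17)
  g <- random_gamma(2)
  ias <- sapply(seq(0.1, 0.9, by = 0.2),
                function(p) ia_from_channel(c(p, 1 - p), g))
  expect_gt(max(ias) - min(ias), 0)   # prevalence affects the index...
  for (p in c(0.2, 0.5, 0.9)) {
    p_x <- c(p, 1 - p)
    joint <- t(sweep(g, 2, p_x, "*"))
    recovered <- sweep(t(joint), 2, colSums(t(joint)), "/")
    expect_equal(recovered, g, tolerance = 1e-12)  # ...but never the channel
  }
})

test_that("sensitivity and specificity read the binary channel diagonal", {
  expect_equal(sensitivity_specificity(diag(2)),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sensitivity_specificity(matrix(0.5, 2, 2)),
               c(sensitivity = 0.5, specificity = 0.5))
  s5 <- contingency_table(matrix(c(40, 3, 5, 2), 2))
  expect_equal(sensitivity_specificity(transition_matrix(s5)),
               c(sensitivity = 40 / 43, specificity = 2 / 7),
               tolerance = 1e-12)
  expect_error(sensitivity_specificity(diag(3)), "q = 2")
})

test_that("simulation is seeded, deterministic and recovers the channel", {
  g <- matrix(c(0.93, 0.07, 0.71, 0.29), 2)
  p_x <- c(0.9, 0.1)

  # noiseless channel gives a strictly diagonal table
  diag_tab <- simulate_ratings(c(0.4, 0.6), diag(2), n = 200, seed = 5)
  expect_equal(sum(diag(unclass(diag_tab))), 200L)

  # determinism: same seed, same table; caller RNG state untouched
  set.seed(99); before <- .Random.seed
  t1 <- simulate_ratings(p_x, g, n = 500, seed = 42)
  expect_identical(.Random.seed, before)
  t2 <- simulate_ratings(p_x, g, n = 500, seed = 42)
  expect_identical(unclass(t1), unclass(t2))
  expect_equal(sum(t1), 500L)

  # root-n recovery of the channel from one large simulation
  big <- simulate_ratings(p_x, g, n = 50000, seed = 271)
  expect_lt(max(abs(unclass(transition_matrix(big)) - g)), 0.02)

  # sampling-error bound holds for the vast majority of seeds
  hits <- sapply(1:200, function(s) {
    est <- transition_matrix(simulate_ratings(p_x, g, n = 50000, seed = s))
    max(abs(unclass(est) - g)) < 0.02
  })
  expect_gte(mean(hits), 0.95)
})
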