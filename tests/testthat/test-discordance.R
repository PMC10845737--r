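test_that("discordance labels follow the strict cutoffs", {
  expect_equal(label_discordance(0.29, 5L), "false_negative")
  expect_equal(label_discordance(0.71, 1L), "false_positive")
  # exactly at a cutoff is concordant (strict inequalities)
  expect_equal(label_discordance(0.30, 5L), "concordant")
  expect_equal(label_discordance(0.70, 1L), "concordant")
  # only the extreme pathologist scores can be discordant
  expect_equal(label_discordance(0.05, 4L), "concordant")
  expect_equal(label_discordance(0.95, 2L), "concordant")
})

test_that("no image set can be both false positive and false negative", {
  set.seed(31)
  lab <- label_discordance(runif(5000), sample(1:5, 5000, TRUE))
  expect_true(all(lab %in% c("false_positive", "false_negative", "concordant")))
  fn_possible <- sum(lab == "false_negative")
  # bounds: FN only among pathologist-5 sets, FP only among pathologist-1
  ps <- sample(1:5, 5000, TRUE); dsa <- runif(5000)
  lab <- label_discordance(dsa, ps)
  expect_lte(sum(lab == "false_negative"), sum(ps == 5))
  expect_lte(sum(lab == "false_positive"), sum(ps == 1))
})

test_that("tabulated rates are additive and conserved", {
  set.seed(32)
  sets <- data.frame(
    case_id = rep(sprintf("c%03d", 1:60), each = 10),
    cohort = rep(c("lab1", "lab2"), each = 300),
    set_index = rep(1:10, 60),
    dsa_score = runif(600), pathologist_score = sample(1:5, 600, TRUE)
  )
  tab <- tabulate_discordance(sets, by = "cohort")
  r <- tab$rates
  expect_equal(r$fp_rate + r$fn_rate, r$total_error_rate)
  expect_true(all(r$n_fp + r$n_fn <= r$n_sets))
  expect_equal(sum(r$n_sets), 600)
  # cause table covers the full taxonomy for every stratum and error type
  expect_equal(nrow(tab$causes), 2 * 2 * 4)
})

test_that("cause percentages are relative to the error-type total", {
  sets <- data.frame(
    case_id = "c1", cohort = "lab", set_index = 1:4,
    dsa_score = c(0.1, 0.1, 0.9, 0.5),
    pathologist_score = c(5L, 5L, 1L, 3L),
    causes = c("technical", "technical;missing_sens_spec", "unknown", NA)
  )
  tab <- tabulate_discordance(sets, by = "cohort")
  cc <- tab$causes
  tech_fn <- cc[cc$error_type == "false_negative" & cc$cause == "technical", ]
  expect_equal(tech_fn$n, 2)
  expect_equal(tech_fn$pct_of_type, 100)  # 2 of 2 false negatives
  miss_fn <- cc[cc$error_type == "false_negative" &
                  cc$cause == "missing_sens_spec", ]
  expect_equal(miss_fn$pct_of_type, 50)   # multi-cause set counted once each
  unk_fp <- cc[cc$error_type == "false_positive" & cc$cause == "unknown", ]
  expect_equal(unk_fp$pct_of_type, 100)
})

test_that("stratum-free sets are dropped with a warning", {
  sets <- data.frame(case_id = c("c1", "c2"), cohort = c("lab", NA),
                     set_index = 1L, dsa_score = 0.5,
                     pathologist_score = 3L)
  expect_warning(tab <- tabulate_discordance(sets, by = "cohort"),
                 "missing stratum")
  expect_equal(tab$rates$n_sets, 1)
})

test_that("chi-square statistic matches hand-computed expected counts", {
  # independent oracle: expected counts and statistic computed by hand
  tab <- matrix(c(20, 40, 80, 60), 2, 2)
  ht <- chi_square_independence(tab)
  e <- outer(c(100, 100), c(60, 140)) / 200
  expect_equal(unname(ht$statistic), sum((tab - e)^2 / e))
  expect_equal(unname(ht$statistic), 9.523809523809524, tolerance = 1e-12)
  expect_equal(unname(ht$parameter), 1)

  # identical proportions give a zero statistic and p = 1
  flat <- chi_square_independence(matrix(10, 2, 2))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p.value, 1)

  # df formula for a 2x3 table
  expect_equal(unname(chi_square_independence(
    matrix(c(5, 3, 8, 2, 4, 9), 2, 3))$parameter), 2)
})

test_that("chi-square agrees with stats::chisq.test and integration", {
  set.seed(41)
  for (rep in 1:20) {
    tab <- matrix(sample(1:60, 4), 2, 2)
    ours <- chi_square_independence(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(unname(ours$statistic), unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value)
    yat <- chi_square_independence(tab, yates = TRUE)
    ref_y <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(unname(yat$statistic), unname(ref_y$statistic))
  }
  # p-value against direct numerical integration of the chi-square density
  ht <- chi_square_independence(matrix(c(20, 40, 80, 60), 2, 2))
  dens <- function(x, k) x^(k / 2 - 1) * exp(-x / 2) / (2^(k / 2) * gamma(k / 2))
  p_int <- stats::integrate(dens, unname(ht$statistic), Inf, k = 1,
                            rel.tol = 1e-12)$value
  expect_equal(ht$p.value, p_int, tolerance = 1e-10)
})

test_that("chi-square invariances: permutation, count scaling, monotone p", {
  set.seed(42)
  tab <- matrix(sample(5:50, 6), 2, 3)
  base <- chi_square_independence(tab)
  perm <- chi_square_independence(tab[2:1, c(3, 1, 2)])
  expect_equal(unname(perm$statistic), unname(base$statistic))

  scaled <- chi_square_independence(tab * 4)
  expect_equal(unname(scaled$statistic), 4 * unname(base$statistic))

  # p decreases as the statistic grows at fixed df
  stats_grid <- c(0.5, 1, 2, 5, 10)
  ps <- pchisq(stats_grid, df = 2, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("degenerate and invalid contingency tables are rejected", {
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2, 2)),
               "marginal")
  expect_error(chi_square_independence(matrix(c(1, -1, 2, 3), 2, 2)),
               "non-negative")
  expect_error(chi_square_independence(matrix(c(1.5, 1, 2, 3), 2, 2)),
               "integer")
  expect_error(chi_square_independence(matrix(1:3, 1, 3)), "2x2")
})

test_that("pairwise error-profile comparison builds the right tables", {
  counts <- study_counts()$center_errors
  sets <- reconstruct_discordant_sets(counts)
  tab <- tabulate_discordance(sets, by = "cohort")
  cmp <- compare_error_profiles(tab)
  expect_equal(nrow(cmp), choose(4, 2))
  expect_true(all(cmp$df == 1))
  expect_true(all(cmp$p > 0 & cmp$p <= 1))
  bonf <- compare_error_profiles(tab, p_adjust = "bonferroni")
  expect_true(all(bonf$p >= cmp$p))
})
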