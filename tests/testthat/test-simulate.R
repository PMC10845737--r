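test_that("generator parameters are validated", {
  expect_error(score_gen_params(prevalence_hscr = 1.2), "\\[0, 1\\]")
  expect_error(score_gen_params(sets_per_case = 13), "1\\.\\.12")
  expect_error(score_gen_params(dsa_true_dist = c(-1, 2)), "positive")
  expect_error(score_gen_params(
    pathologist_confusion = matrix(1, 5, 2)), "stochastic")
})

test_that("score cohorts are reproducible and respect the content model", {
  p <- score_gen_params(n_cases = 40)
  a <- generate_cohort(p, seed = 123)
  b <- generate_cohort(p, seed = 123)
  expect_identical(a, b)
  c2 <- generate_cohort(p, seed = 124)
  expect_false(identical(a$sets$dsa_score, c2$sets$dsa_score))

  joined <- merge(a$sets, a$cases[, c("case_id", "ground_truth")],
                  by = "case_id")
  # disease cases contain no true-ganglion sets; others at least one
  expect_false(any(joined$true_content[
    joined$ground_truth == "ganglion_absent"]))
  per_case <- tapply(joined$true_content,
                     joined$case_id[drop = TRUE], any)
  present <- unique(joined$case_id[joined$ground_truth == "ganglion_present"])
  expect_true(all(per_case[present]))

  expect_true(all(a$sets$dsa_score >= 0 & a$sets$dsa_score <= 1))
  expect_true(all(a$sets$pathologist_score %in% 1:5))
  # annotations attached consistently
  expect_true(all(a$sets$causes[a$sets$artifact] == "technical"))
  expect_true(all(a$sets$causes[a$sets$mimic] == "missing_sens_spec"))
})

test_that("a noiseless, perfectly separated cohort is classified perfectly", {
  perfect <- matrix(c(0, 0, 0, 0, 1,
                      1, 0, 0, 0, 0), 5, 2)
  p <- score_gen_params(n_cases = 50, artifact_prob = 0, mimic_prob = 0,
                        dsa_true_dist = c(400, 1), dsa_false_dist = c(1, 400),
                        pathologist_confusion = perfect)
  coh <- generate_cohort(p, seed = 77)
  s <- summarize_cohort(coh$cases, coh$sets)
  expect_equal(s$n_correct, 50)
  expect_equal(s$n_referrals, 0)
  expect_equal(s$sensitivity_positive_cases_pre_referral, 100)
})

test_that("raising the artifact probability raises the false-negative rate", {
  p_hi <- score_gen_params(n_cases = 500, artifact_prob = 0.3, mimic_prob = 0)
  p_lo <- score_gen_params(n_cases = 500, artifact_prob = 0.0, mimic_prob = 0)
  hi <- generate_cohort(p_hi, seed = 2024)
  lo <- generate_cohort(p_lo, seed = 2024)
  fn_rate <- function(coh) {
    mean(label_discordance(coh$sets$dsa_score,
                           coh$sets$pathologist_score) == "false_negative")
  }
  expect_gt(fn_rate(hi), fn_rate(lo))
})

test_that("tiles are bit-identical under a fixed seed", {
  a <- generate_tile(64, 64, "ganglion", seed = 5)
  b <- generate_tile(64, 64, "ganglion", seed = 5)
  expect_identical(a, b)
  d <- generate_tile(64, 64, "ganglion", seed = 6)
  expect_false(identical(a, d))
  expect_equal(dim(a), c(64, 64, 3))
  expect_true(all(a >= 0 & a <= 255 & a == round(a)))
})

test_that("a neutral scanner and identity stain pass content through", {
  neutral <- scanner_profile(blur_sigma = 0, gamma = 1,
                             color_spread_sigma = 0)
  shifted <- stain_profile(gain = c(1.1, 1, 0.9), offset = c(5, 0, -5))
  base <- generate_tile(48, 48, "background_stroma",
                        scanner = neutral, seed = 13)
  again <- generate_tile(48, 48, "background_stroma",
                         scanner = neutral, seed = 13)
  expect_identical(base, again)
  # a non-identity stain changes the rendering of the same content/seed
  stained <- generate_tile(48, 48, "background_stroma", stain = shifted,
                           scanner = neutral, seed = 13)
  expect_false(identical(base, stained))
  expect_error(generate_tile(16, 16, "ganglion"), "at least 32")
})

test_that("wider colour spread lowers peaks and widens support", {
  narrow <- scanner_profile(color_spread_sigma = 0)
  wide <- scanner_profile(color_spread_sigma = 8)
  for (seed in c(3, 14)) {
    s_narrow <- spread_summary(compute_histogram(
      generate_tile(64, 64, "ganglion", scanner = narrow, seed = seed)))
    s_wide <- spread_summary(compute_histogram(
      generate_tile(64, 64, "ganglion", scanner = wide, seed = seed)))
    expect_true(all(s_wide$peak_height < s_narrow$peak_height))
    expect_true(all(s_wide$occupied_bins > s_narrow$occupied_bins))
  }
})

test_that("tile sets are written with a usable manifest", {
  dir <- withr::local_tempdir()
  man <- generate_tile_set(dir, n_per_profile = 2, width = 48, height = 48,
                           seed = 5)
  expect_equal(nrow(man), 6)
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
})
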