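#' Parameters for the synthetic score-cohort generator
#'
#' Defines the generative model standing in for the upstream ganglion-cell
#' detector and the reviewing pathologist. Per case, a Hirschsprung status
#' is drawn (`prevalence_hscr`); ganglion-absent cases contain only
#' non-ganglion image sets, ganglion-present cases contain at least one
#' true-ganglion set. Per set:
#'
#' * the DSA score is drawn from `dsa_true_dist` (Beta) for true-ganglion
#'   content and `dsa_false_dist` otherwise;
#' * with probability `artifact_prob`, a true-ganglion set carries a
#'   technical artifact (staining irregularity, focus, ...):
#'   `artifact_dsa_penalty` is subtracted from its DSA score (clipped to
#'   \[0, 1\]) and the set is annotated `technical`. The pathologist score
#'   is unaffected -- technical changes degrade the algorithm, not the
#'   human reader;
#' * with probability `mimic_prob`, a non-ganglion set is a high-scoring
#'   mimic: its DSA score is drawn from `dsa_true_dist` instead and the
#'   set is annotated `missing_sens_spec`;
#' * the pathologist score is drawn from `pathologist_confusion`, a 5 x 2
#'   matrix of probabilities of scores 1..5 given true content (columns
#'   `ganglion`, `non_ganglion`).
#'
#' Defaults mirror the study shape: 186 cases, 62 of them Hirschsprung
#' (prevalence 1/3), 12 image sets per case, well-separated Beta score
#' families and a near-expert pathologist, with moderate artifact and
#' mimic probabilities. High `artifact_prob` with zero `mimic_prob`
#' reproduces the false-negative-dominant external-laboratory regime; the
#' reverse reproduces the false-positive-dominant home-laboratory regime.
#'
#' @param n_cases Number of cases (default 186).
#' @param prevalence_hscr Probability a case is ganglion-absent
#'   (default 62/186).
#' @param sets_per_case Number of image sets per case, 1..12 (default 12).
#' @param dsa_true_dist,dsa_false_dist Length-2 Beta shape vectors for DSA
#'   scores of true-ganglion / non-ganglion content.
#' @param artifact_prob Probability a true-ganglion set carries a technical
#'   artifact (default 0.08).
#' @param artifact_dsa_penalty Amount subtracted from the DSA score under
#'   artifact, clipped to \[0, 1\] (default 0.45).
#' @param mimic_prob Probability a non-ganglion set is a high-scoring mimic
#'   (default 0.04).
#' @param pathologist_confusion 5 x 2 column-stochastic matrix,
#'   `P(score | content)`.
#' @param p_ganglion_set Probability each set of a ganglion-present case
#'   contains true ganglion content (at least one is enforced; default 0.6).
#' @return A validated list of class `score_gen_params`.
#' @export
score_gen_params <- function(n_cases = 186L,
                             prevalence_hscr = 62 / 186,
                             sets_per_case = 12L,
                             dsa_true_dist = c(8, 2),
                             dsa_false_dist = c(1.5, 6),
                             artifact_prob = 0.08,
                             artifact_dsa_penalty = 0.45,
                             mimic_prob = 0.04,
                             pathologist_confusion = default_pathologist_confusion(),
                             p_ganglion_set = 0.6) {
  probs <- c(prevalence_hscr, artifact_prob, mimic_prob, p_ganglion_set)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_cases < 1) stop("n_cases must be >= 1", call. = FALSE)
  if (sets_per_case < 1 || sets_per_case > 12) {
    stop("sets_per_case must be in 1..12", call. = FALSE)
  }
  for (shp in list(dsa_true_dist, dsa_false_dist)) {
    if (length(shp) != 2 || any(!is.finite(shp)) || any(shp <= 0)) {
      stop("Beta shape parameters must be two positive numbers", call. = FALSE)
    }
  }
  pc <- as.matrix(pathologist_confusion)
  if (!identical(dim(pc), c(5L, 2L)) || any(pc < 0) ||
      any(abs(colSums(pc) - 1) > 1e-8)) {
    stop("pathologist_confusion must be a 5 x 2 column-stochastic matrix",
         call. = FALSE)
  }
  dimnames(pc) <- list(paste0("score_", 1:5), c("ganglion", "non_ganglion"))
  if (artifact_dsa_penalty < 0 || artifact_dsa_penalty > 1) {
    stop("artifact_dsa_penalty must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases), prevalence_hscr = prevalence_hscr,
         sets_per_case = as.integer(sets_per_case),
         dsa_true_dist = dsa_true_dist, dsa_false_dist = dsa_false_dist,
         artifact_prob = artifact_prob,
         artifact_dsa_penalty = artifact_dsa_penalty,
         mimic_prob = mimic_prob, pathologist_confusion = pc,
         p_ganglion_set = p_ganglion_set),
    class = "score_gen_params"
  )
}

#' @rdname score_gen_params
#' @export
default_pathologist_confusion <- function() {
  matrix(
    c(0.005, 0.010, 0.015, 0.070, 0.900,   # true ganglion content
      0.900, 0.070, 0.015, 0.010, 0.005),  # non-ganglion content
    nrow = 5, ncol = 2,
    dimnames = list(paste0("score_", 1:5), c("ganglion", "non_ganglion"))
  )
}

#' Generate a seeded synthetic score cohort
#'
#' Draws a full cohort of cases and image sets under the model described
#' in [score_gen_params()]. Generation is deterministic given `seed`: the
#' root seed fans out to one sub-seed per case (Mersenne-Twister
#' throughout), so the first `k` cases of a run are identical across runs
#' with the same seed and `n_cases >= k`.
#'
#' The expert call attached to every case equals the ground truth (the
#' expert is assumed correct on referral), so referred synthetic cases
#' always resolve correctly.
#'
#' @param params A `score_gen_params` object.
#' @param seed Integer root seed.
#' @param cohort,scanner Labels stamped on the generated records.
#' @return A list with `cases` (case table) and `sets` (score table). The
#'   score table carries bookkeeping columns `true_content` (logical:
#'   ganglion content), `artifact` and `mimic`, which downstream
#'   operations ignore but tests use as ground truth.
#' @export
generate_cohort <- function(params = score_gen_params(), seed = 1L,
                            cohort = "synthetic", scanner = "synthetic") {
  stopifnot(inherits(params, "score_gen_params"))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  case_seeds <- sample.int(.Machine$integer.max - 1L, params$n_cases)
  is_hscr <- runif(params$n_cases) < params$prevalence_hscr

  per_case <- purrr::map2(seq_len(params$n_cases), case_seeds, function(i, s) {
    set.seed(s, kind = "Mersenne-Twister")
    .generate_case(params, case_id = sprintf("%s_case_%04d", cohort, i),
                   hscr = is_hscr[i], cohort = cohort, scanner = scanner)
  })

  cases <- bind_rows(purrr::map(per_case, "case"))
  sets <- bind_rows(purrr::map(per_case, "sets"))
  list(cases = as_case_table(cases), sets = as_score_table(sets))
}

.generate_case <- function(params, case_id, hscr, cohort, scanner) {
  k <- params$sets_per_case
  if (hscr) {
    true_content <- rep(FALSE, k)
  } else {
    true_content <- runif(k) < params$p_ganglion_set
    if (!any(true_content)) true_content[sample.int(k, 1)] <- TRUE
  }
  artifact <- true_content & runif(k) < params$artifact_prob
  mimic <- !true_content & runif(k) < params$mimic_prob

  dsa <- numeric(k)
  n_true <- sum(true_content | mimic)
  dsa[true_content | mimic] <- rbeta(n_true, params$dsa_true_dist[1],
                                     params$dsa_true_dist[2])
  dsa[!(true_content | mimic)] <- rbeta(k - n_true, params$dsa_false_dist[1],
                                        params$dsa_false_dist[2])
  dsa[artifact] <- pmin(pmax(dsa[artifact] - params$artifact_dsa_penalty, 0), 1)

  pc <- params$pathologist_confusion
  pathologist <- vapply(true_content, function(tc) {
    sample.int(5L, 1, prob = pc[, if (tc) "ganglion" else "non_ganglion"])
  }, integer(1))

  causes <- ifelse(artifact, "technical",
            ifelse(mimic, "missing_sens_spec", NA_character_))

  list(
    case = tibble(
      case_id = case_id, cohort = cohort, scanner = scanner,
      ground_truth = if (hscr) "ganglion_absent" else "ganglion_present",
      expert_call = if (hscr) "ganglion_absent" else "ganglion_present"
    ),
    sets = tibble(
      case_id = case_id, cohort = cohort, scanner = scanner,
      set_index = seq_len(k), dsa_score = dsa,
      pathologist_score = pathologist, causes = causes,
      true_content = true_content, artifact = artifact, mimic = mimic
    )
  )
}
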