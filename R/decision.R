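#' Classify a case from its image-set scores
#'
#' Applies the DSS decision criteria combining pathologist and algorithm
#' (DSA) scores over all image sets presented for one case:
#'
#' 1. **positive** (ganglion cells present, non-Hirschsprung) -- the
#'    pathologist gave the certain score (5) to at least
#'    `n_certain_required` image sets;
#' 2. **negative** (ganglion cells absent, Hirschsprung) -- the positive
#'    criterion is not met and the mean DSA score over all of the case's
#'    sets is strictly below `ai_cutoff`;
#' 3. **in_doubt** (expert consultation required) -- the positive criterion
#'    is not met and the mean DSA score is at or above `ai_cutoff`.
#'
#' The boundary is inclusive on the in-doubt side: a mean DSA score of
#' exactly `ai_cutoff` is in doubt, not negative. Pathologist scores of 4
#' never count toward the positive criterion.
#'
#' @param dsa_scores Numeric vector of per-set DSA scores in \[0, 1\].
#' @param pathologist_scores Integer vector of per-set pathologist scores in
#'   1..5, same length as `dsa_scores`.
#' @param ai_cutoff Mean-DSA threshold separating negative from in-doubt
#'   (default 0.6).
#' @param certain_score The pathologist score treated as a certain ganglion
#'   call (default 5).
#' @param n_certain_required Number of certain sets required for a positive
#'   classification (default 2).
#' @return An object of class `dss_classification`: a list with `label`
#'   (one of `"positive"`, `"negative"`, `"in_doubt"`), `mean_dsa` and
#'   `n_certain_sets`.
#' @export
#' @examples
#' classify_case(c(0.1, 0.1), c(5, 5))$label          # "positive"
#' classify_case(c(0.2, 0.3, 0.1), c(1, 2, 1))$label  # "negative"
#' classify_case(c(0.9, 0.3), c(5, 4))$label          # "in_doubt" (mean 0.6)
classify_case <- function(dsa_scores, pathologist_scores,
                          ai_cutoff = 0.6, certain_score = 5L,
                          n_certain_required = 2L) {
  n <- length(dsa_scores)
  if (n == 0L) {
    stop("cannot classify a case with no image sets", call. = FALSE)
  }
  if (length(pathologist_scores) != n) {
    stop("dsa_scores and pathologist_scores must have the same length",
         call. = FALSE)
  }
  if (anyNA(dsa_scores) || any(dsa_scores < 0) || any(dsa_scores > 1)) {
    stop("dsa_score must lie in [0, 1]", call. = FALSE)
  }
  if (anyNA(pathologist_scores) ||
      any(pathologist_scores != as.integer(pathologist_scores)) ||
      any(pathologist_scores < 1) || any(pathologist_scores > 5)) {
    stop("pathologist_score must be an integer in 1..5", call. = FALSE)
  }
  n_certain <- sum(pathologist_scores == certain_score)
  mean_dsa <- mean(dsa_scores)
  label <- if (n_certain >= n_certain_required) {
    "positive"
  } else if (mean_dsa < ai_cutoff) {
    "negative"
  } else {
    "in_doubt"
  }
  structure(
    list(label = label, mean_dsa = mean_dsa, n_certain_sets = n_certain),
    class = "dss_classification"
  )
}

#' @export
print.dss_classification <- function(x, ...) {
  cat(sprintf("DSS classification: %s (mean DSA %.3f, %d certain set%s)\n",
              x$label, x$mean_dsa, x$n_certain_sets,
              if (x$n_certain_sets == 1) "" else "s"))
  invisible(x)
}

#' Classify every case in a score table
#'
#' Vectorised form of [classify_case()]: groups the score table by
#' `case_id` and applies the DSS decision criteria to each case.
#'
#' @param sets A score table (see [as_score_table()]).
#' @inheritParams classify_case
#' @return A tibble with one row per case: `case_id`, `label`, `mean_dsa`,
#'   `n_certain_sets`, `n_sets`.
#' @export
classify_cases <- function(sets, ai_cutoff = 0.6, certain_score = 5L,
                           n_certain_required = 2L) {
  sets <- as_score_table(sets)
  out <- sets %>%
    group_by(.data$case_id) %>%
    summarise(
      mean_dsa = mean(.data$dsa_score),
      n_certain_sets = sum(.data$pathologist_score == certain_score),
      n_sets = n(),
      .groups = "drop"
    ) %>%
    mutate(label = dplyr::case_when(
      .data$n_certain_sets >= n_certain_required ~ "positive",
      .data$mean_dsa < ai_cutoff ~ "negative",
      TRUE ~ "in_doubt"
    )) %>%
    select("case_id", "label", "mean_dsa", "n_certain_sets", "n_sets")
  out
}

#' Resolve the final call for a classified case
#'
#' Positive cases map to `"ganglion_present"`, negative cases to
#' `"ganglion_absent"`. In-doubt cases are referred: the expert's call on
#' the presented image sets becomes the final call and is required. For
#' positive or negative cases any expert call is ignored.
#'
#' @param classification A `dss_classification` (from [classify_case()]) or
#'   a bare label string.
#' @param expert_call Optional expert call, one of `"ganglion_present"` or
#'   `"ganglion_absent"`; required when the label is `"in_doubt"`.
#' @return `"ganglion_present"` or `"ganglion_absent"`.
#' @export
resolve_referral <- function(classification, expert_call = NULL) {
  label <- if (inherits(classification, "dss_classification")) {
    classification$label
  } else {
    as.character(classification)
  }
  if (!label %in% .dss_labels) {
    stop("unknown DSS label: ", label, call. = FALSE)
  }
  switch(label,
    positive = "ganglion_present",
    negative = "ganglion_absent",
    in_doubt = {
      if (is.null(expert_call) || is.na(expert_call)) {
        stop("case is in doubt: an expert call is required to resolve it",
             call. = FALSE)
      }
      if (!expert_call %in% .truth_levels) {
        stop("expert_call must be one of: ",
             paste(.truth_levels, collapse = ", "), call. = FALSE)
      }
      expert_call
    }
  )
}

#' Summarise DSS performance over a cohort of cases
#'
#' Classifies every case, resolves referrals, compares the final call with
#' the ground truth, and tabulates performance, optionally per stratum
#' (e.g. per medical-center cohort or per scanner).
#'
#' Sensitivity is reported among ganglion-present (non-Hirschsprung) cases
#' only, both pre-referral (a case still in doubt counts as not yet
#' correct) and post-referral (after the expert call is substituted).
#'
#' @param cases A case table (see [as_case_table()]).
#' @param sets A score table covering every case in `cases`.
#' @param by Optional name of a column of `cases` to stratify by
#'   (`"cohort"` or `"scanner"`); `NULL` gives a single overall row.
#' @inheritParams classify_case
#' @return A tibble with one row per stratum (column `stratum`, `"all"`
#'   when `by` is `NULL`): `n_cases`, `n_hscr`, `n_non_hscr`, `n_correct`,
#'   `n_incorrect`, `n_referrals`,
#'   `sensitivity_positive_cases_pre_referral` and
#'   `sensitivity_positive_cases_post_referral` (percentages).
#' @export
summarize_cohort <- function(cases, sets, by = NULL, ai_cutoff = 0.6,
                             certain_score = 5L, n_certain_required = 2L) {
  cases <- as_case_table(cases)
  sets <- as_score_table(sets)
  if (nrow(cases) == 0L) stop("empty cohort: no cases to summarise", call. = FALSE)

  orphan_sets <- setdiff(unique(sets$case_id), cases$case_id)
  if (length(orphan_sets)) {
    stop("score table references unknown case id(s): ",
         paste(head(orphan_sets, 5), collapse = ", "), call. = FALSE)
  }
  no_sets <- setdiff(cases$case_id, unique(sets$case_id))
  if (length(no_sets)) {
    stop("case(s) without image sets cannot be classified: ",
         paste(head(no_sets, 5), collapse = ", "), call. = FALSE)
  }

  cls <- classify_cases(sets, ai_cutoff = ai_cutoff,
                        certain_score = certain_score,
                        n_certain_required = n_certain_required)
  df <- left_join(cases, cls, by = "case_id")

  doubt_no_expert <- df$label == "in_doubt" & is.na(df$expert_call)
  if (any(doubt_no_expert)) {
    stop("in-doubt case(s) without an expert call: ",
         paste(head(df$case_id[doubt_no_expert], 5), collapse = ", "),
         call. = FALSE)
  }
  df$final_call <- ifelse(df$label == "positive", "ganglion_present",
                   ifelse(df$label == "negative", "ganglion_absent",
                          df$expert_call))

  if (is.null(by)) {
    df$stratum <- "all"
  } else {
    if (!by %in% names(df)) stop("no such stratification column: ", by, call. = FALSE)
    df$stratum <- as.character(df[[by]])
  }

  df %>%
    group_by(.data$stratum) %>%
    summarise(
      n_cases = n(),
      n_hscr = sum(.data$ground_truth == "ganglion_absent"),
      n_non_hscr = sum(.data$ground_truth == "ganglion_present"),
      n_correct = sum(.data$final_call == .data$ground_truth),
      n_incorrect = sum(.data$final_call != .data$ground_truth),
      n_referrals = sum(.data$label == "in_doubt"),
      sensitivity_positive_cases_pre_referral =
        100 * sum(.data$label == "positive" &
                    .data$ground_truth == "ganglion_present") /
        sum(.data$ground_truth == "ganglion_present"),
      sensitivity_positive_cases_post_referral =
        100 * sum(.data$final_call == "ganglion_present" &
                    .data$ground_truth == "ganglion_present") /
        sum(.data$ground_truth == "ganglion_present"),
      .groups = "drop"
    ) %>%
    arrange(.data$stratum)
}
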