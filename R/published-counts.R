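#' Published multi-center evaluation counts
#'
#' The raw slides and per-set scores of the multi-center evaluation of the
#' Hirschsprung decision support system are not publicly deposited; what
#' is available are the published summary counts. This accessor returns
#' them as tidy tibbles, shipped with the package:
#'
#' * `case_performance` -- per-cohort case counts, disease status, DSS
#'   correctness and referrals;
#' * `center_errors`, `scanner_errors` -- per-stratum image-set totals and
#'   false-positive/false-negative counts with causative-factor
#'   breakdowns;
#' * `positive_cases` -- ganglion-present case counts with referral and
#'   misclassification breakdowns per cohort and scanner subset;
#' * `case_level_distances` -- the two published case-level histogram
#'   distances between scanner brands.
#'
#' Combined with [reconstruct_outcome_cohort()] and
#' [reconstruct_discordant_sets()], these counts let the tabulation
#' operations recompute every published rate from scratch.
#'
#' @return A named list of tibbles.
#' @export
study_counts <- function() {
  ext <- function(f) {
    readr::read_csv(system.file("extdata", f, package = "hscrdss",
                                mustWork = TRUE),
                    show_col_types = FALSE, progress = FALSE)
  }
  list(
    case_performance = ext("published_case_performance.csv"),
    center_errors = ext("published_center_errors.csv"),
    scanner_errors = ext("published_scanner_errors.csv"),
    positive_cases = ext("published_positive_cases.csv"),
    case_level_distances = ext("published_case_distances.csv")
  )
}

#' Reconstruct a ganglion-present cohort from outcome counts
#'
#' Expands outcome counts -- `n_cases` ganglion-present cases of which
#' `n_referred` were left in doubt by the DSS (and resolved correctly by
#' the expert) and `n_misclassified` were classified negative -- into
#' minimal case and score tables whose classification reproduces exactly
#' those outcomes. Directly-correct cases get two certain (score 5) sets;
#' referred cases get one certain set with a high mean DSA score;
#' misclassified cases get low pathologist and DSA scores. Running
#' [summarize_cohort()] on the result recomputes the pre- and
#' post-referral sensitivities implied by the counts.
#'
#' @param n_cases Total ganglion-present cases.
#' @param n_referred Cases referred to the expert (resolved correctly).
#' @param n_misclassified Cases classified negative by the DSS.
#' @param stratum Label stamped on the `cohort` and `scanner` columns.
#' @return A list with `cases` and `sets` tables.
#' @export
#' @examples
#' rc <- reconstruct_outcome_cohort(125, n_referred = 4, n_misclassified = 1)
#' summarize_cohort(rc$cases, rc$sets)
reconstruct_outcome_cohort <- function(n_cases, n_referred = 0,
                                       n_misclassified = 0,
                                       stratum = "cohort") {
  if (n_referred + n_misclassified > n_cases) {
    stop("n_referred + n_misclassified cannot exceed n_cases", call. = FALSE)
  }
  outcome <- c(rep("direct", n_cases - n_referred - n_misclassified),
               rep("referred", n_referred),
               rep("missed", n_misclassified))
  ids <- sprintf("%s_case_%04d", gsub("\\s+", "_", tolower(stratum)),
                 seq_len(n_cases))
  cases <- tibble(
    case_id = ids, cohort = stratum, scanner = stratum,
    ground_truth = "ganglion_present",
    expert_call = ifelse(outcome == "referred", "ganglion_present",
                         NA_character_)
  )
  sets <- purrr::map2_dfr(ids, outcome, function(id, oc) {
    scores <- switch(oc,
      direct   = list(ps = c(5L, 5L), dsa = c(0.9, 0.9)),  # positive
      referred = list(ps = c(5L, 4L), dsa = c(0.9, 0.8)),  # in doubt
      missed   = list(ps = c(2L, 2L), dsa = c(0.2, 0.2))   # negative
    )
    tibble(case_id = id, cohort = stratum, scanner = stratum,
           set_index = seq_along(scores$ps), dsa_score = scores$dsa,
           pathologist_score = scores$ps)
  })
  list(cases = as_case_table(cases), sets = as_score_table(sets))
}

#' Reconstruct per-set records from published discordance counts
#'
#' Expands a tibble of per-stratum error counts (the shape returned by
#' [study_counts()]`$center_errors` / `$scanner_errors`: columns
#' `stratum`, `n_sets`, `error_type`, `n` and one column per causative
#' factor) into a score table with one row per image set: `n` discordant
#' sets of each error type (pathologist 5 / DSA 0.1 for false negatives,
#' pathologist 1 / DSA 0.9 for false positives) carrying the published
#' cause annotations, padded with concordant sets (pathologist 3, DSA
#' 0.5) up to `n_sets`. Running [tabulate_discordance()] on the result
#' recomputes the published rates and cause percentages from scratch.
#'
#' @param counts A tibble in the shape described above.
#' @return A score table with a `cohort` column holding the stratum.
#' @export
reconstruct_discordant_sets <- function(counts) {
  needed <- c("stratum", "n_sets", "error_type", "n", .cause_levels)
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols)) {
    stop("counts table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- purrr::map_dfr(unique(counts$stratum), function(s) {
    sub <- counts[counts$stratum == s, ]
    n_sets <- sub$n_sets[1]
    rows <- purrr::pmap_dfr(sub, function(stratum, n_sets, error_type, n, ...) {
      cause_counts <- c(...)[.cause_levels]
      causes <- rep(names(cause_counts), times = cause_counts)
      # pad in case annotated causes do not cover every error
      causes <- c(causes, rep(NA_character_, max(0, n - length(causes))))[seq_len(n)]
      if (n == 0) return(tibble())
      tibble(
        dsa_score = if (error_type == "false_negative") 0.1 else 0.9,
        pathologist_score = if (error_type == "false_negative") 5L else 1L,
        causes = causes
      )
    })
    n_disc <- nrow(rows)
    if (n_disc > n_sets) stop("more errors than sets in stratum ", s, call. = FALSE)
    conc <- tibble(dsa_score = rep(0.5, n_sets - n_disc),
                   pathologist_score = 3L, causes = NA_character_)
    all_rows <- bind_rows(rows, conc)
    # spread sets across pseudo-cases of at most 12 sets each
    all_rows$case_id <- sprintf("%s_case_%04d", gsub("\\s+", "_", tolower(s)),
                                (seq_len(n_sets) - 1L) %/% 12L + 1L)
    all_rows$set_index <- (seq_len(n_sets) - 1L) %% 12L + 1L
    all_rows$cohort <- s
    all_rows
  })
  as_score_table(out)
}
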