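#' Format a rate for display
#'
#' Display rounding mirrors the mixed precision of the published tables:
#' rates below 1% are shown with two decimals, others with one. Stored
#' values always keep full precision; this rule applies only in the text
#' renderers.
#'
#' @param rate Numeric vector of percentages.
#' @return Character vector like `"0.29%"`, `"6.8%"`.
#' @export
format_rate <- function(rate) {
  ifelse(is.na(rate), "NA",
         ifelse(rate < 1, sprintf("%.2f%%", rate), sprintf("%.1f%%", rate)))
}

#' Render a cohort performance summary as a text table
#'
#' @param summary A tibble from [summarize_cohort()].
#' @return A character vector of lines.
#' @export
format_cohort_table <- function(summary) {
  header <- sprintf("%-14s %7s %5s %8s %8s %10s %10s %9s %9s",
                    "Stratum", "Cases", "HSCR", "non-HSCR", "Correct",
                    "Incorrect", "Referrals", "Sens.pre", "Sens.post")
  rows <- sprintf("%-14s %7d %5d %8d %8d %10d %10d %9s %9s",
                  summary$stratum, summary$n_cases, summary$n_hscr,
                  summary$n_non_hscr, summary$n_correct, summary$n_incorrect,
                  summary$n_referrals,
                  format_rate(summary$sensitivity_positive_cases_pre_referral),
                  format_rate(summary$sensitivity_positive_cases_post_referral))
  c(header, strrep("-", nchar(header)), rows)
}

#' Render discordance tables as text
#'
#' @param tables A `discordance_tables` object.
#' @return A character vector of lines in the published tables' layout:
#'   per stratum, the image-set total, total error, then one row per error
#'   type with its rate and cause breakdown.
#' @export
format_discordance_table <- function(tables) {
  stopifnot(inherits(tables, "discordance_tables"))
  r <- tables$rates
  lines <- character(0)
  for (i in seq_len(nrow(r))) {
    s <- r$stratum[i]
    lines <- c(lines, sprintf(
      "%s: %d image sets, %d total errors (%s)",
      s, r$n_sets[i], r$n_fp[i] + r$n_fn[i],
      format_rate(r$total_error_rate[i])))
    for (et in c("false_positive", "false_negative")) {
      n_et <- if (et == "false_positive") r$n_fp[i] else r$n_fn[i]
      rate <- if (et == "false_positive") r$fp_rate[i] else r$fn_rate[i]
      cc <- tables$causes[tables$causes$stratum == s &
                            tables$causes$error_type == et, ]
      cause_txt <- if (nrow(cc)) {
        paste(sprintf("%s %d (%s)", cc$cause, cc$n,
                      ifelse(is.na(cc$pct_of_type), "-",
                             sprintf("%.1f%%", cc$pct_of_type))),
              collapse = ", ")
      } else {
        "-"
      }
      lines <- c(lines, sprintf("  %s: %d (%s) | %s",
                                gsub("_", " ", et), n_et, format_rate(rate),
                                cause_txt))
    }
  }
  lines
}

#' Run the case-classification pipeline over score/case tables
#'
#' End-to-end orchestration: reads and validates the score and case
#' tables, classifies every case under the DSS decision criteria,
#' resolves referrals, and tabulates performance per stratum and overall.
#' With `out_dir` set, writes `classification_summary.json` (full
#' precision) and `classification_summary.txt` (display rounding), plus
#' `case_classifications.csv`. Outputs are deterministic for fixed
#' inputs.
#'
#' @param score_table Path to a score CSV/TSV, or a data frame.
#' @param case_table Path to a case CSV/TSV, or a data frame.
#' @param stratify_by `"cohort"` or `"scanner"`.
#' @param out_dir Optional output directory (created if needed).
#' @inheritParams classify_case
#' @return A list with `summary` (per-stratum tibble including a `Total`
#'   row), `classifications` (per-case tibble with final calls) and the
#'   paths written (`files`), invisibly `NULL` entries when `out_dir` is
#'   not given.
#' @export
run_classification <- function(score_table, case_table,
                               stratify_by = c("cohort", "scanner"),
                               out_dir = NULL, ai_cutoff = 0.6,
                               certain_score = 5L, n_certain_required = 2L) {
  stratify_by <- match.arg(stratify_by)
  sets <- if (is.character(score_table)) read_score_table(score_table)
          else as_score_table(score_table)
  cases <- if (is.character(case_table)) read_case_table(case_table)
           else as_case_table(case_table)

  per_stratum <- summarize_cohort(cases, sets, by = stratify_by,
                                  ai_cutoff = ai_cutoff,
                                  certain_score = certain_score,
                                  n_certain_required = n_certain_required)
  overall <- summarize_cohort(cases, sets, ai_cutoff = ai_cutoff,
                              certain_score = certain_score,
                              n_certain_required = n_certain_required)
  overall$stratum <- "Total"
  summary <- bind_rows(per_stratum, overall)

  cls <- classify_cases(sets, ai_cutoff = ai_cutoff,
                        certain_score = certain_score,
                        n_certain_required = n_certain_required)
  cls <- left_join(cls, select(cases, "case_id", "ground_truth",
                               "expert_call"), by = "case_id")
  cls$final_call <- ifelse(cls$label == "positive", "ganglion_present",
                    ifelse(cls$label == "negative", "ganglion_absent",
                           cls$expert_call))
  cls <- arrange(cls, .data$case_id)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    json_path <- file.path(out_dir, "classification_summary.json")
    txt_path <- file.path(out_dir, "classification_summary.txt")
    csv_path <- file.path(out_dir, "case_classifications.csv")
    jsonlite::write_json(summary, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_cohort_table(summary), txt_path)
    readr::write_csv(cls, csv_path)
    files <- c(json = json_path, text = txt_path, csv = csv_path)
  }
  list(summary = summary, classifications = cls, files = files)
}

#' Run the colour-distribution report over an image manifest
#'
#' Reads every tile listed in the manifest, computes per-image RGB
#' histograms, aggregates them per case and per group (scanner or
#' cohort), and reports pairwise squared-L2 distance matrices (case level
#' and group level) plus per-group spread summaries. Rows and columns are
#' ordered by first appearance in the manifest, so outputs are
#' deterministic for a fixed manifest.
#'
#' @param manifest Path to a manifest CSV with columns `path`, `case_id`
#'   and the grouping column, or an equivalent data frame. Relative image
#'   paths are resolved against the manifest's directory.
#' @param group_by Name of the manifest column defining groups (default
#'   `"scanner"`).
#' @param out_dir Optional output directory; writes
#'   `case_distance_matrix.csv`, `group_distance_matrix.csv` and
#'   `spread_summary.csv`.
#' @return A list with `case_distances` and `group_distances` (symmetric
#'   matrices), `spread` (per-group per-channel tibble),
#'   `group_histograms` (named list of `rgb_histogram`s) and `files`.
#' @export
run_color_report <- function(manifest, group_by = "scanner",
                             out_dir = NULL) {
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- .read_delim_auto(manifest)
  }
  manifest <- as_tibble(manifest)
  needed <- c("path", "case_id", group_by)
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(manifest) == 0) stop("empty manifest", call. = FALSE)

  paths <- ifelse(file.exists(manifest$path), manifest$path,
                  file.path(base_dir, manifest$path))
  hists <- lapply(paths, function(p) compute_histogram(read_image_tile(p)))

  case_ids <- unique(manifest$case_id)
  case_hists <- lapply(case_ids, function(cid) {
    aggregate_histograms(hists[manifest$case_id == cid])
  })
  names(case_hists) <- case_ids

  groups <- unique(as.character(manifest[[group_by]]))
  group_hists <- lapply(groups, function(g) {
    aggregate_histograms(hists[as.character(manifest[[group_by]]) == g])
  })
  names(group_hists) <- groups

  dist_matrix <- function(hs) {
    n <- length(hs)
    m <- matrix(0, n, n, dimnames = list(names(hs), names(hs)))
    if (n > 1) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- histogram_distance(hs[[i]], hs[[j]])$value
      }
    }
    m
  }
  case_d <- dist_matrix(case_hists)
  group_d <- dist_matrix(group_hists)

  spread <- purrr::map_dfr(groups, function(g) {
    mutate(spread_summary(group_hists[[g]]), group = g, .before = 1)
  })

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "case_distance_matrix.csv")
    f2 <- file.path(out_dir, "group_distance_matrix.csv")
    f3 <- file.path(out_dir, "spread_summary.csv")
    utils::write.csv(case_d, f1)
    utils::write.csv(group_d, f2)
    readr::write_csv(spread, f3)
    files <- c(case_distances = f1, group_distances = f2, spread = f3)
  }
  list(case_distances = case_d, group_distances = group_d, spread = spread,
       group_histograms = group_hists, files = files)
}
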