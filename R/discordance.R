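#' Label complete pathologist/algorithm discordance for image sets
#'
#' An image set is a **false negative** when the pathologist is certain a
#' ganglion cell is present (score 5) while the DSA score is strictly below
#' `fn_cutoff`: the algorithm under-scored a true ganglion cell. It is a
#' **false positive** when the pathologist is certain no ganglion cell is
#' present (score 1) while the DSA score is strictly above `fp_cutoff`: the
#' algorithm over-scored a non-ganglion structure. Everything else,
#' including sets exactly at a cutoff, is **concordant**. The two
#' conditions are mutually exclusive (they require different pathologist
#' scores).
#'
#' @param dsa_score Numeric vector of DSA scores in \[0, 1\].
#' @param pathologist_score Integer vector of pathologist scores in 1..5.
#' @param fn_cutoff DSA score strictly below which a pathologist-5 set is a
#'   false negative (default 0.3).
#' @param fp_cutoff DSA score strictly above which a pathologist-1 set is a
#'   false positive (default 0.7).
#' @return Character vector with elements in
#'   `c("false_negative", "false_positive", "concordant")`.
#' @export
#' @examples
#' label_discordance(c(0.29, 0.71, 0.30), c(5, 1, 5))
label_discordance <- function(dsa_score, pathologist_score,
                              fn_cutoff = 0.3, fp_cutoff = 0.7) {
  if (length(dsa_score) != length(pathologist_score)) {
    stop("dsa_score and pathologist_score must have the same length",
         call. = FALSE)
  }
  ifelse(pathologist_score == 5L & dsa_score < fn_cutoff, "false_negative",
  ifelse(pathologist_score == 1L & dsa_score > fp_cutoff, "false_positive",
         "concordant"))
}

#' Tabulate discordance rates and causes per stratum
#'
#' Labels every image set with [label_discordance()] and aggregates per
#' stratum: set counts, false-positive/false-negative counts and rates (as
#' percentages of all sets in the stratum), the total error rate, and a
#' causative-factor breakdown. Cause annotations are read from the `causes`
#' column of discordant sets only; a set may carry several causes, and
#' cause percentages are expressed relative to the error-type total
#' (the false-positive or false-negative count), not to all sets.
#'
#' @param sets A score table; every row must carry a non-missing value in
#'   the stratification column.
#' @param by Name of the column of `sets` to stratify by (default
#'   `"cohort"`).
#' @inheritParams label_discordance
#' @return An object of class `discordance_tables`: a list with
#'   * `rates` -- tibble `stratum`, `n_sets`, `n_fp`, `n_fn`, `fp_rate`,
#'     `fn_rate`, `total_error_rate` (full-precision percentages);
#'   * `causes` -- tibble `stratum`, `error_type`, `cause`, `n`,
#'     `pct_of_type`.
#' @export
tabulate_discordance <- function(sets, by = "cohort",
                                 fn_cutoff = 0.3, fp_cutoff = 0.7) {
  sets <- as_score_table(sets)
  if (!by %in% names(sets)) stop("no such stratification column: ", by, call. = FALSE)
  sets$stratum <- as.character(sets[[by]])
  if (anyNA(sets$stratum)) {
    warning("dropping ", sum(is.na(sets$stratum)),
            " image set(s) with missing stratum label")
    sets <- filter(sets, !is.na(.data$stratum))
  }
  if (nrow(sets) == 0L) stop("no image sets to tabulate", call. = FALSE)

  sets$disc <- label_discordance(sets$dsa_score, sets$pathologist_score,
                                 fn_cutoff = fn_cutoff, fp_cutoff = fp_cutoff)

  rates <- sets %>%
    group_by(.data$stratum) %>%
    summarise(
      n_sets = n(),
      n_fp = sum(.data$disc == "false_positive"),
      n_fn = sum(.data$disc == "false_negative"),
      .groups = "drop"
    ) %>%
    mutate(
      fp_rate = 100 * .data$n_fp / .data$n_sets,
      fn_rate = 100 * .data$n_fn / .data$n_sets,
      total_error_rate = 100 * (.data$n_fp + .data$n_fn) / .data$n_sets
    ) %>%
    arrange(.data$stratum)

  discordant <- filter(sets, .data$disc != "concordant")
  if (nrow(discordant)) {
    causes <- discordant %>%
      mutate(cause = lapply(.data$causes, parse_causes)) %>%
      select("stratum", error_type = "disc", "cause") %>%
      tidyr::unnest_longer("cause", keep_empty = FALSE) %>%
      count(.data$stratum, .data$error_type, .data$cause, name = "n")
    # complete over the full taxonomy so zero-count causes are explicit
    grid <- tidyr::expand_grid(
      stratum = unique(rates$stratum),
      error_type = c("false_positive", "false_negative"),
      cause = .cause_levels
    )
    totals <- rates %>%
      select("stratum", false_positive = "n_fp", false_negative = "n_fn") %>%
      tidyr::pivot_longer(-"stratum", names_to = "error_type",
                          values_to = "n_type")
    causes <- grid %>%
      left_join(causes, by = c("stratum", "error_type", "cause")) %>%
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) %>%
      left_join(totals, by = c("stratum", "error_type")) %>%
      mutate(pct_of_type = ifelse(.data$n_type > 0,
                                  100 * .data$n / .data$n_type, NA_real_)) %>%
      select(-"n_type")
  } else {
    causes <- tibble(stratum = character(), error_type = character(),
                     cause = character(), n = integer(),
                     pct_of_type = double())
  }

  structure(list(rates = rates, causes = causes, by = by),
            class = "discordance_tables")
}

#' @export
print.discordance_tables <- function(x, ...) {
  cat(format_discordance_table(x), sep = "\n")
  invisible(x)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Computes expected counts `E = row_total * col_total / N`, the Pearson
#' statistic `sum((O - E)^2 / E)` with `df = (r - 1)(c - 1)`, and the upper
#' tail of the chi-square distribution as the p-value. With
#' `yates = TRUE` and a 2x2 table, the Yates continuity correction
#' (subtracting 0.5 from each `|O - E|`, floored at zero) is applied.
#' Used to compare error-profile counts between cohorts or scanners.
#'
#' @param table A matrix (r >= 2, c >= 2) of non-negative integer counts.
#' @param yates Apply the continuity correction for 2x2 tables (default
#'   `FALSE`, matching uncorrected reporting).
#' @return An object of class `htest` with `statistic`, `parameter` (df),
#'   `p.value`, `observed` and `expected`.
#' @export
#' @examples
#' chi_square_independence(matrix(c(20, 40, 80, 60), 2, 2))
chi_square_independence <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (anyNA(table) || any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: zero row or column marginal", call. = FALSE)
  }
  n <- sum(table)
  expected <- outer(rs, cs) / n
  dev <- abs(table - expected)
  if (yates && nrow(table) == 2 && ncol(table) == 2) {
    dev <- pmax(dev - 0.5, 0)
  }
  statistic <- sum(dev^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  p <- pchisq(statistic, df = df, lower.tail = FALSE)
  structure(
    list(
      statistic = c("X-squared" = statistic),
      parameter = c(df = df),
      p.value = p,
      method = paste0("Pearson's chi-square test of independence",
                      if (yates && df == 1) " with Yates continuity correction"),
      data.name = deparse(substitute(table)),
      observed = table,
      expected = expected
    ),
    class = "htest"
  )
}

#' Pairwise chi-square comparisons of error profiles
#'
#' Builds, for every pair of strata, the 2x2 table of false-negative and
#' false-positive counts and runs [chi_square_independence()]. P-values are
#' uncorrected by default; `p_adjust = "bonferroni"` applies the Bonferroni
#' correction across the pairs.
#'
#' @param tables A `discordance_tables` object from [tabulate_discordance()].
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @param yates Passed to [chi_square_independence()].
#' @return A tibble with `stratum_1`, `stratum_2`, `statistic`, `df`, `p`.
#' @export
compare_error_profiles <- function(tables, p_adjust = "none", yates = FALSE) {
  stopifnot(inherits(tables, "discordance_tables"))
  r <- tables$rates
  if (nrow(r) < 2) stop("need at least two strata to compare", call. = FALSE)
  pairs <- utils::combn(r$stratum, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    a <- r[r$stratum == p[1], ]
    b <- r[r$stratum == p[2], ]
    tab <- rbind(c(a$n_fn, a$n_fp), c(b$n_fn, b$n_fp))
    ht <- chi_square_independence(tab, yates = yates)
    tibble(stratum_1 = p[1], stratum_2 = p[2],
           statistic = unname(ht$statistic),
           df = unname(ht$parameter), p = ht$p.value)
  })
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  out
}
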