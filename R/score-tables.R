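#' Validate and coerce an image-set score table
#'
#' An image-set score table holds one row per image set presented to the
#' pathologist: the algorithm (DSA) confidence score in \[0, 1\], the
#' pathologist score on the 1--5 ordinal scale (1 = certainly no ganglion
#' cells, 5 = certainly ganglion cells), and optional semicolon-separated
#' causative-factor annotations used in discordance analysis.
#'
#' Required columns: `case_id`, `set_index`, `dsa_score`,
#' `pathologist_score`. Optional: `cohort`, `scanner`, `causes` (filled with
#' `NA` when absent). Extra columns are preserved.
#'
#' @param x A data frame.
#' @return A validated tibble with at least the columns above.
#' @export
#' @examples
#' as_score_table(data.frame(
#'   case_id = "c1", set_index = 1:2,
#'   dsa_score = c(0.9, 0.2), pathologist_score = c(5, 1)
#' ))
as_score_table <- function(x) {
  x <- as_tibble(x)
  required <- c("case_id", "set_index", "dsa_score", "pathologist_score")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("score table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("cohort", "scanner", "causes")) {
    if (!opt %in% names(x)) x[[opt]] <- NA_character_
  }
  x$case_id <- as.character(x$case_id)
  x$causes <- as.character(x$causes)

  if (anyNA(x$pathologist_score)) {
    bad <- unique(x$case_id[is.na(x$pathologist_score)])
    stop("missing pathologist score(s) for case(s): ",
         paste(head(bad, 5), collapse = ", "),
         " (scores are required, not imputed)", call. = FALSE)
  }
  ps <- x$pathologist_score
  if (any(ps != as.integer(ps)) || any(ps < 1) || any(ps > 5)) {
    stop("pathologist_score must be an integer in 1..5", call. = FALSE)
  }
  x$pathologist_score <- as.integer(ps)
  if (anyNA(x$dsa_score) || any(x$dsa_score < 0) || any(x$dsa_score > 1)) {
    stop("dsa_score must lie in [0, 1] with no missing values", call. = FALSE)
  }
  if (any(x$set_index < 1) || any(x$set_index != as.integer(x$set_index))) {
    stop("set_index must be an integer >= 1", call. = FALSE)
  }
  x$set_index <- as.integer(x$set_index)
  dup <- x %>%
    count(.data$case_id, .data$set_index) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicated set_index within case(s): ",
         paste(head(unique(dup$case_id), 5), collapse = ", "), call. = FALSE)
  }
  over <- x %>% count(.data$case_id) %>% filter(.data$n > 12)
  if (nrow(over)) {
    stop("more than 12 image sets for case(s): ",
         paste(head(over$case_id, 5), collapse = ", "), call. = FALSE)
  }
  known <- !is.na(x$causes) & x$causes != ""
  if (any(known)) {
    parsed <- unique(unlist(strsplit(x$causes[known], ";", fixed = TRUE)))
    parsed <- trimws(parsed)
    bad <- setdiff(parsed, .cause_levels)
    if (length(bad)) {
      stop("unknown cause annotation(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(.cause_levels, collapse = ", "), call. = FALSE)
    }
  }
  x
}

#' Validate and coerce a case table
#'
#' One row per clinical case: `case_id`, `ground_truth`
#' (`"ganglion_present"` = non-Hirschsprung, `"ganglion_absent"` = disease),
#' and optionally `expert_call` (the expert's call, consulted only for cases
#' the DSS leaves in doubt), `cohort` and `scanner`.
#'
#' @param x A data frame.
#' @return A validated tibble.
#' @export
as_case_table <- function(x) {
  x <- as_tibble(x)
  required <- c("case_id", "ground_truth")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("case table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("cohort", "scanner", "expert_call")) {
    if (!opt %in% names(x)) x[[opt]] <- NA_character_
  }
  x$case_id <- as.character(x$case_id)
  if (anyDuplicated(x$case_id)) {
    stop("duplicated case_id in case table", call. = FALSE)
  }
  if (!all(x$ground_truth %in% .truth_levels)) {
    stop("ground_truth must be one of: ", paste(.truth_levels, collapse = ", "),
         call. = FALSE)
  }
  ec <- x$expert_call
  if (!all(is.na(ec) | ec %in% .truth_levels)) {
    stop("expert_call must be NA or one of: ",
         paste(.truth_levels, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read score and case tables from delimited files
#'
#' Comma-separated by default; files ending in `.tsv` or `.txt` are read as
#' tab-separated. A header row is required.
#'
#' @param path Path to a CSV/TSV file.
#' @return A validated tibble (see [as_score_table()], [as_case_table()]).
#' @export
read_score_table <- function(path) {
  as_score_table(.read_delim_auto(path))
}

#' @rdname read_score_table
#' @export
read_case_table <- function(path) {
  as_case_table(.read_delim_auto(path))
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

# Split a semicolon-separated cause string into a character vector.
parse_causes <- function(causes) {
  if (is.na(causes) || causes == "") return(character(0))
  trimws(strsplit(causes, ";", fixed = TRUE)[[1]])
}
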