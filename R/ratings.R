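# Registration methods compared in the rating study.
RATING_METHODS <- c("3P", "TIE", "EL", "ANTS")

# Grades on the 6-point school-style Likert scale, half-steps allowed:
# 1 = best possible alignment, 6 = no alignment / non-convergence.
valid_grades <- function() seq(1, 6, by = 0.5)

#' Build a validated rating table
#'
#' One row per (dataset, method, rater): a grade on the 6-point Likert scale
#' with half-steps (1 = best possible alignment, 6 = no
#' alignment/non-convergence).
#'
#' @param dataset_id Character vector of dataset identifiers.
#' @param method Character vector of method labels; one of `3P`, `TIE`,
#'   `EL`, `ANTS` (case-insensitive).
#' @param rater_id Character vector of rater identifiers.
#' @param grade Numeric vector of grades in `{1, 1.5, ..., 6}`.
#' @return A `data.frame` with class `rating_table`.
#' @export
rating_table <- function(dataset_id, method, rater_id, grade) {
  df <- data.frame(dataset_id = as.character(dataset_id),
                   method = toupper(as.character(method)),
                   rater_id = as.character(rater_id),
                   grade = as.numeric(grade),
                   stringsAsFactors = FALSE)
  bad_method <- setdiff(unique(df$method), RATING_METHODS)
  if (length(bad_method)) {
    stopf("unknown method label(s): %s (expected %s)",
          paste(bad_method, collapse = ", "),
          paste(RATING_METHODS, collapse = ", "))
  }
  out_of_range <- df$grade < 1 | df$grade > 6 | !is.finite(df$grade)
  if (any(out_of_range)) {
    stopf("grade(s) outside [1, 6]: %s",
          paste(unique(df$grade[out_of_range]), collapse = ", "))
  }
  off_step <- abs(df$grade * 2 - round(df$grade * 2)) > 1e-9
  if (any(off_step)) {
    stopf("grade(s) not on the half-step grid: %s",
          paste(unique(df$grade[off_step]), collapse = ", "))
  }
  key <- paste(df$dataset_id, df$method, df$rater_id, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("duplicate (dataset, method, rater) record(s)")
  }
  class(df) <- c("rating_table", "data.frame")
  df
}

#' Read a rating table from CSV
#'
#' Expects a delimited text file with header
#' `dataset_id,method,rater_id,grade`; records are validated against the
#' 6-point half-step scale.
#'
#' @param path File path.
#' @return A [rating_table()].
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dataset_id", "method", "rater_id", "grade")
  if (!all(need %in% names(df))) {
    stopf("rating file must have columns %s", paste(need, collapse = ", "))
  }
  rating_table(df$dataset_id, df$method, df$rater_id, df$grade)
}

#' Write a rating table to CSV
#'
#' @param ratings A [rating_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  stopifnot(inherits(ratings, "rating_table"))
  write.csv(as.data.frame(ratings), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
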