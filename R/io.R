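# Tidy CSV readers/writers for the four record types, with row-level
# validation.  All tables are comma-separated, UTF-8, "." decimal, one row
# per probe/trial/rating/guess.

probe_cols <- function() {
  readr::cols(
    participant_id = readr::col_character(),
    condition = readr::col_character(),
    probe_index = readr::col_integer(),
    time_s = readr::col_double(),
    answer = readr::col_character(),
    confidence = readr::col_double()
  )
}

trial_cols <- function() {
  readr::cols(
    participant_id = readr::col_character(),
    condition = readr::col_character(),
    block = readr::col_integer(),
    subblock = readr::col_integer(),
    stimulus = readr::col_character(),
    response = readr::col_character(),
    correct = readr::col_logical(),
    rt_ms = readr::col_double()
  )
}

rating_cols <- function() {
  readr::cols(
    participant_id = readr::col_character(),
    condition = readr::col_character(),
    headache = readr::col_integer(),
    tingling = readr::col_integer(),
    itching = readr::col_integer(),
    burning = readr::col_integer(),
    pain = readr::col_integer()
  )
}

guess_cols <- function() {
  readr::cols(
    participant_id = readr::col_character(),
    guessed_sham_session = readr::col_character(),
    correct = readr::col_logical(),
    confidence = readr::col_double()
  )
}

# Return a character vector of row-level problems (empty if clean).
validate_probes <- function(x) {
  p <- character()
  bad <- function(i, msg) sprintf("row %d: %s", i, msg)
  idx <- seq_len(nrow(x))
  p <- c(p, bad(idx[!x$condition %in% c("active", "sham")],
                "condition must be 'active' or 'sham'"))
  p <- c(p, bad(idx[is.na(x$probe_index) | x$probe_index < 1],
                "probe_index must be a positive integer"))
  p <- c(p, bad(idx[!is.na(x$answer) & !x$answer %in% c("yes", "no")],
                "answer must be 'yes', 'no' or missing"))
  p <- c(p, bad(idx[!is.na(x$confidence) & (x$confidence < 0 | x$confidence > 10)],
                "confidence must lie in [0, 10]"))
  p <- c(p, bad(idx[is.na(x$answer) != is.na(x$confidence)],
                "answer and confidence must be missing together"))
  p <- c(p, bad(idx[is.na(x$time_s) | x$time_s < 0],
                "time_s must be non-negative"))
  p
}

validate_trials <- function(x) {
  p <- character()
  bad <- function(i, msg) sprintf("row %d: %s", i, msg)
  idx <- seq_len(nrow(x))
  p <- c(p, bad(idx[!x$condition %in% c("active", "sham")],
                "condition must be 'active' or 'sham'"))
  p <- c(p, bad(idx[is.na(x$block) | x$block < 1 | x$block > 4],
                "block must be in 1..4"))
  p <- c(p, bad(idx[!x$stimulus %in% c("diamond", "square")],
                "stimulus must be 'diamond' or 'square'"))
  p <- c(p, bad(idx[!x$response %in% c("left", "right", "none")],
                "response must be 'left', 'right' or 'none'"))
  expected_correct <- (x$stimulus == "diamond" & x$response == "left") |
    (x$stimulus == "square" & x$response == "right")
  p <- c(p, bad(idx[!is.na(x$correct) & x$response %in% c("left", "right", "none") &
                      x$stimulus %in% c("diamond", "square") &
                      x$correct != expected_correct],
                "correct is inconsistent with stimulus/response mapping"))
  p <- c(p, bad(idx[is.na(x$rt_ms) != (x$response == "none")],
                "rt_ms must be missing exactly when response is 'none'"))
  p <- c(p, bad(idx[!is.na(x$rt_ms) & x$rt_ms <= 0],
                "rt_ms must be positive"))
  p
}

validate_ratings <- function(x) {
  p <- character()
  bad <- function(i, msg) sprintf("row %d: %s", i, msg)
  idx <- seq_len(nrow(x))
  p <- c(p, bad(idx[!x$condition %in% c("active", "sham")],
                "condition must be 'active' or 'sham'"))
  for (scale in c("headache", "tingling", "itching", "burning", "pain")) {
    v <- x[[scale]]
    p <- c(p, bad(idx[is.na(v) | v < 1 | v > 5],
                  sprintf("%s must be an integer in 1..5", scale)))
  }
  p
}

validate_guesses <- function(x) {
  p <- character()
  bad <- function(i, msg) sprintf("row %d: %s", i, msg)
  idx <- seq_len(nrow(x))
  p <- c(p, bad(idx[!x$guessed_sham_session %in% c("session1", "session2")],
                "guessed_sham_session must be 'session1' or 'session2'"))
  p <- c(p, bad(idx[is.na(x$correct)], "correct must be TRUE or FALSE"))
  p <- c(p, bad(idx[is.na(x$confidence) | x$confidence < 1 | x$confidence > 10],
                "confidence must lie in [1, 10]"))
  p
}

read_validated <- function(path, cols, validator, what, strict) {
  x <- readr::read_csv(path, col_types = cols, progress = FALSE)
  missing_cols <- setdiff(names(cols$cols), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  what, paste(missing_cols, collapse = ", ")))
  }
  problems <- validator(x)
  if (length(problems) > 0) {
    msg <- sprintf("%s: %d invalid row(s) rejected:\n%s", what, length(problems),
                   paste(utils::head(problems, 10), collapse = "\n"))
    if (strict) abort(msg)
    warn(msg)
    bad_rows <- unique(as.integer(sub("^row (\\d+):.*$", "\\1", problems)))
    x <- x[-bad_rows, , drop = FALSE]
  }
  attr(x, "problems") <- problems
  x
}

#' Read and validate study tables
#'
#' Readers for the four tidy CSV schemas used throughout the package:
#' probe responses, reaction-time trials, side-effect ratings, and
#' end-of-study sham guesses.  Each reader type-checks the columns and
#' applies the row-level invariants of its record type (confidence within
#' scale bounds, answer/confidence jointly missing, correctness consistent
#' with the stimulus-response mapping, and so on).  Offending rows are
#' dropped with a diagnostic naming each row, or rejected outright when
#' `strict = TRUE`.
#'
#' @param path Path to a CSV file with a header row.
#' @param strict If `TRUE`, any invalid row aborts the read; otherwise
#'   invalid rows are dropped with a warning listing them.
#' @return A tibble of validated records.  The character vector of row
#'   diagnostics is attached as attribute `"problems"`.
#' @name read_tables
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 2), seed = 1)
#' tmp <- tempfile(fileext = ".csv")
#' write_probes(cohort$probes, tmp)
#' probes <- read_probes(tmp)
#' nrow(probes)  # 2 participants x 2 sessions x 32 probes
NULL

#' @rdname read_tables
#' @export
read_probes <- function(path, strict = FALSE) {
  read_validated(path, probe_cols(), validate_probes, "probes", strict)
}

#' @rdname read_tables
#' @export
read_trials <- function(path, strict = FALSE) {
  read_validated(path, trial_cols(), validate_trials, "trials", strict)
}

#' @rdname read_tables
#' @export
read_ratings <- function(path, strict = FALSE) {
  read_validated(path, rating_cols(), validate_ratings, "ratings", strict)
}

#' @rdname read_tables
#' @export
read_guesses <- function(path, strict = FALSE) {
  read_validated(path, guess_cols(), validate_guesses, "guesses", strict)
}

#' Write study tables
#'
#' Plain-CSV writers matching the [read_probes()] family.  Writing and
#' re-reading a table is lossless.
#'
#' @param x A tibble of the corresponding record type.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_probes <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' @rdname write_tables
#' @export
write_trials <- write_probes

#' @rdname write_tables
#' @export
write_ratings <- write_probes

#' @rdname write_tables
#' @export
write_guesses <- write_probes
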