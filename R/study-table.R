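#' Study-level attrition tables
#'
#' A study table holds, for each randomized controlled trial, the
#' intention-to-treat (ITT) sample size and the number of posttreatment
#' dropouts in the active and passive (waitlist / no treatment) arms,
#' plus optional coded design moderators. It is the input to the
#' differential-attrition meta-analysis functions.
#'
#' Required columns: `study_id`, `n_itt_active`, `drop_active`,
#' `n_itt_passive`, `drop_passive`. Recognized moderator columns:
#' `diff` (one of `"not_tested"`, `"tested_no_difference"`,
#' `"higher_in_active"`), `method` (`"anova"`, `"mlm"`, `"t_test"`),
#' `used_mi` and `used_ml` (`"yes"`, `"no"`, `"unclear"`,
#' `"not_reported"`).
#'
#' @param x A data frame with the columns above.
#' @return `as_study_table()` returns `x` validated and classed as
#'   `study_table`.
#' @examples
#' tab <- as_study_table(data.frame(
#'   study_id = c("a", "b"),
#'   n_itt_active = c(100, 50), drop_active = c(25, 10),
#'   n_itt_passive = c(100, 50), drop_passive = c(10, 5)))
#' @export
as_study_table <- function(x) {
  required <- c("study_id", "n_itt_active", "drop_active",
                "n_itt_passive", "drop_passive")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)
  counts <- c("n_itt_active", "drop_active", "n_itt_passive", "drop_passive")
  for (cc in counts) {
    if (!is.numeric(x[[cc]])) {
      stop("column '", cc, "' must be numeric", call. = FALSE)
    }
  }
  bad <- which(!complete.cases(x[counts]))
  if (length(bad) > 0L) {
    stop("missing counts in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(x$n_itt_active < 0 | x$n_itt_passive < 0 |
                 x$drop_active < 0 | x$drop_passive < 0)
  if (length(bad) > 0L) {
    stop("negative counts in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(x$drop_active > x$n_itt_active |
                 x$drop_passive > x$n_itt_passive)
  if (length(bad) > 0L) {
    stop("dropouts exceed the ITT sample in row(s): ",
         paste(bad, collapse = ", "),
         " (", paste(x$study_id[bad], collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(x$study_id)) {
    stop("duplicated study_id: ",
         paste(unique(x$study_id[duplicated(x$study_id)]), collapse = ", "),
         call. = FALSE)
  }
  x$study_id <- as.character(x$study_id)
  class(x) <- c("study_table", "data.frame")
  x
}

#' Read and write study tables
#'
#' CSV with a header row; comma separated, decimal point; missing values
#' written as empty cells ("NA" is also accepted on read). Malformed rows
#' are reported by row number.
#'
#' @param path Path to a CSV file.
#' @return `read_study_table()` returns a [as_study_table()] object.
#' @seealso [attrition_fixture()] for the packaged 36-study table.
#' @export
read_study_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  as_study_table(x)
}

#' @param x A study table.
#' @rdname read_study_table
#' @export
write_study_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Packaged attrition table: 36 mHealth RCTs with waitlist controls
#'
#' Posttreatment attrition counts and coded design features for 36
#' randomized controlled trials of smartphone-based mental health
#' interventions that compared one or more active conditions with a
#' waitlist (or no-treatment) control. For each trial the table records
#' the ITT sample size and the number of dropouts at the posttreatment
#' assessment in each arm, whether differential attrition was tested and
#' detected, the primary analysis method, and whether multiple imputation
#' or maximum likelihood was used for missing data.
#'
#' @return A [as_study_table()] object with 36 rows
#'   (`attrition_fixture()`), or the file path of the underlying CSV
#'   (`attrition_fixture_path()`).
#' @examples
#' tab <- attrition_fixture()
#' nrow(tab)
#' @export
attrition_fixture <- function() {
  read_study_table(attrition_fixture_path())
}

#' @rdname attrition_fixture
#' @export
attrition_fixture_path <- function() {
  system.file("extdata", "mhealth_rct_attrition.csv", package = "mnarsens",
              mustWork = TRUE)
}

#' Code binary moderators from a study table
#'
#' Derives the numeric moderator columns used in the meta-regressions:
#' `total_n` (ITT active + passive), `overall_attrition` (total dropouts /
#' total N, a proportion), `tested_diff` (1 if differential attrition was
#' statistically compared), `detected_diff` (1 if a difference was
#' detected; `NA` for studies that did not test, so that regressions on
#' this moderator run among tested studies only), and `used_ml_or_mi`
#' (1 if either multiple imputation or maximum likelihood was used;
#' "unclear" and "not_reported" count as 0).
#'
#' @param table A [as_study_table()] object.
#' @return A data frame with one row per study.
#' @export
code_moderators <- function(table) {
  table <- as_study_table(table)
  total_n <- table$n_itt_active + table$n_itt_passive
  out <- data.frame(
    study_id = table$study_id,
    total_n = total_n,
    overall_attrition = (table$drop_active + table$drop_passive) / total_n,
    stringsAsFactors = FALSE
  )
  if ("diff" %in% names(table)) {
    out$tested_diff <- as.integer(table$diff %in%
                                    c("tested_no_difference", "higher_in_active"))
    out$detected_diff <- ifelse(out$tested_diff == 1L,
                                as.integer(table$diff == "higher_in_active"),
                                NA_integer_)
  }
  if (all(c("used_mi", "used_ml") %in% names(table))) {
    yes <- function(v) !is.na(v) & tolower(v) == "yes"
    out$used_ml_or_mi <- as.integer(yes(table$used_mi) | yes(table$used_ml))
  }
  out
}
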