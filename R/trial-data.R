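#' Subject-level trial data
#'
#' A trial dataset holds one row per randomized subject: `subject_id`,
#' `arm` (`"active"` or `"passive"`), `pretest` (continuous, observed
#' for everyone), `posttest` (continuous, `NA` when the subject dropped
#' out before the posttreatment assessment), and optional numeric
#' covariate columns. The outcome direction (whether lower scores are
#' better, as for a distress composite, or higher, as for well-being)
#' travels with the dataset.
#'
#' Subjects with a missing pretest are removed with a warning: both
#' sensitivity analyses condition on the pretest throughout.
#'
#' @param x A data frame with the columns above.
#' @param direction `"lower_is_better"` (default) or `"higher_is_better"`.
#' @param covariates Character vector of covariate column names to carry
#'   into the imputation model.
#' @return `x` validated and classed as `trial_data`, with the arm coded
#'   as a factor with levels `passive`, `active` (so regression
#'   coefficients contrast active against passive).
#' @examples
#' d <- as_trial_data(data.frame(
#'   subject_id = 1:6, arm = rep(c("active", "passive"), 3),
#'   pretest = rnorm(6), posttest = c(rnorm(5), NA)))
#' @export
as_trial_data <- function(x, direction = c("lower_is_better",
                                           "higher_is_better"),
                          covariates = character()) {
  direction <- match.arg(direction)
  required <- c("subject_id", "arm", "pretest", "posttest")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("trial data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)
  if (anyDuplicated(x$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(x$subject_id[duplicated(x$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_arm <- setdiff(unique(as.character(x$arm)), c("active", "passive"))
  if (length(bad_arm) > 0L) {
    stop("unknown arm label(s): ", paste(bad_arm, collapse = ", "),
         call. = FALSE)
  }
  x$arm <- factor(as.character(x$arm), levels = c("passive", "active"))
  missing_cov <- setdiff(covariates, names(x))
  if (length(missing_cov) > 0L) {
    stop("covariate column(s) not found: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  if (anyNA(x$pretest)) {
    n_bad <- sum(is.na(x$pretest))
    warning(n_bad, " subject(s) with missing pretest removed")
    x <- x[!is.na(x$pretest), , drop = FALSE]
  }
  if (any(table(x$arm) < 2L)) {
    stop("need at least 2 subjects per arm", call. = FALSE)
  }
  attr(x, "direction") <- direction
  attr(x, "covariates") <- covariates
  class(x) <- c("trial_data", "data.frame")
  x
}

#' @rdname as_trial_data
#' @export
trial_direction <- function(x) {
  attr(x, "direction") %||% "lower_is_better"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write subject-level trial data
#'
#' CSV with header `subject_id, arm, pretest, posttest` plus optional
#' covariate columns; empty cells and `NA` in `posttest` mean the
#' posttest is missing.
#'
#' @param path Path to a CSV file.
#' @inheritParams as_trial_data
#' @return `read_trial()` returns a [as_trial_data()] object.
#' @export
read_trial <- function(path, direction = c("lower_is_better",
                                           "higher_is_better"),
                       covariates = character()) {
  x <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  as_trial_data(x, direction = direction, covariates = covariates)
}

#' @param x A trial dataset.
#' @rdname read_trial
#' @export
write_trial <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
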