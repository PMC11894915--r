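#' Individual-level validation sample
#'
#' One row per subject: the model's predicted risk and the observed binary
#' outcome. This is the raw input of the bootstrap algorithm and of decision
#' curves; the aggregate algorithms only need its confusion counts at a
#' threshold.
#'
#' @param risk Numeric vector of predicted risks in \[0, 1\].
#' @param outcome Vector of 0/1 observed outcomes, same length as `risk`.
#' @return A data frame of class `validation_sample` with columns `risk` and
#'   `outcome`.
#' @export
validation_sample <- function(risk, outcome) {
  if (length(risk) != length(outcome)) {
    stop("`risk` and `outcome` must have the same length", call. = FALSE)
  }
  if (length(risk) < 1L) stop("sample must contain at least one record",
                              call. = FALSE)
  check_risk_outcome(risk, outcome)
  out <- data.frame(risk = as.numeric(risk), outcome = as.integer(outcome))
  class(out) <- c("validation_sample", "data.frame")
  out
}

check_risk_outcome <- function(risk, outcome, where = "input") {
  bad_r <- which(!is.finite(risk) | risk < 0 | risk > 1)
  if (length(bad_r)) {
    stop(sprintf("%s: `risk` must lie in [0, 1]; offending row(s): %s",
                 where, paste(utils::head(bad_r, 5L), collapse = ", ")),
         call. = FALSE)
  }
  bad_o <- which(!(outcome %in% c(0, 1)))
  if (length(bad_o)) {
    stop(sprintf("%s: `outcome` must be 0 or 1; offending row(s): %s",
                 where, paste(utils::head(bad_o, 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

as_validation_sample <- function(x) {
  if (inherits(x, "validation_sample")) return(x)
  if (is.data.frame(x) && all(c("risk", "outcome") %in% names(x))) {
    return(validation_sample(x$risk, x$outcome))
  }
  stop("expected a validation_sample or a data frame with columns ",
       "`risk` and `outcome`", call. = FALSE)
}

#' @export
print.validation_sample <- function(x, ...) {
  cat(sprintf("Validation sample: n = %d, events = %d (prevalence %.4g)\n",
              nrow(x), sum(x$outcome), mean(x$outcome)))
  invisible(x)
}

#' Read / write a validation sample as CSV
#'
#' The file must have a header with columns `risk` (float in \[0, 1\]) and
#' `outcome` (0/1); extra columns are ignored. Invalid values are rejected
#' with the offending row numbers.
#'
#' @param path Path to a CSV file.
#' @return [read_validation_sample()] returns a [validation_sample()];
#'   [write_validation_sample()] returns `path` invisibly.
#' @export
read_validation_sample <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(c("risk", "outcome"), names(df))
  if (length(missing_cols)) {
    stop("CSV ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_risk_outcome(df$risk, df$outcome, where = path)
  validation_sample(df$risk, df$outcome)
}

#' @rdname read_validation_sample
#' @param sample A [validation_sample()].
#' @export
write_validation_sample <- function(sample, path) {
  sample <- as_validation_sample(sample)
  utils::write.csv(sample, path, row.names = FALSE)
  invisible(path)
}

#' Confusion counts of a validation sample at a threshold
#'
#' Classifies predicted risk >= `z` as positive (a risk exactly equal to the
#' threshold is treated).
#'
#' @param sample A [validation_sample()].
#' @param threshold A [risk_threshold()] or bare `z`.
#' @return A [confusion_counts()] object.
#' @export
counts_from_sample <- function(sample, threshold) {
  sample <- as_validation_sample(sample)
  thr <- as_risk_threshold(threshold)
  cc <- counts_at_threshold(sample$risk, sample$outcome, thr$z)
  confusion_counts(cc["n_tp"], cc["n_fn"], cc["n_tn"], cc["n_fp"])
}
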