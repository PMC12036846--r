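# Canonical trial-log interchange: CSV (UTF-8, comma, header) with one row
# per decision, schema-validated on read.

.trial_log_schema <- c(
  "subject_id", "group", "block", "block_label", "trial", "design_tag",
  "agent", "ss_amount", "ll_amount", "delay_days", "choice",
  "feedback_correct", "rng_stream_id"
)

.block_labels <- c("Self1", "Other1", "Self2", "Other2", "Self3")

#' Validate a trial-log data frame
#'
#' Checks the canonical schema: required columns, integer amounts and delays,
#' 1-based block (1-5) and trial (1-50) indices, block labels consistent with
#' block numbers, choices in `{SS, LL}`, and design tags in
#' `{generative, adaptive}`.
#'
#' @param trials data frame to validate.
#' @return The validated data frame, invisibly; errors describe the first
#'   offending column/rows.
#' @export
validate_trial_log <- function(trials) {
  miss <- setdiff(.trial_log_schema, names(trials))
  if (length(miss)) stop("trial log is missing column(s): ", paste(miss, collapse = ", "))
  bad <- function(cond, what) {
    w <- which(cond)
    if (length(w)) stop(sprintf("invalid %s at row(s) %s", what,
                                paste(utils::head(w, 5L), collapse = ", ")))
  }
  bad(is.na(trials$choice) | !trials$choice %in% c("SS", "LL"), "choice")
  bad(!trials$design_tag %in% c("generative", "adaptive"), "design_tag")
  bad(!trials$block %in% 1:5, "block")
  bad(trials$block_label != .block_labels[trials$block], "block_label")
  bad(!trials$trial %in% 1:50, "trial")
  bad(trials$ss_amount != round(trials$ss_amount) | trials$ss_amount < 1 |
        trials$ss_amount > 20, "ss_amount")
  bad(trials$ll_amount != round(trials$ll_amount) | trials$ll_amount < 1 |
        trials$ll_amount > 20 | trials$ll_amount <= trials$ss_amount, "ll_amount")
  bad(trials$delay_days != round(trials$delay_days) | trials$delay_days < 1 |
        trials$delay_days > 90, "delay_days")
  invisible(trials)
}

#' Write a trial log to CSV
#'
#' @param trials validated trial-log data frame (e.g. the `trials` element of
#'   a [generate_cohort()] result).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  validate_trial_log(trials)
  utils::write.csv(trials[, .trial_log_schema], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial log from CSV
#'
#' @param path CSV file as written by [write_trial_log()].
#' @return Validated trial-log data frame.
#' @export
read_trial_log <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                            colClasses = c(feedback_correct = "logical"))
  validate_trial_log(trials)
  trials
}
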