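# --- error metrics and study summaries ----------------------------------

#' Needle pose error against ground truth
#'
#' Euclidean displacement of the estimated base and tip from the true ones.
#'
#' @param estimated,truth [needle_pose()] objects with equal needle length.
#' @return List of class `pose_error`: `base_error`, `tip_error` (mm).
#' @export
pose_error <- function(estimated, truth) {
  stopifnot(inherits(estimated, "needle_pose"), inherits(truth, "needle_pose"))
  if (abs(estimated$length - truth$length) > 1e-6)
    stop("needle lengths differ between estimated and true pose")
  structure(list(base_error = sqrt(sum((estimated$base - truth$base)^2)),
                 tip_error = sqrt(sum((estimated$tip - truth$tip)^2))),
            class = "pose_error")
}

#' Summarize pose errors as mean +/- standard deviation
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' base and tip errors, formatted "m +/- s" to two decimals. With a single
#' measurement the SD is reported as 0 and the result flagged.
#'
#' @param errors List of [pose_error()] objects (or a data.frame with
#'   columns `base_error`, `tip_error`), non-empty.
#' @return data.frame with columns component, mean, sd, formatted; attribute
#'   `"flagged_single"` is TRUE when n = 1.
#' @export
summarize_errors <- function(errors) {
  if (is.data.frame(errors)) df <- errors
  else df <- do.call(rbind, lapply(errors, function(e)
    data.frame(base_error = e$base_error, tip_error = e$tip_error)))
  if (is.null(df) || nrow(df) == 0) stop("no errors to summarize")
  single <- nrow(df) == 1
  sdv <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  out <- data.frame(
    component = c("base", "tip"),
    mean = c(mean(df$base_error), mean(df$tip_error)),
    sd = c(sdv(df$base_error), sdv(df$tip_error)))
  out$formatted <- sprintf("%.2f ± %.2f", out$mean, out$sd)
  attr(out, "flagged_single") <- single
  out
}

#' Puncture accuracy
#'
#' Percentage of punctures that hit the lesion, rounded to two decimals.
#'
#' @param records Logical hit vector, or a data.frame with a logical `hit`
#'   column (e.g. from [simulate_puncture_study()]).
#' @return Accuracy in percent.
#' @export
puncture_accuracy <- function(records) {
  hits <- if (is.data.frame(records)) records$hit else records
  if (length(hits) == 0) stop("no puncture records")
  round(100 * sum(hits) / length(hits), 2)
}

#' Parse "mm:ss" durations to seconds
#'
#' Numeric input is passed through unchanged.
#'
#' @param x Character vector like "01:57" (or numeric seconds).
#' @return Numeric seconds.
#' @export
parse_mmss <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(strsplit(as.character(x), ":"), function(p) {
    if (length(p) != 2) stop("time not in mm:ss format: ", paste(p, collapse = ":"))
    60 * as.numeric(p[1]) + as.numeric(p[2])
  }, numeric(1))
}

#' Read an injection-time study table
#'
#' CSV with columns `exam`, `experienced` (yes/no), `punctures_with`,
#' `time_with`, `punctures_without`, `time_without`; times as "mm:ss" or
#' seconds.
#'
#' @param path CSV path.
#' @return data.frame with times converted to seconds.
#' @export
read_study <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("exam", "experienced", "punctures_with", "time_with",
            "punctures_without", "time_without")
  if (!all(need %in% names(df)))
    stop("study CSV must have columns: ", paste(need, collapse = ", "))
  df$time_with <- parse_mmss(df$time_with)
  df$time_without <- parse_mmss(df$time_without)
  df$experienced <- tolower(as.character(df$experienced)) %in%
    c("yes", "true", "1", "y")
  if (any(df$punctures_with < 1 | df$punctures_without < 1))
    stop("puncture counts must be >= 1")
  if (any(df$time_with <= 0 | df$time_without <= 0))
    stop("times must be positive")
  df
}

#' Summarize an injection-time study
#'
#' Per-exam time reduction is `100 * (time_without - time_with) /
#' time_without`, rounded to an integer; the headline mean reduction is the
#' mean of those rounded per-exam values (the aggregate-total formula is
#' also reported). First-attempt rate is the fraction of exams completed
#' with exactly one puncture. Experience-group means partition by the
#' `experienced` flag (> 3 years of practice).
#'
#' @param records data.frame from [read_study()].
#' @return List of class `study_summary`: `per_exam` (with reduction_pct),
#'   `mean_punctures_with`, `mean_punctures_without`, `mean_time_with_s`,
#'   `mean_time_without_s`, `mean_time_reduction_pct`,
#'   `aggregate_time_reduction_pct`, `first_attempt_with_pct`,
#'   `first_attempt_without_pct`, `reduction_experienced_pct`,
#'   `reduction_less_experienced_pct`.
#' @export
summarize_study <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("empty study")
  if (any(records$time_without <= 0)) stop("time_without must be positive")
  red <- round(100 * (records$time_without - records$time_with) /
                 records$time_without)
  per_exam <- cbind(records, reduction_pct = red)
  grp <- function(flag) if (!any(records$experienced == flag)) NA_real_
                        else round(mean(red[records$experienced == flag]))
  structure(list(
    per_exam = per_exam,
    mean_punctures_with = mean(records$punctures_with),
    mean_punctures_without = mean(records$punctures_without),
    mean_time_with_s = mean(records$time_with),
    mean_time_without_s = mean(records$time_without),
    mean_time_reduction_pct = round(mean(red)),
    aggregate_time_reduction_pct =
      round(100 * (sum(records$time_without) - sum(records$time_with)) /
              sum(records$time_without)),
    first_attempt_with_pct = 100 * mean(records$punctures_with == 1),
    first_attempt_without_pct = 100 * mean(records$punctures_without == 1),
    reduction_experienced_pct = grp(TRUE),
    reduction_less_experienced_pct = grp(FALSE)),
    class = "study_summary")
}

#' Load a simulator configuration from YAML
#'
#' YAML keys mirror the arguments of [sim_config()].
#'
#' @param path YAML path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sim_config, y)
}
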