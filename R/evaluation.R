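#' @title Subject-level evaluation statistics
#' @name evaluation
#' @description
#' Performance grouping, cohort score statistics and the subject-level
#' accuracy summaries derived from a prediction table (one row per subject
#' with the predicted labels of the rest and task segments).
NULL

#' Split a manifest into BAD and GOOD performers
#'
#' The threshold rule: subjects completing at most `threshold` subtraction
#' problems per minute are BAD performers, the rest GOOD. Original row
#' order is preserved within each group.
#'
#' @param manifest Data frame with `subject_id` and `X`.
#' @param threshold Problems-per-minute cut (default 10; X = 10 is BAD).
#' @return List with data frames `bad` and `good`.
#' @export
group_by_performance <- function(manifest, threshold = 10) {
  if (is.null(manifest) || nrow(manifest) == 0L)
    stop("empty manifest", call. = FALSE)
  is_bad <- manifest$X <= threshold
  list(bad = manifest[is_bad, , drop = FALSE],
       good = manifest[!is_bad, , drop = FALSE])
}

#' Mean and sample SD of a score vector
#'
#' Uses the n-1 (sample) divisor — the convention that reproduces the
#' published cohort statistics from the published score column. Note the
#' deliberate contrast with the 1/n divisor of the IMF features.
#'
#' @param values Numeric vector (n >= 2 for the SD).
#' @return Named vector `c(mean, sd)`.
#' @export
group_stats <- function(values) {
  if (length(values) < 2L)
    stop("sample SD undefined for fewer than 2 values", call. = FALSE)
  c(mean = mean(values), sd = stats::sd(values))
}

#' Summarise a subject-level prediction table
#'
#' @param table Data frame with `subject_id`, `pred_rest` and `pred_task`
#'   (labels `"class_1"` / `"class_2"`); `X` optional.
#' @return Object of class `evaluation_summary`: list with `n`,
#'   `both_class_accuracy`, `class1_accuracy`, `class2_accuracy`,
#'   `overall_accuracy` (all percent), and the counts `n_reversed`,
#'   `n_both_as_class1`, `n_both_as_class2`. Both-class accuracy is the
#'   fraction of subjects with rest and task both correct; overall accuracy
#'   is correct segment predictions over 2n.
#' @export
evaluate_prediction_table <- function(table) {
  if (is.null(table) || nrow(table) == 0L)
    stop("empty prediction table", call. = FALSE)
  labs <- c(table$pred_rest, table$pred_task)
  if (!all(labs %in% c("class_1", "class_2")))
    stop("unknown label in prediction table (expected class_1/class_2)",
         call. = FALSE)
  if (anyDuplicated(table$subject_id))
    stop("duplicate subject_id in prediction table", call. = FALSE)
  n <- nrow(table)
  rest_ok <- table$pred_rest == "class_1"
  task_ok <- table$pred_task == "class_2"
  both <- rest_ok & task_ok
  reversed <- !rest_ok & !task_ok & table$pred_rest == "class_2" &
    table$pred_task == "class_1"
  same <- table$pred_rest == table$pred_task
  structure(list(
    n = n,
    both_class_accuracy = 100 * mean(both),
    class1_accuracy = 100 * mean(rest_ok),
    class2_accuracy = 100 * mean(task_ok),
    overall_accuracy = 100 * (sum(rest_ok) + sum(task_ok)) / (2 * n),
    n_reversed = sum(reversed),
    n_both_as_class1 = sum(same & table$pred_rest == "class_1" & !both),
    n_both_as_class2 = sum(same & table$pred_rest == "class_2" & !both)),
    class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<evaluation_summary> n = %d\n",
    "  both-class accuracy : %6.2f%%\n",
    "  class 1 (rest)      : %6.2f%%\n",
    "  class 2 (task)      : %6.2f%%\n",
    "  overall             : %6.2f%%\n",
    "  reversed %d | both-as-class_1 %d | both-as-class_2 %d\n"),
    x$n, x$both_class_accuracy, x$class1_accuracy, x$class2_accuracy,
    x$overall_accuracy, x$n_reversed, x$n_both_as_class1, x$n_both_as_class2))
  invisible(x)
}
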