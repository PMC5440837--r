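# BiFC scoring: classify cells as Cy3/Venus positive at a fold-over-background
# threshold, normalize Venus intensities to a control group, and test group
# differences with Welch's ANOVA.

#' Classify BiFC records at a fold-over-background threshold
#'
#' A channel is positive iff its intensity strictly exceeds
#' `factor * background` (the per-cell background). Equality at exactly the
#' threshold is negative: the ">3.5x or <3.5x" rule leaves equality
#' unassigned, so strictness is made explicit and recorded.
#'
#' @param records data.frame with columns `background`, `cy3`, `venus`
#'   (`cell_id` and `group` carried through when present).
#' @param factor fold threshold (default 3.5).
#' @return `records` with logical columns `cy3_positive`, `venus_positive`
#'   added, and the threshold recorded in attribute `factor`.
#' @export
bifc_classify <- function(records, factor = 3.5) {
  req <- c("background", "cy3", "venus")
  if (!all(req %in% names(records)))
    stop_gd("records need columns: %s", paste(req, collapse = ", "),
            class = "groovedock_value_error")
  if (any(records$background <= 0))
    stop_gd("background must be > 0 for classification", class = "groovedock_value_error")
  records$cy3_positive <- records$cy3 > factor * records$background
  records$venus_positive <- records$venus > factor * records$background
  attr(records, "factor") <- factor
  records
}

#' Normalize Venus intensities to a control group
#'
#' Only Cy3-positive cells (bait-expressing) enter the analysis; each cell's
#' Venus intensity is divided by the mean Venus intensity of the Cy3-positive
#' control cells, so the control group's mean normalized intensity is 1 by
#' construction.
#'
#' @param records classified records (see [bifc_classify()]); unclassified
#'   records are classified with the default factor first.
#' @param control_group label of the control group.
#' @param factor fold threshold used if classification is still needed.
#' @return the Cy3-positive subset of `records` with a `venus_norm` column.
#' @export
normalize_to_control <- function(records, control_group, factor = 3.5) {
  if (is.null(records$cy3_positive)) records <- bifc_classify(records, factor)
  if (!"group" %in% names(records))
    stop_gd("records need a 'group' column", class = "groovedock_value_error")
  gated <- records[records$cy3_positive, , drop = FALSE]
  ctrl <- gated$venus[gated$group == control_group]
  if (length(ctrl) == 0)
    stop_gd("control group '%s' is empty after Cy3 gating", control_group,
            class = "groovedock_value_error")
  gated$venus_norm <- gated$venus / mean(ctrl)
  rownames(gated) <- NULL
  gated
}

#' Full BiFC scoring pipeline
#'
#' Gate on Cy3 positivity, normalize Venus to the control group, summarize
#' each group as mean +/- s.e.m., and compare groups with Welch's one-way
#' ANOVA.
#'
#' @param records data.frame (cell_id, group, background, cy3, venus).
#' @param control_group label of the control group.
#' @param factor fold-over-background threshold.
#' @return object of class `bifc_result` with `records` (gated, flagged,
#'   normalized), `group_table` (group, mean, sem, n of venus_norm), `test`
#'   (Welch ANOVA across groups) and `factor`.
#' @export
bifc_pipeline <- function(records, control_group, factor = 3.5) {
  gated <- normalize_to_control(bifc_classify(records, factor), control_group)
  groups <- split(gated$venus_norm, gated$group)
  if (length(groups) < 2)
    stop_gd("need at least 2 groups after Cy3 gating", class = "groovedock_value_error")
  tab <- do.call(rbind, lapply(names(groups), function(g) {
    ms <- mean_sem(groups[[g]])
    data.frame(group = g, mean = ms[["mean"]], sem = ms[["sem"]], n = ms[["n"]],
               stringsAsFactors = FALSE)
  }))
  structure(list(records = gated, group_table = tab,
                 test = welch_anova(groups), factor = factor),
            class = "bifc_result")
}

#' @export
print.bifc_result <- function(x, ...) {
  cat(sprintf("<bifc_result> %d Cy3-positive cells, %d groups (threshold %.1fx background)\n",
              nrow(x$records), nrow(x$group_table), x$factor))
  print(x$group_table)
  print(x$test)
  invisible(x)
}
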