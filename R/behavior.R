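#' Pooled-variance independent-samples t-test from group summaries
#'
#' Computes the Student (pooled-variance) two-sample t statistic from group
#' means, SDs and sizes:
#' `t = (m1 - m2) / sqrt(sp2 * (1/n1 + 1/n2))` with
#' `sp2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2`. The pooled form (rather than Welch) matches reports
#' quoting df = n1 + n2 - 2. Two groups with zero pooled variance and equal
#' means give t = 0.
#'
#' @param mean1,sd1,n1 First group's mean, SD and size.
#' @param mean2,sd2,n2 Second group's mean, SD and size.
#' @return A one-row tibble: `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' t_from_summary(3.53, 0.80, 33, 2.40, 0.90, 33)
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) {
    stop("Each group needs at least 2 observations.", call. = FALSE)
  }
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative.", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) {
    if (mean1 == mean2) 0 else stop(
      "Zero pooled variance with unequal means: t is infinite.",
      call. = FALSE)
  } else {
    (mean1 - mean2) / se
  }
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Summarize the purchase-count table
#'
#' Per-task totals and means across subjects, per-category sums and SDs of
#' the per-subject counts, and pooled t-tests comparing the two tasks — the
#' behavioral analysis of how many items subjects bought with and without
#' the promotion. The per-category SD is the SD of per-subject counts (the
#' sum's companion spread); both are reported since a printed "sum +/- SD"
#' pair does not pin the SD definition down.
#'
#' @param behavior Tibble from [simulate_behavior()] (columns `subject`,
#'   `condition`, `category`, `count`, counts 0..4).
#' @return A list of class `"upb_behavior_summary"`: `totals` (per-subject
#'   task totals), `task_summary` (per-task mean/SD of totals plus their
#'   pooled t-test columns `t`, `df`, `p` on the Task1 row),
#'   `category_summary` (per category and task: `sum`, `sd_count`, and the
#'   per-category pooled t-test), `t_total` (the task-total t-test tibble).
#' @export
purchase_summary <- function(behavior) {
  required <- c("subject", "condition", "category", "count")
  stopifnot(all(required %in% names(behavior)))
  if (any(behavior$count < 0 | behavior$count > 4)) {
    stop("Purchase counts must lie in 0..4.", call. = FALSE)
  }
  totals <- dplyr::summarise(
    dplyr::group_by(behavior, .data$subject, .data$condition),
    total = sum(.data$count), .groups = "drop"
  )
  task_summary <- dplyr::summarise(
    dplyr::group_by(totals, .data$condition),
    mean_total = mean(.data$total),
    sd_total = stats::sd(.data$total),
    n = dplyr::n(), .groups = "drop"
  )
  s1 <- task_summary[task_summary$condition == "Task1", ]
  s2 <- task_summary[task_summary$condition == "Task2", ]
  t_total <- if (nrow(s1) == 1L && nrow(s2) == 1L &&
                 (s1$sd_total > 0 || s2$sd_total > 0 ||
                    s1$mean_total == s2$mean_total)) {
    t_from_summary(s1$mean_total, s1$sd_total, s1$n,
                   s2$mean_total, s2$sd_total, s2$n)
  } else {
    tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_)
  }
  t_total$degenerate <- nrow(s1) == 1L && nrow(s2) == 1L &&
    s1$sd_total == 0 && s2$sd_total == 0

  category_summary <- dplyr::summarise(
    dplyr::group_by(behavior, .data$category, .data$condition),
    sum = sum(.data$count),
    sd_count = stats::sd(.data$count),
    mean_count = mean(.data$count),
    n = dplyr::n(), .groups = "drop"
  )
  cat_t <- dplyr::group_by(behavior, .data$category) |>
    dplyr::group_modify(function(df, key) {
      g1 <- df$count[df$condition == "Task1"]
      g2 <- df$count[df$condition == "Task2"]
      if (stats::sd(g1) == 0 && stats::sd(g2) == 0 &&
          mean(g1) != mean(g2)) {
        return(tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                              degenerate = TRUE))
      }
      res <- t_from_summary(mean(g1), stats::sd(g1), length(g1),
                            mean(g2), stats::sd(g2), length(g2))
      res$degenerate <- stats::sd(g1) == 0 && stats::sd(g2) == 0
      res
    }) |> dplyr::ungroup()

  structure(list(totals = totals, task_summary = task_summary,
                 t_total = t_total, category_summary = category_summary,
                 category_tests = cat_t),
            class = "upb_behavior_summary")
}

#' Summarize the self-report Likert table
#'
#' Per subject and condition, the score is the mean of the three 1..5
#' items; the two conditions are then compared by group mean/SD and the
#' pooled t-test (the conditions are treated as independent groups,
#' following the source analysis convention, despite the within-subject
#' design).
#'
#' @param likert Tibble from [simulate_likert()] (columns `subject`,
#'   `condition`, `item`, `response`, responses 1..5).
#' @return A list of class `"upb_likert_summary"`: `scores` (per-subject
#'   per-condition item means), `condition_summary` (mean, sd, sem, n per
#'   condition), `t_test` (pooled t tibble).
#' @export
likert_summary <- function(likert) {
  required <- c("subject", "condition", "item", "response")
  stopifnot(all(required %in% names(likert)))
  if (any(likert$response < 1 | likert$response > 5)) {
    stop("Likert responses must lie in 1..5.", call. = FALSE)
  }
  scores <- dplyr::summarise(
    dplyr::group_by(likert, .data$subject, .data$condition),
    score = mean(.data$response), .groups = "drop"
  )
  condition_summary <- dplyr::summarise(
    dplyr::group_by(scores, .data$condition),
    mean = mean(.data$score), sd = stats::sd(.data$score),
    sem = stats::sd(.data$score) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop"
  )
  s1 <- condition_summary[condition_summary$condition == "Task1", ]
  s2 <- condition_summary[condition_summary$condition == "Task2", ]
  t_test <- t_from_summary(s1$mean, s1$sd, s1$n, s2$mean, s2$sd, s2$n)
  structure(list(scores = scores, condition_summary = condition_summary,
                 t_test = t_test),
            class = "upb_likert_summary")
}
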