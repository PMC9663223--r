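#' Confusion counts for a binary prediction
#'
#' Tallies TP/FP/TN/FN with Task 1 (unplanned purchase) as the positive
#' class: TP counts unplanned purchases correctly flagged as such, FP
#' counts control trials misflagged as unplanned purchases.
#'
#' @param truth,pred Character/factor vectors of `"Task1"`/`"Task2"`.
#' @param positive Positive class label.
#' @return A list of class `"upb_confusion"` with `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion_counts(c("Task1", "Task1", "Task2"), c("Task1", "Task2", "Task2"))
confusion_counts <- function(truth, pred, positive = "Task1") {
  stopifnot(length(truth) == length(pred))
  t_pos <- truth == positive
  p_pos <- pred == positive
  structure(list(tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
                 tn = sum(!t_pos & !p_pos), fn = sum(t_pos & !p_pos)),
            class = "upb_confusion")
}

#' True- and false-positive rates
#'
#' `tpr()` is the fraction of actual unplanned purchases judged as such,
#' `TP / (TP + FN)`; `fpr()` is the fraction of control trials misjudged as
#' unplanned purchases, `FP / (FP + TN)`. A zero denominator is an error,
#' never a silent 0.
#'
#' @param counts An `"upb_confusion"` (or list with `tp`, `fp`, `tn`, `fn`).
#' @return A rate in \[0, 1\].
#' @export
#' @examples
#' tpr(confusion_counts(rep(c("Task1", "Task2"), 5),
#'                      rep(c("Task1", "Task2"), 5)))
tpr <- function(counts) {
  den <- counts$tp + counts$fn
  if (den == 0) stop("TPR undefined: no positive-class samples.",
                     call. = FALSE)
  counts$tp / den
}

#' @rdname tpr
#' @export
fpr <- function(counts) {
  den <- counts$fp + counts$tn
  if (den == 0) stop("FPR undefined: no negative-class samples.",
                     call. = FALSE)
  counts$fp / den
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps a threshold over the unique decision values, tallying (FPR, TPR)
#' at each, and integrates the area under the curve by the trapezoidal
#' rule. Tied scores move TP and FP simultaneously, producing the diagonal
#' segments of the Mann-Whitney-consistent convention, so the AUC equals
#' the pairwise ranking probability `P(score+ > score-) + 0.5 P(tie)`.
#'
#' @param scores Numeric decision values; larger favors the positive class.
#' @param labels `"Task1"`/`"Task2"` (or any two labels with `positive`
#'   naming the positive one).
#' @param positive Positive class label.
#' @return An `"upb_roc"`: list with `points` (tibble `threshold`, `fpr`,
#'   `tpr`, from (0,0) to (1,1)) and `auc`.
#' @export
#' @examples
#' roc_auc(c(3, 2, 1, 0), c("Task1", "Task1", "Task2", "Task2"))$auc
roc_auc <- function(scores, labels, positive = "Task1") {
  stopifnot(length(scores) == length(labels))
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes in `labels`.", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- is_pos[ord]
  # one step per unique score (ties collapse into a single diagonal step)
  last_of_run <- c(diff(s) != 0, TRUE)
  tp <- cumsum(pos)[last_of_run]
  fp <- cumsum(!pos)[last_of_run]
  points <- tibble::tibble(
    threshold = c(Inf, s[last_of_run]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "upb_roc")
}

#' @export
print.upb_roc <- function(x, ...) {
  cat("<upb_roc> ", nrow(x$points), " points, AUC = ",
      sprintf("%.4f", x$auc), "\n", sep = "")
  invisible(x)
}

# round-half-up at `digits`, matching how the report tables are printed
# (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Aggregate per-subject AUC values into a reliability report
#'
#' Produces the per-subject AUC table plus its summary: mean, sample SD,
#' SEM (= SD / sqrt(n)), minimum and maximum, each also rounded half-up to
#' two decimals for display — the layout of a published per-subject AUC
#' reliability table.
#'
#' @param auc_values Numeric vector of per-subject AUCs in \[0, 1\].
#' @param subjects Optional subject identifiers.
#' @return An `"upb_auc_report"`: list with `subjects` (tibble `subject`,
#'   `auc`, `auc_2dec`) and `summary` (tibble `stat`, `value`, `value_2dec`
#'   for mean, sd, sem, min, max).
#' @export
#' @examples
#' auc_report(c(0.9, 1.0, 0.95))$summary
auc_report <- function(auc_values, subjects = seq_along(auc_values)) {
  stopifnot(length(auc_values) >= 1L, all(auc_values >= 0 & auc_values <= 1))
  n <- length(auc_values)
  sd_v <- if (n > 1L) stats::sd(auc_values) else 0
  summ <- tibble::tibble(
    stat = c("mean", "sd", "sem", "min", "max"),
    value = c(mean(auc_values), sd_v, sd_v / sqrt(n),
              min(auc_values), max(auc_values))
  )
  summ$value_2dec <- round_half_up(summ$value, 2)
  structure(
    list(subjects = tibble::tibble(subject = subjects, auc = auc_values,
                                   auc_2dec = round_half_up(auc_values, 2)),
         summary = summ),
    class = "upb_auc_report"
  )
}

#' @export
print.upb_auc_report <- function(x, ...) {
  s <- x$summary
  cat("<upb_auc_report> ", nrow(x$subjects), " subject(s): mean AUC ",
      sprintf("%.2f (SD %.2f, range %.2f-%.2f)",
              s$value_2dec[s$stat == "mean"], s$value_2dec[s$stat == "sd"],
              s$value_2dec[s$stat == "min"], s$value_2dec[s$stat == "max"]),
      "\n", sep = "")
  invisible(x)
}
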