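#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-iteration accuracies of a cross-validation result
#'
#' @param x An `"upb_cv"`.
#' @param ... Unused.
#' @return Tibble `iteration`, `accuracy`.
#' @export
tidy.upb_cv <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$accuracy), accuracy = x$accuracy)
}

#' One-row summary of a cross-validation result
#'
#' @param x An `"upb_cv"`.
#' @param ... Unused.
#' @return Tibble `accuracy_mean`, `accuracy_sd`, `accuracy_sem`,
#'   `n_iterations`, `scheme`.
#' @export
glance.upb_cv <- function(x, ...) {
  tibble::tibble(accuracy_mean = x$mean, accuracy_sd = x$sd,
                 accuracy_sem = x$sem, n_iterations = x$repeats,
                 scheme = x$scheme)
}

#' Tidy the points of an ROC curve
#'
#' @param x An `"upb_roc"`.
#' @param ... Unused.
#' @return Tibble `threshold`, `fpr`, `tpr`.
#' @export
tidy.upb_roc <- function(x, ...) x$points

#' One-row summary of an ROC curve
#'
#' @param x An `"upb_roc"`.
#' @param ... Unused.
#' @return Tibble `auc`, `n_pos`, `n_neg`.
#' @export
glance.upb_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy the per-subject rows of an accuracy report
#'
#' @param x An `"upb_report"`.
#' @param ... Unused.
#' @export
tidy.upb_report <- function(x, ...) x$subjects

#' Grand-mean row of an accuracy report
#'
#' @param x An `"upb_report"`.
#' @param ... Unused.
#' @export
glance.upb_report <- function(x, ...) x$grand

#' Tidy the per-subject rows of an AUC reliability report
#'
#' @param x An `"upb_auc_report"`.
#' @param ... Unused.
#' @export
tidy.upb_auc_report <- function(x, ...) x$subjects

#' Summary statistics of an AUC reliability report, one row
#'
#' @param x An `"upb_auc_report"`.
#' @param ... Unused.
#' @export
glance.upb_auc_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary[c("stat", "value")], names_from = "stat",
                     values_from = "value")
}
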