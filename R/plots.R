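#' Plot an ROC curve
#'
#' @param object An `"upb_roc"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.upb_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("ROC (AUC = %.2f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot per-subject classification accuracies with SEM bars
#'
#' Per-subject bars plus the grand-average bar "A", with the readiness
#' threshold drawn as a horizontal line.
#'
#' @param report An `"upb_report"` from [per_subject_report()].
#' @param threshold Detection threshold drawn as a reference line.
#' @return A ggplot.
#' @export
plot_accuracy <- function(report, threshold = 0.80) {
  stopifnot(inherits(report, "upb_report"))
  df <- dplyr::bind_rows(
    report$subjects[c("subject", "accuracy_mean", "accuracy_sem")],
    tibble::tibble(subject = "A",
                   accuracy_mean = report$grand$accuracy_mean,
                   accuracy_sem = report$grand$accuracy_sem)
  )
  df$subject <- factor(df$subject, levels = df$subject)
  ggplot2::ggplot(df, ggplot2::aes(.data$subject, 100 * .data$accuracy_mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * (.data$accuracy_mean - .data$accuracy_sem),
                   ymax = 100 * (.data$accuracy_mean + .data$accuracy_sem)),
      width = 0.3, colour = "red") +
    ggplot2::geom_hline(yintercept = 100 * threshold, linetype = "dotted") +
    ggplot2::labs(x = "Subject", y = "Classification accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Plot grand-average epoch waveforms per ROI and condition
#'
#' The mean baseline-corrected HbO time course over each region's epochs,
#' one panel per ROI — the time-domain view of the activation contrast.
#'
#' @param epochs Baseline-corrected `"upb_epochs"`.
#' @param layout Montage; defaults to the layout carried by the epochs.
#' @return A ggplot.
#' @export
plot_epoch_means <- function(epochs, layout = attr(epochs, "layout")) {
  stopifnot(inherits(epochs, "upb_epochs"))
  df <- tibble::as_tibble(epochs) |>
    dplyr::left_join(layout[c("channel", "roi")], by = "channel") |>
    dplyr::group_by(.data$roi, .data$condition, .data$t) |>
    dplyr::summarise(hbo = mean(.data$hbo), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$hbo,
                                   colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "Time from task onset (s)",
                  y = expression(Delta * "HbO (" * mu * "M)"),
                  colour = "Condition") +
    ggplot2::theme_minimal()
}
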