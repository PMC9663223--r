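#' Run the full per-subject analysis for one recording
#'
#' The fixed stage order: band-pass the optical density (0.01-0.1 Hz,
#' zero-phase), convert to hemoglobin via the modified Beer-Lambert law,
#' epoch -1..60 s around task onsets, baseline-correct on \[-1, 0) s, build
#' the 6-feature matrix (one row per channel x trial), and run repeated
#' stratified cross-validation of the linear SVM with per-split min-max
#' rescaling.
#'
#' @param rec An `"upb_recording"`.
#' @param cv_repeats,cv_seed Passed to [cross_validate()].
#' @param mbll Beer-Lambert constants.
#' @return A list: `features`, `cv` (an `"upb_cv"`), `roc` (pooled held-out
#'   scores), `roi` (ROI mean table), `verdict`.
#' @export
analyze_recording <- function(rec, cv_repeats = 30, cv_seed = 1L,
                              mbll = mbll_params()) {
  epochs <- rec |>
    bandpass() |>
    od_to_hemoglobin(mbll = mbll) |>
    epoch_hemo() |>
    baseline_correct()
  features <- build_feature_matrix(epochs)
  cv <- cross_validate(features, repeats = cv_repeats, seed = cv_seed)
  roc <- roc_auc(cv$scores$score, cv$scores$truth)
  list(features = features, cv = cv, roc = roc,
       roi = roi_means(epochs), verdict = detection_verdict(cv$mean))
}

#' Run the whole study pipeline on simulated subjects
#'
#' Simulates `n_subjects` recordings plus the behavioral and self-report
#' tables, runs the per-subject analysis ([analyze_recording()]) on each,
#' and aggregates: the per-subject accuracy report, the per-subject AUC
#' reliability table, ROI activation means, behavioral statistics, and the
#' detection verdicts. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of subjects to run (defaults to
#'   `config$n_subjects`).
#' @param cv_repeats Held-out evaluations per subject.
#' @return An `"upb_results"` list: `accuracy` (an `"upb_report"`),
#'   `auc` (an `"upb_auc_report"`), `roi` (tibble pooled over subjects),
#'   `behavior` (an `"upb_behavior_summary"`), `likert`
#'   (an `"upb_likert_summary"`), `verdicts` (tibble with one row per
#'   subject), `seed`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(n_subjects = 2, seed = 7))
#' res$accuracy$grand
#' }
run_pipeline <- function(config, n_subjects = config$n_subjects,
                         cv_repeats = 30) {
  validate_config(config)
  per_subject <- purrr::map(seq_len(n_subjects), function(s) {
    analyze_recording(simulate_recording(config, s),
                      cv_repeats = cv_repeats,
                      cv_seed = subject_seed(config, s))
  })
  names(per_subject) <- sprintf("S%02d", seq_len(n_subjects))

  report <- per_subject_report(purrr::map(per_subject, "cv"))
  aucs <- purrr::map_dbl(per_subject, function(x) x$roc$auc)
  auc_rep <- auc_report(aucs, subjects = names(per_subject))
  roi <- purrr::imap(per_subject, function(x, nm) {
    dplyr::mutate(x$roi, subject = nm)
  }) |> purrr::list_rbind() |>
    dplyr::group_by(.data$roi, .data$condition) |>
    dplyr::summarise(mean_hbo = mean(.data$mean_hbo), .groups = "drop")
  verdicts <- purrr::imap(per_subject, function(x, nm) {
    dplyr::mutate(x$verdict, subject = nm, .before = 1)
  }) |> purrr::list_rbind()

  structure(
    list(accuracy = report, auc = auc_rep, roi = roi,
         behavior = purchase_summary(simulate_behavior(config)),
         likert = likert_summary(simulate_likert(config)),
         verdicts = verdicts,
         per_subject = per_subject,
         seed = config$seed),
    class = "upb_results"
  )
}

#' @export
print.upb_results <- function(x, ...) {
  cat("<upb_results> ", nrow(x$accuracy$subjects), " subject(s)\n", sep = "")
  cat("  grand accuracy: ",
      sprintf("%.2f%% +/- %.2f%% (SEM)",
              100 * x$accuracy$grand$accuracy_mean,
              100 * x$accuracy$grand$accuracy_sem), "\n", sep = "")
  s <- x$auc$summary
  cat("  mean AUC: ", sprintf("%.2f", s$value_2dec[s$stat == "mean"]),
      "  READY: ", sum(x$verdicts$status == "READY"), "/",
      nrow(x$verdicts), "\n", sep = "")
  invisible(x)
}
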