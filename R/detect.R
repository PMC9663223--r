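#' Detection verdict from a classification accuracy
#'
#' The deployment rule of the analysis: a subject's classifier is ready to
#' detect unplanned-purchase patterns only if its accuracy strictly exceeds
#' the 80% threshold ("exceeds" is read strictly, so exactly 0.80 is
#' NOT_READY).
#'
#' @param accuracy Classification accuracy as a fraction in \[0, 1\].
#' @param threshold Readiness threshold (fraction), default 0.80.
#' @return A one-row tibble: `status` (`"READY"`/`"NOT_READY"`), `accuracy`,
#'   `threshold`, `message`.
#' @export
#' @examples
#' detection_verdict(0.8642)$status
#' detection_verdict(0.80)$status
detection_verdict <- function(accuracy, threshold = 0.80) {
  if (!is.numeric(accuracy) || length(accuracy) != 1L ||
      is.na(accuracy) || accuracy < 0 || accuracy > 1) {
    stop("`accuracy` must be a single fraction in [0, 1].", call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must be in [0, 1].", call. = FALSE)
  }
  ready <- accuracy > threshold
  tibble::tibble(
    status = if (ready) "READY" else "NOT_READY",
    accuracy = accuracy,
    threshold = threshold,
    message = if (ready) {
      sprintf("Ready to detect unplanned purchase patterns (accuracy %.2f%% > %.0f%%).",
              100 * accuracy, 100 * threshold)
    } else {
      sprintf("Cannot detect unplanned purchase patterns (accuracy %.2f%% <= %.0f%%).",
              100 * accuracy, 100 * threshold)
    }
  )
}
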