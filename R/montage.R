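#' Default 15-channel prefrontal montage
#'
#' The probe layout assumed throughout the package: 15 source-detector
#' channels formed from 5 sources and 7 detectors arranged symmetrically
#' across the forehead at 3 cm separation, grouped into five regions of
#' interest (ROIs): dorsolateral prefrontal cortex (`DLPFC`), left and right
#' ventrolateral prefrontal cortex (`VLPFC_L`, `VLPFC_R`), medial prefrontal
#' cortex (`mPFC`) and orbitofrontal cortex (`OFC`).
#'
#' @param separation_cm Source-detector separation in cm (> 0).
#' @return A tibble with one row per channel and columns `channel`
#'   (`"ch01"`..`"ch15"`), `source` (1..5), `detector` (1..7), `roi`, and
#'   `separation_cm`.
#' @export
#' @examples
#' default_montage()
default_montage <- function(separation_cm = 3.0) {
  if (!is.numeric(separation_cm) || length(separation_cm) != 1L ||
      !is.finite(separation_cm) || separation_cm <= 0) {
    stop("`separation_cm` must be a single positive number.", call. = FALSE)
  }
  tibble::tibble(
    channel = sprintf("ch%02d", 1:15),
    source = rep(1:5, each = 3L),
    detector = c(1L, 2L, 3L, 2L, 3L, 4L, 3L, 4L, 5L, 4L, 5L, 6L, 5L, 6L, 7L),
    roi = c(
      "DLPFC", "DLPFC", "VLPFC_L", "VLPFC_L", "OFC",
      "mPFC", "mPFC", "OFC", "OFC", "mPFC",
      "OFC", "VLPFC_R", "VLPFC_R", "DLPFC", "DLPFC"
    ),
    separation_cm = separation_cm
  )
}

rois <- function() c("DLPFC", "VLPFC_L", "VLPFC_R", "mPFC", "OFC")

validate_montage <- function(layout) {
  required <- c("channel", "source", "detector", "roi", "separation_cm")
  missing <- setdiff(required, names(layout))
  if (length(missing) > 0L) {
    stop("Montage is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(layout) != 15L) {
    stop("Montage must have exactly 15 channels, got ", nrow(layout), ".",
         call. = FALSE)
  }
  if (anyDuplicated(layout$channel)) {
    stop("Montage channel ids must be unique.", call. = FALSE)
  }
  if (!all(layout$roi %in% rois())) {
    bad <- setdiff(unique(layout$roi), rois())
    stop("Unknown ROI label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(layout$separation_cm <= 0)) {
    stop("Source-detector separation must be positive.", call. = FALSE)
  }
  invisible(layout)
}
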