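#' Simulation configuration
#'
#' Bundles every parameter of the synthetic fNIRS study: block-design timing,
#' sampling, per-ROI hemodynamic response amplitudes for the two task
#' conditions, physiological noise amplitudes, behavioral and Likert response
#' distributions, and the root random seed. Defaults reproduce the paradigm
#' the analysis assumes: a 1 s trial cue, 25 s task, 30 s rest, 5 trials per
#' task, two tasks (Task 1 with the BOGOF promotion eliciting unplanned
#' purchases, Task 2 without), recorded at 8.138 Hz over the 15-channel
#' prefrontal montage.
#'
#' @details
#' `roi_amplitudes` is a named list `list(Task1 = c(...), Task2 = c(...))`
#' giving the peak oxygenated-hemoglobin response (micromolar) per ROI. The
#' defaults encode the qualitative activation contrast assumed as simulation
#' ground truth: Task 1 activates only the left VLPFC; Task 2 activates OFC
#' strongly and mPFC/VLPFC moderately, with near-silent DLPFC.
#'
#' Noise amplitudes are in optical-density units. Cardiac (~1.0 Hz),
#' respiratory (~0.3 Hz) and Mayer-wave (~0.1 Hz) components are sinusoids
#' with per-channel random phase and jittered frequency; `drift` scales a
#' 1/f-weighted sum of very-low-frequency sinusoids; `white` is the standard
#' deviation of additive Gaussian noise per sample. At the default modified
#' Beer-Lambert constants a 0.5 micromolar HbO response maps to roughly
#' 0.01 OD, so the defaults correspond to single-digit-milli-OD physiological
#' noise.
#'
#' Trials are spaced `cue_s + task_s + rest_s + iti_extra_s` apart
#' onset-to-onset (default 61 s) so that the -1..60 s analysis epoch of one
#' trial never overlaps the next.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_trials_per_task Trials per task condition.
#' @param cue_s,task_s,rest_s Trial-phase durations in seconds.
#' @param iti_extra_s Extra inter-trial rest (s) appended so that
#'   onset-to-onset spacing accommodates the 60 s post-onset epoch.
#' @param pre_s Lead-in rest (s) recorded before the first trial cue; long
#'   enough (default 75 s) that the first epoch stays clear of the
#'   band-pass filter's warm-up region.
#' @param tail_s Trailing rest (s) recorded after the last epoch window,
#'   keeping the final epoch clear of the filter's edge region.
#' @param layout Channel montage tibble, see [default_montage()].
#' @param roi_amplitudes Named list of per-ROI peak HbO amplitudes
#'   (micromolar) for `Task1` and `Task2`.
#' @param hrf_params Double-gamma hemodynamic response parameters
#'   (`peak_s`, `undershoot_s`, `ratio`).
#' @param noise Named numeric vector of noise amplitudes (OD units):
#'   `cardiac`, `respiratory`, `mayer`, `drift`, `white`.
#' @param behavior_p Named per-condition success probability for purchase
#'   counts: each of 5 clothing categories is a binomial(4, p) draw, so a
#'   task total ranges 0..20.
#' @param likert_mean,likert_sd Named per-condition mean and SD of the
#'   latent normal behind the 1..5 Likert items (3 items per condition).
#' @param seed Root random seed (integer). Subject `i` draws from a child
#'   stream seeded `(seed + 7919 * i) mod (2^31 - 1)`.
#' @return A list of class `"upb_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, seed = 1)
#' cfg$sampling_rate
sim_config <- function(n_subjects = 33,
                       sampling_rate = 8.138,
                       n_trials_per_task = 5,
                       cue_s = 1,
                       task_s = 25,
                       rest_s = 30,
                       iti_extra_s = 5,
                       pre_s = 75,
                       tail_s = 75,
                       layout = default_montage(),
                       roi_amplitudes = list(
                         Task1 = c(DLPFC = 0, VLPFC_L = 0.2, VLPFC_R = 0,
                                   mPFC = 0, OFC = 0),
                         Task2 = c(DLPFC = 0.35, VLPFC_L = 0.75,
                                   VLPFC_R = 0.7, mPFC = 0.7, OFC = 0.9)
                       ),
                       hrf_params = c(peak_s = 6, undershoot_s = 16,
                                      ratio = 6),
                       noise = c(cardiac = 0.004, respiratory = 0.003,
                                 mayer = 0.001, drift = 0.002,
                                 white = 0.001),
                       behavior_p = c(Task1 = 0.3335, Task2 = 0.168),
                       likert_mean = c(Task1 = 3.53, Task2 = 2.40),
                       likert_sd = c(Task1 = 0.80, Task2 = 0.90),
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    sampling_rate = sampling_rate,
    n_trials_per_task = as.integer(n_trials_per_task),
    cue_s = cue_s, task_s = task_s, rest_s = rest_s,
    iti_extra_s = iti_extra_s, pre_s = pre_s, tail_s = tail_s,
    layout = layout,
    roi_amplitudes = roi_amplitudes,
    hrf_params = hrf_params,
    noise = noise,
    behavior_p = behavior_p,
    likert_mean = likert_mean,
    likert_sd = likert_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "upb_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "upb_config"))
  durs <- c(cfg$sampling_rate, cfg$cue_s, cfg$task_s, cfg$rest_s, cfg$pre_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("Durations and sampling rate must be positive and finite.",
         call. = FALSE)
  }
  if (cfg$iti_extra_s < 0 || cfg$tail_s < 0) {
    stop("`iti_extra_s` and `tail_s` must be non-negative.", call. = FALSE)
  }
  if (cfg$n_subjects < 1L || cfg$n_trials_per_task < 1L) {
    stop("`n_subjects` and `n_trials_per_task` must be at least 1.",
         call. = FALSE)
  }
  validate_montage(cfg$layout)
  for (cond in c("Task1", "Task2")) {
    amps <- cfg$roi_amplitudes[[cond]]
    if (is.null(amps)) {
      stop("`roi_amplitudes` must contain an entry for ", cond, ".",
           call. = FALSE)
    }
    missing <- setdiff(rois(), names(amps))
    if (length(missing) > 0L) {
      stop("`roi_amplitudes$", cond, "` is missing ROI(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  needed <- c("cardiac", "respiratory", "mayer", "drift", "white")
  if (!all(needed %in% names(cfg$noise))) {
    stop("`noise` must name amplitudes: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(cfg$noise < 0)) stop("Noise amplitudes must be >= 0.", call. = FALSE)
  p <- cfg$behavior_p[c("Task1", "Task2")]
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("`behavior_p` must give Task1/Task2 probabilities in [0, 1].",
         call. = FALSE)
  }
  m <- cfg$likert_mean[c("Task1", "Task2")]
  if (any(is.na(m)) || any(m < 1) || any(m > 5)) {
    stop("`likert_mean` must give Task1/Task2 means within the 1..5 scale.",
         call. = FALSE)
  }
  if (any(cfg$likert_sd[c("Task1", "Task2")] < 0)) {
    stop("`likert_sd` must be >= 0.", call. = FALSE)
  }
  cfg
}

# Documented stream-splitting rule: one root seed, one child seed per
# subject (and one for behavioral tables, subject index 0).
subject_seed <- function(cfg, subject_index) {
  as.integer((as.numeric(cfg$seed) + 7919 * as.numeric(subject_index)) %%
               2147483647)
}

#' @export
print.upb_config <- function(x, ...) {
  cat("<upb_config>\n")
  cat("  subjects:", x$n_subjects,
      " trials/task:", x$n_trials_per_task,
      " fs:", x$sampling_rate, "Hz\n")
  cat("  trial: cue", x$cue_s, "s + task", x$task_s, "s + rest",
      x$rest_s + x$iti_extra_s, "s (onset-to-onset",
      x$cue_s + x$task_s + x$rest_s + x$iti_extra_s, "s)\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
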