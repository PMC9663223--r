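#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma impulse response used in hemodynamic modelling:
#' a positive gamma peaking near 6 s minus a scaled gamma undershoot
#' peaking near 16 s.
#'
#' @param t Time points (s), `t >= 0`.
#' @param peak_s Time-to-peak of the positive lobe (s).
#' @param undershoot_s Time-to-peak of the undershoot (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector of the response at `t`, peak-normalized to 1.
#' @export
#' @examples
#' h <- hrf_double_gamma(seq(0, 32, by = 0.5))
#' which.max(h)
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16, ratio = 6) {
  stopifnot(all(t >= 0), peak_s > 0, undershoot_s > 0, ratio > 0)
  # gamma densities with scale 1 peak at shape-1 = time-to-peak
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot_s + 1, rate = 1) / ratio
  h / max(h)
}

# Per-trial boxcar convolved with the HRF, normalized so a single task
# block reaches peak 1 (roi amplitudes are then literal peak microns).
convolved_regressor <- function(onsets, duration, n, fs, hrf_params) {
  box <- numeric(n)
  for (on in onsets) {
    i0 <- floor(on * fs) + 1L
    i1 <- min(n, floor((on + duration) * fs))
    if (i0 <= n) box[i0:max(i0, i1)] <- 1
  }
  tk <- seq(0, 32, by = 1 / fs)
  h <- hrf_double_gamma(tk, hrf_params[["peak_s"]],
                        hrf_params[["undershoot_s"]], hrf_params[["ratio"]])
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n)]
  ref_len <- floor(duration * fs) + length(h)
  ref <- stats::convolve(c(rep(1, floor(duration * fs)),
                           numeric(length(h))),
                         rev(h), type = "open")[seq_len(ref_len)]
  conv / max(ref)
}

recording_duration_s <- function(cfg) {
  spacing <- cfg$cue_s + cfg$task_s + cfg$rest_s + cfg$iti_extra_s
  n_trials <- 2L * cfg$n_trials_per_task
  cfg$pre_s + cfg$cue_s + n_trials * spacing + cfg$tail_s
}

#' Simulate one subject's dual-wavelength fNIRS recording
#'
#' Builds a block-design recording for one subject: per condition, a boxcar
#' over the task intervals is convolved with the double-gamma hemodynamic
#' response and scaled per channel by the configured ROI amplitude; the
#' resulting HbO series (with HbR = -1/3 HbO plus independent noise) is
#' pushed through the forward Beer-Lambert model to dual-wavelength optical
#' density, and sinusoidal physiological components (cardiac, respiratory,
#' Mayer waves) with per-channel random phases, 1/f-like drift, and white
#' noise are added in the OD domain. Task 1 trials come first, then Task 2.
#'
#' @param config A [sim_config()] object.
#' @param subject_index Subject number (1-based); selects the per-subject
#'   random stream, so recordings are deterministic given
#'   `(config$seed, subject_index)`.
#' @param mbll Forward-model constants, see [mbll_params()]. Must match the
#'   constants later used for inversion if exact recovery is wanted.
#' @return An object of class `"upb_recording"`: a list with `od` (tibble:
#'   `time_s`, `ch01_wl780`..`ch15_wl780`, `ch01_wl850`..`ch15_wl850`),
#'   `events` (tibble: `onset`, `duration`, `condition`), `layout`,
#'   `sampling_rate`, and `filtered = FALSE`. The attribute `ground_truth`
#'   holds the trial labels, the channel-to-ROI map, the programmed
#'   amplitudes, and the noise-free HbO/HbR matrices (micromolar).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 1, seed = 42)
#' rec <- simulate_recording(cfg, 1)
#' nrow(rec$events)
simulate_recording <- function(config, subject_index,
                               mbll = mbll_params()) {
  validate_config(config)
  fs <- config$sampling_rate
  dur <- recording_duration_s(config)
  n <- floor(dur * fs)
  time_s <- (seq_len(n) - 1L) / fs
  spacing <- config$cue_s + config$task_s + config$rest_s + config$iti_extra_s
  n_trials <- 2L * config$n_trials_per_task
  # task onset = end of the 1 s cue
  onsets <- config$pre_s + config$cue_s + (seq_len(n_trials) - 1L) * spacing
  conditions <- rep(c("Task1", "Task2"), each = config$n_trials_per_task)
  events <- tibble::tibble(onset = onsets,
                           duration = config$task_s,
                           condition = conditions)

  regress <- list(
    Task1 = convolved_regressor(onsets[conditions == "Task1"], config$task_s,
                                n, fs, config$hrf_params),
    Task2 = convolved_regressor(onsets[conditions == "Task2"], config$task_s,
                                n, fs, config$hrf_params)
  )

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(subject_seed(config, subject_index))

  n_ch <- nrow(config$layout)
  hbo <- matrix(0, n, n_ch)
  hbr <- matrix(0, n, n_ch)
  for (j in seq_len(n_ch)) {
    roi <- config$layout$roi[j]
    clean <- config$roi_amplitudes$Task1[[roi]] * regress$Task1 +
      config$roi_amplitudes$Task2[[roi]] * regress$Task2
    hbo[, j] <- clean
    hbr[, j] <- -clean / 3
  }

  od780 <- matrix(0, n, n_ch)
  od850 <- matrix(0, n, n_ch)
  for (j in seq_len(n_ch)) {
    od <- hemoglobin_to_od(hbo[, j], hbr[, j],
                           separation_cm = config$layout$separation_cm[j],
                           mbll = mbll)
    od780[, j] <- od[, 1L] + physio_noise(time_s, config$noise)
    od850[, j] <- od[, 2L] + physio_noise(time_s, config$noise)
  }

  od_tbl <- tibble::as_tibble(
    c(list(time_s = time_s),
      stats::setNames(lapply(seq_len(n_ch), function(j) od780[, j]),
                      paste0(config$layout$channel, "_wl780")),
      stats::setNames(lapply(seq_len(n_ch), function(j) od850[, j]),
                      paste0(config$layout$channel, "_wl850")))
  )

  rec <- structure(
    list(od = od_tbl, events = events, layout = config$layout,
         sampling_rate = fs, filtered = FALSE),
    class = "upb_recording"
  )
  attr(rec, "ground_truth") <- list(
    labels = tibble::tibble(trial = seq_len(n_trials), onset = onsets,
                            condition = conditions),
    roi_map = stats::setNames(config$layout$roi, config$layout$channel),
    amplitudes = config$roi_amplitudes,
    hbo_clean = hbo, hbr_clean = hbr,
    subject = subject_index, seed = subject_seed(config, subject_index)
  )
  rec
}

# Sum of jittered sinusoids + 1/f drift + white noise, in OD units.
# One independent draw per call (i.e. per channel x wavelength).
# Each oscillation carries a slow random-walk phase (finite coherence, as
# physiological rhythms do): a perfectly coherent sinusoid would correlate
# the blocked trial order with slow nuisance structure and bias even a
# zero-contrast simulation away from chance-level classification.
physio_noise <- function(time_s, amp, phase_diffusion = 0.05) {
  n <- length(time_s)
  out <- numeric(n)
  sin_comp <- function(a, f0, jitter) {
    if (a <= 0) return(0)
    f <- f0 + stats::runif(1, -jitter, jitter)
    phase <- stats::runif(1, 0, 2 * pi) +
      cumsum(stats::rnorm(n, 0, phase_diffusion))
    a * sin(2 * pi * f * time_s + phase)
  }
  out <- out + sin_comp(amp[["cardiac"]], 1.0, 0.1)
  out <- out + sin_comp(amp[["respiratory"]], 0.3, 0.05)
  out <- out + sin_comp(amp[["mayer"]], 0.1, 0.01)
  if (amp[["drift"]] > 0) {
    drift_f <- c(0.002, 0.004, 0.008)
    for (f in drift_f) {
      phase <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(n, 0, phase_diffusion))
      out <- out + amp[["drift"]] * (0.002 / f) *
        sin(2 * pi * f * time_s + phase)
    }
  }
  if (amp[["white"]] > 0) out <- out + stats::rnorm(n, 0, amp[["white"]])
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Simulate the purchase-count table
#'
#' Each subject decides, per task condition, how many of 4 products to buy in
#' each of 5 clothing categories (knitwear, coat, vest, pants, suit); counts
#' are binomial(4, p) with a per-condition probability, so task totals range
#' 0..20. Default probabilities give expected totals of about 6.67 (Task 1,
#' BOGOF) and 3.36 (Task 2).
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `subject`, `condition`, `category`, `count`.
#' @export
#' @examples
#' b <- simulate_behavior(sim_config(n_subjects = 3, seed = 1))
#' dplyr::count(b, condition, wt = count)
simulate_behavior <- function(config) {
  validate_config(config)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(subject_seed(config, 0L))
  categories <- c("knitwear", "coat", "vest", "pants", "suit")
  grid <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    condition = c("Task1", "Task2"),
    category = categories
  )
  grid$count <- stats::rbinom(nrow(grid), size = 4L,
                              prob = config$behavior_p[grid$condition])
  grid
}

#' Simulate the self-report Likert table
#'
#' Three compulsive-desire-to-buy items answered on a 1..5 Likert scale per
#' condition, drawn as a rounded, clipped normal with per-condition mean and
#' SD (defaults 3.53/0.80 with the promotion, 2.40/0.90 without).
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `subject`, `condition`, `item`, `response`
#'   (integer 1..5).
#' @export
#' @examples
#' l <- simulate_likert(sim_config(n_subjects = 3, seed = 1))
#' range(l$response)
simulate_likert <- function(config) {
  validate_config(config)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(subject_seed(config, 0L) + 1L)
  grid <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    condition = c("Task1", "Task2"),
    item = 1:3
  )
  latent <- stats::rnorm(nrow(grid),
                         mean = config$likert_mean[grid$condition],
                         sd = config$likert_sd[grid$condition])
  grid$response <- as.integer(pmin(5L, pmax(1L, round(latent))))
  grid
}
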