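# --- modified Beer-Lambert conversion ------------------------------------

test_that("zero optical density maps to zero concentrations", {
  cfg <- small_config(
    noise = zero_noise,
    roi_amplitudes = list(Task1 = c(DLPFC = 0, VLPFC_L = 0, VLPFC_R = 0,
                                    mPFC = 0, OFC = 0),
                          Task2 = c(DLPFC = 0, VLPFC_L = 0, VLPFC_R = 0,
                                    mPFC = 0, OFC = 0))
  )
  h <- od_to_hemoglobin(simulate_recording(cfg, 1))
  expect_equal(max(abs(as.matrix(h$hbo[-1]))), 0)
  expect_equal(max(abs(as.matrix(h$hbr[-1]))), 0)
})

test_that("forward then inverse Beer-Lambert recovers arbitrary inputs to 1e-10", {
  set.seed(7)
  mbll <- mbll_params()
  hbo <- stats::rnorm(200, 0, 2)
  hbr <- stats::rnorm(200, 0, 1)
  od <- fnirsupb:::hemoglobin_to_od(hbo, hbr, separation_cm = 3, mbll = mbll)
  # route the OD pair through the public inverse via a minimal recording
  layout <- default_montage()[1, ]
  rec <- structure(list(
    od = tibble::tibble(time_s = seq_along(hbo) / 8.138,
                        ch01_wl780 = od[, 1], ch01_wl850 = od[, 2]),
    events = tibble::tibble(onset = numeric(), duration = numeric(),
                            condition = character()),
    layout = layout, sampling_rate = 8.138, filtered = FALSE
  ), class = "upb_recording")
  h <- od_to_hemoglobin(rec, mbll = mbll)
  expect_lt(max(abs(h$hbo$ch01 - hbo)), 1e-10)
  expect_lt(max(abs(h$hbr$ch01 - hbr)), 1e-10)
})

test_that("doubling both DPFs halves recovered concentrations", {
  cfg <- small_config()
  rec <- simulate_recording(cfg, 1)
  h1 <- od_to_hemoglobin(rec, mbll = mbll_params(dpf = c(6, 6)))
  h2 <- od_to_hemoglobin(rec, mbll = mbll_params(dpf = c(12, 12)))
  expect_equal(as.matrix(h2$hbo[-1]), as.matrix(h1$hbo[-1]) / 2,
               tolerance = 1e-12)
})

test_that("singular extinction matrices and non-positive DPF are rejected", {
  expect_error(mbll_params(eps_hbo = c(1, 2), eps_hbr = c(2, 4)), "singular")
  expect_error(mbll_params(dpf = c(0, 6)), "positive")
})

# --- band-pass filter ------------------------------------------------------

fs <- 8.138
t_axis <- seq(0, 600, by = 1 / fs)
mid <- function(x) x[(length(x) %/% 4):(3 * length(x) %/% 4)]

test_that("band-pass meets its passband and stopband contracts", {
  dc <- fnirsupb:::bandpass_core(rep(1, length(t_axis)), fs, 0.01, 0.1)
  expect_lt(max(abs(mid(dc))), 1e-3)

  pass <- fnirsupb:::bandpass_core(sin(2 * pi * 0.05 * t_axis), fs, 0.01, 0.1)
  expect_gte(max(abs(mid(pass))), 0.9)

  cardiac <- fnirsupb:::bandpass_core(sin(2 * pi * 1.0 * t_axis), fs, 0.01, 0.1)
  expect_lte(max(abs(mid(cardiac))), 0.01)
})

test_that("filtering is linear (superposition on two sinusoids)", {
  x1 <- sin(2 * pi * 0.03 * t_axis)
  x2 <- 0.5 * sin(2 * pi * 0.07 * t_axis + 1)
  y_sum <- fnirsupb:::bandpass_core(x1 + x2, fs, 0.01, 0.1)
  y_parts <- fnirsupb:::bandpass_core(x1, fs, 0.01, 0.1) +
    fnirsupb:::bandpass_core(x2, fs, 0.01, 0.1)
  expect_equal(y_sum, y_parts, tolerance = 1e-8)
})

test_that("too-short signals fail with a minimum-length message", {
  expect_error(fnirsupb:::bandpass_core(rnorm(100), fs, 0.01, 0.1),
               "at least")
  expect_error(fnirsupb:::bandpass_core(rnorm(100), fs, 0.2, 0.1),
               "low < high")
})

# --- epoching and baseline -------------------------------------------------

test_that("epoching yields one epoch per channel x trial with N = floor(61 fs)", {
  cfg <- small_config()
  h <- simulate_recording(cfg, 1) |> bandpass() |> od_to_hemoglobin()
  ep <- epoch_hemo(h)
  n_trials <- 2 * cfg$n_trials_per_task
  expect_equal(attr(ep, "n_samples"), floor(61 * 8.138))  # 496
  expect_equal(nrow(ep), 15 * n_trials * 496)
  counts <- dplyr::count(tibble::as_tibble(ep), channel, trial)
  expect_equal(nrow(counts), 15 * n_trials)
  expect_true(all(counts$n == 496))
  # t = 0 is the first sample at/after the onset
  expect_true(all(dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ep), channel, trial),
    ok = any(t == min(abs(t[t >= 0]))), .groups = "drop")$ok))
})

test_that("epoching requires filtered input (pipeline order is enforced)", {
  cfg <- small_config()
  h <- od_to_hemoglobin(simulate_recording(cfg, 1))
  expect_error(epoch_hemo(h), "bandpass")
})

test_that("trials without enough pre/post data are rejected, others kept", {
  cfg <- small_config()
  h <- simulate_recording(cfg, 1) |> bandpass() |> od_to_hemoglobin()
  ev <- h$events
  ev$onset[1] <- 0.5  # less than 1 s of pre-onset data
  expect_message(ep <- epoch_hemo(h, events = ev), "Rejecting trial 1")
  expect_equal(length(unique(ep$trial)), nrow(ev) - 1)
})

test_that("baseline correction zeroes the [-1, 0) mean and is idempotent", {
  cfg <- small_config()
  ep <- simulate_recording(cfg, 1) |> bandpass() |> od_to_hemoglobin() |>
    epoch_hemo() |> baseline_correct()
  ref_means <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ep), channel, trial),
    m = mean(hbo[t >= -1 & t < 0]), .groups = "drop")
  expect_lt(max(abs(ref_means$m)), 1e-12)
  ep2 <- baseline_correct(ep)
  expect_equal(ep2$hbo, ep$hbo, tolerance = 1e-12)
})

test_that("a constant epoch baseline-corrects to all zeros, shifted by a constant", {
  ep <- structure(
    tibble::tibble(channel = "ch01", trial = 1L, condition = "Task1",
                   t = seq(-1, 2, by = 0.25), hbo = 5),
    class = c("upb_epochs", class(tibble::tibble())),
    sampling_rate = 4, baseline_corrected = FALSE, n_samples = 13,
    layout = default_montage())
  out <- baseline_correct(ep)
  expect_true(all(out$hbo == 0))

  ep$hbo <- ep$hbo + ifelse(ep$t >= 0, 1, 0) - 3  # baseline mean = 2
  out2 <- baseline_correct(ep)
  expect_equal(out2$hbo, ep$hbo - 2)
})

test_that("temporal mean matches closed forms on simple windows", {
  make_ep <- function(vals, t) structure(
    tibble::tibble(channel = "ch01", trial = 1L, condition = "Task1",
                   t = t, hbo = vals),
    class = c("upb_epochs", class(tibble::tibble())),
    sampling_rate = 1 / diff(t)[1], baseline_corrected = TRUE,
    n_samples = length(t), layout = default_montage())

  t <- seq(-1, 60, by = 0.5)
  ones <- make_ep(rep(1, length(t)), t)
  expect_equal(temporal_mean(ones)$mean_hbo, 1.0)

  ramp_t <- t[t >= 0]
  ramp <- make_ep(c(rep(0, sum(t < 0)), ramp_t / 60), t)
  expect_equal(temporal_mean(ramp)$mean_hbo, 0.5, tolerance = 1e-2)

  expect_error(temporal_mean(ones, window = c(100, 200)), "Empty")
})
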