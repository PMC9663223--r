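test_that("hand-computed features of x = [0,1,2,3] are reproduced exactly", {
  f <- time_domain_features(c(0, 1, 2, 3), dt = 1)
  expect_equal(f$sm, 1.5)
  expect_equal(f$sv, 5 / 3)
  expect_equal(f$ss, 1)
  expect_equal(f$sa, 6)
  # standardized 4th/3rd moments, frozen from the naive-loop oracle
  expect_equal(f$kr, 0.9225, tolerance = 1e-12)
  expect_equal(f$sk, 0, tolerance = 1e-12)
  expect_false(f$degenerate)
})

test_that("a constant epoch yields the degenerate-moment flag, never NaN", {
  f <- time_domain_features(c(1, 1, 1, 1), dt = 0.5)
  expect_equal(f$sm, 1)
  expect_equal(f$sv, 0)
  expect_equal(f$ss, 0)
  expect_equal(f$sa, 4 * 0.5)
  expect_true(f$degenerate)
  expect_equal(f$kr, 0)
  expect_equal(f$sk, 0)
  expect_false(anyNA(f))
})

test_that("all six features agree with the naive-loop oracle on random vectors", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    x <- stats::rnorm(n, sd = stats::runif(1, 0.1, 10))
    dt <- stats::runif(1, 0.01, 2)
    got <- time_domain_features(x, dt)
    want <- naive_features(x, dt)
    for (col in names(want)) {
      expect_equal(got[[col]], want[[col]], tolerance = 1e-12)
    }
  }
})

test_that("kurtosis converges to 3 and skewness to 0 on standard normals", {
  set.seed(11)
  f <- time_domain_features(stats::rnorm(1e6), dt = 1)
  expect_lt(abs(f$kr - 3), 0.05)
  expect_lt(abs(f$sk), 0.01)
})

test_that("KR/SK are affine-invariant; SM, SV, SS, SA transform by closed forms", {
  set.seed(5)
  x <- stats::rnorm(40)
  dt <- 0.25
  a <- 2.5
  b <- -1.3
  f0 <- time_domain_features(x, dt)
  f1 <- time_domain_features(a * x + b, dt)
  expect_equal(f1$kr, f0$kr, tolerance = 1e-10)
  expect_equal(f1$sk, f0$sk, tolerance = 1e-10)
  expect_equal(f1$sm, a * f0$sm + b, tolerance = 1e-10)
  expect_equal(f1$sv, a^2 * f0$sv, tolerance = 1e-10)
  expect_equal(f1$ss, a * f0$ss, tolerance = 1e-10)
  expect_equal(f1$sa, a * f0$sa + b * length(x) * dt, tolerance = 1e-10)
})

test_that("endpoint slope telescopes and lsq slope matches lm", {
  set.seed(3)
  x <- stats::rnorm(30)
  dt <- 0.5
  f <- time_domain_features(x, dt)
  expect_equal(f$ss, (x[30] - x[1]) / (29 * dt))
  t <- (0:29) * dt
  expect_equal(time_domain_features(x, dt, slope = "lsq")$ss,
               unname(stats::coef(stats::lm(x ~ t))[2]), tolerance = 1e-10)
})

test_that("min-max rescaling reproduces its contract and guards", {
  m <- tibble::tibble(sm = c(2, 4, 6), sv = c(1, 2, 3), kr = c(0, 5, 10),
                      sk = c(-1, 0, 1), ss = c(10, 20, 30), sa = c(5, 5, 5))
  expect_warning(out <- apply_minmax(fit_minmax(m), m), "constant")
  expect_equal(out$sm, c(0, 0.5, 1))
  expect_equal(out$sa, c(0, 0, 0))  # constant-column guard

  # fit on train rows only: test rows may legitimately leave [0, 1]
  m2 <- tibble::tibble(sm = c(2, 4, 1), sv = c(1, 2, 3), kr = c(0, 5, 10),
                       sk = c(-1, 0, 1), ss = c(10, 20, 30), sa = c(5, 6, 7))
  sc <- fit_minmax(m2, rows = 1:2)
  out2 <- apply_minmax(sc, m2)
  expect_true(all(as.matrix(out2[1:2, ]) >= 0 & as.matrix(out2[1:2, ]) <= 1))
  expect_lt(out2$sm[3], 0)
})

test_that("rescaling matches the naive formula on random columns", {
  set.seed(21)
  for (i in 1:50) {
    z <- stats::rnorm(20)
    m <- tibble::tibble(sm = z, sv = z + 1, kr = 2 * z, sk = z^2,
                        ss = -z, sa = z / 3)
    out <- apply_minmax(fit_minmax(m), m)
    expect_equal(out$sm, naive_minmax(z), tolerance = 1e-12)
    expect_equal(out$ss, naive_minmax(-z), tolerance = 1e-12)
  }
})

test_that("the per-subject feature matrix has one row per channel x trial", {
  cfg <- small_config()
  ep <- simulate_recording(cfg, 1) |> bandpass() |> od_to_hemoglobin() |>
    epoch_hemo() |> baseline_correct()
  f <- build_feature_matrix(ep)
  n_trials <- 2 * cfg$n_trials_per_task
  expect_equal(nrow(f), 15 * n_trials)
  expect_equal(sum(f$condition == "Task1"), 15 * cfg$n_trials_per_task)
  expect_true(all(feature_cols() %in% names(f)))
  expect_false(attr(f, "rescaled"))

  # shuffling epoch order leaves the row multiset unchanged
  shuffled <- tibble::as_tibble(ep)[sample(nrow(ep)), ]
  attributes(shuffled) <- c(attributes(shuffled),
                            attributes(ep)[c("sampling_rate",
                                             "baseline_corrected",
                                             "n_samples", "layout")])
  class(shuffled) <- class(ep)
  shuffled <- dplyr::arrange(shuffled, channel, trial, t)
  class(shuffled) <- class(ep)
  f2 <- build_feature_matrix(shuffled)
  key <- function(d) dplyr::arrange(tibble::as_tibble(d), channel, trial)
  expect_equal(key(f2)$sm, key(f)$sm, tolerance = 1e-12)
})

test_that("single-condition epochs cannot form a classifiable matrix", {
  cfg <- small_config()
  ep <- simulate_recording(cfg, 1) |> bandpass() |> od_to_hemoglobin() |>
    epoch_hemo() |> baseline_correct()
  one <- dplyr::filter(tibble::as_tibble(ep), condition == "Task1")
  class(one) <- class(ep)
  attr(one, "sampling_rate") <- attr(ep, "sampling_rate")
  attr(one, "baseline_corrected") <- TRUE
  expect_error(build_feature_matrix(one), "Both conditions")
})
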