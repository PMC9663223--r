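test_that("well-separated clouds train to perfect accuracy with positive margin", {
  set.seed(1)
  xy <- rbind(matrix(stats::rnorm(40, 0, 0.1), ncol = 2),
              matrix(stats::rnorm(40, 3, 0.1), ncol = 2))
  f <- points_as_features(xy, rep(c("Task2", "Task1"), each = 20))
  fit <- train_svm(f)
  pred <- ifelse(decision_values(fit, f) > 0, "Task1", "Task2")
  expect_equal(mean(pred == f$condition), 1.0)
  expect_gt(fit$margin, 0)
})

test_that("the two-point problem recovers the closed-form maximum-margin plane", {
  # {(0,0) negative, (2,0) positive}: hyperplane x = 1, margin 2, w = (1, 0)
  f <- points_as_features(rbind(c(0, 0), c(2, 0)), c("Task2", "Task1"))
  fit <- train_svm(f, cost = 1e3)
  expect_equal(unname(fit$margin), 2, tolerance = 1e-3)
  expect_equal(unname(fit$w), c(1, 0, 0, 0, 0, 0), tolerance = 1e-3)
  # decision boundary at sm = 1
  expect_equal(unname(-fit$b / fit$w[1]), 1, tolerance = 1e-3)
  # margin identity 2/||w|| holds by construction of the accessor
  expect_equal(fit$margin, 2 / sqrt(sum(fit$w^2)))
})

test_that("identical points with opposite labels degrade gracefully", {
  xy <- rbind(matrix(0, 10, 2), matrix(0, 10, 2))
  f <- points_as_features(xy, rep(c("Task1", "Task2"), each = 10))
  fit <- train_svm(f)
  pred <- ifelse(decision_values(fit, f) > 0, "Task1", "Task2")
  expect_lte(mean(pred == f$condition), 0.5)
})

test_that("single-class input is an error", {
  f <- points_as_features(matrix(stats::rnorm(20), ncol = 2), rep("Task1", 10))
  expect_error(train_svm(f), "Both classes")
})

test_that("cross-validation is reproducible and perfect on separated classes", {
  set.seed(2)
  xy <- rbind(matrix(stats::rnorm(60, 0, 0.05), ncol = 2),
              matrix(stats::rnorm(60, 5, 0.05), ncol = 2))
  f <- points_as_features(xy, rep(c("Task2", "Task1"), each = 30))
  class(f) <- c("upb_features", class(f))
  cv <- cross_validate(f, repeats = 10, seed = 7)
  expect_equal(cv$mean, 1.0)
  expect_equal(cv$sem, 0.0)
  cv2 <- cross_validate(f, repeats = 10, seed = 7)
  expect_identical(cv$accuracy, cv2$accuracy)
  expect_identical(cv$scores, cv2$scores)
  # SEM definition
  expect_equal(cv$sem, cv$sd / sqrt(cv$repeats))
  # stratified 80/20: 24 train + 6 test per class per split
  expect_equal(nrow(cv$scores), 10 * 12)
})

test_that("randomly relabelled data classify at chance", {
  set.seed(3)
  accs <- numeric(50)
  xy <- matrix(stats::rnorm(200), ncol = 2)
  for (i in seq_len(50)) {
    set.seed(300 + i)
    f <- points_as_features(xy, sample(rep(c("Task1", "Task2"), each = 50)))
    class(f) <- c("upb_features", class(f))
    accs[i] <- cross_validate(f, repeats = 5, seed = i)$mean
  }
  sem <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * sem + 0.02)
})

test_that("classes below the fold minimum raise the sample-unit hint", {
  f <- points_as_features(matrix(stats::rnorm(24), ncol = 2),
                          rep(c("Task1", "Task2"), each = 6))
  class(f) <- c("upb_features", class(f))
  expect_error(cross_validate(f), "per-\\(channel, trial\\)|sample unit")
})

test_that("per-split rescaling is leakage-free; global mode is the leaky variant", {
  cfg <- small_config()
  ep <- simulate_recording(cfg, 1) |> bandpass() |> od_to_hemoglobin() |>
    epoch_hemo() |> baseline_correct()
  f <- build_feature_matrix(ep)
  cv_split <- cross_validate(f, repeats = 5, seed = 1)
  cv_global <- cross_validate(f, repeats = 5, seed = 1, rescale = "global")
  expect_equal(cv_split$rescale, "per_split")
  expect_equal(cv_global$rescale, "global")
  # the leak's signature: a global scaler maps every row into [0,1],
  # a train-fitted scaler lets held-out rows escape the unit interval
  sc_train <- fit_minmax(f, rows = which(f$trial != max(f$trial)))
  held <- which(f$trial == max(f$trial))
  out <- suppressWarnings(apply_minmax(sc_train, f))
  expect_true(any(as.matrix(out[held, feature_cols()]) < 0 |
                    as.matrix(out[held, feature_cols()]) > 1))
  out_g <- suppressWarnings(apply_minmax(fit_minmax(f), f))
  expect_true(all(as.matrix(out_g[feature_cols()]) >= 0 &
                    as.matrix(out_g[feature_cols()]) <= 1))
})

test_that("the kfold scheme partitions all samples across each repetition", {
  set.seed(4)
  xy <- rbind(matrix(stats::rnorm(60, 0, 0.3), ncol = 2),
              matrix(stats::rnorm(60, 4, 0.3), ncol = 2))
  f <- points_as_features(xy, rep(c("Task2", "Task1"), each = 30))
  class(f) <- c("upb_features", class(f))
  cv <- cross_validate(f, repeats = 10, scheme = "kfold", seed = 5)
  # one full 10-fold pass: every sample tested exactly once
  expect_equal(sort(unique(cv$scores$iteration)), 1:10)
  expect_equal(nrow(cv$scores), 60)
})

test_that("per-subject report aggregates means and the grand average", {
  mk <- function(m) structure(list(accuracy = m, mean = mean(m),
                                   sd = stats::sd(m),
                                   sem = stats::sd(m) / sqrt(length(m)),
                                   repeats = length(m)), class = "upb_cv")
  rep2 <- per_subject_report(list(a = mk(c(0.9, 0.9)), b = mk(c(1, 1))))
  expect_equal(rep2$grand$accuracy_mean, 0.95)
  expect_equal(rep2$subjects$accuracy_mean, c(0.9, 1.0))

  rep1 <- per_subject_report(list(only = mk(c(0.8, 0.9))))
  expect_equal(rep1$grand$accuracy_mean, 0.85)
  expect_equal(rep1$grand$accuracy_sem, 0)
})

test_that("tidy and glance methods expose CV results as tibbles", {
  set.seed(6)
  xy <- rbind(matrix(stats::rnorm(60, 0, 0.2), ncol = 2),
              matrix(stats::rnorm(60, 4, 0.2), ncol = 2))
  f <- points_as_features(xy, rep(c("Task2", "Task1"), each = 30))
  class(f) <- c("upb_features", class(f))
  cv <- cross_validate(f, repeats = 6, seed = 2)
  td <- tidy(cv)
  expect_equal(nrow(td), 6)
  expect_named(td, c("iteration", "accuracy"))
  gl <- glance(cv)
  expect_equal(gl$accuracy_mean, cv$mean)
  expect_equal(gl$n_iterations, 6)
})
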