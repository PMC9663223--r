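#' Train a maximum-margin SVM on a feature matrix
#'
#' Fits a support-vector machine separating unplanned-purchase (Task 1,
#' positive class) from control (Task 2) feature vectors. The established
#' libsvm solver (via e1071) performs the quadratic-margin optimization;
#' this wrapper owns the label convention, disables internal scaling (the
#' pipeline min-max rescales explicitly), and, for the linear kernel,
#' exposes the primal weight vector `w`, offset `b`, the decision function
#' `d(x) = w'x + b`, and the geometric margin `2 / ||w||`.
#'
#' @param features Tibble with the six feature columns (already rescaled)
#'   and a label column.
#' @param label_col Name of the label column (default `"condition"`).
#' @param cost Soft-margin constant C.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @return An `"upb_svm"`: list with the fitted `model`, `levels` (positive
#'   class first), and for the linear kernel `w`, `b`, `margin`.
#' @export
#' @examples
#' f <- tibble::tibble(sm = c(0, 0.1, 1, 0.9), sv = c(0, 0.1, 1, 0.9),
#'                     kr = 0, sk = 0, ss = 0, sa = 0,
#'                     condition = c("Task2", "Task2", "Task1", "Task1"))
#' fit <- train_svm(f)
#' fit$margin > 0
train_svm <- function(features, label_col = "condition", cost = 1,
                      kernel = c("linear", "radial")) {
  kernel <- match.arg(kernel)
  labels <- features[[label_col]]
  if (length(unique(labels)) < 2L) {
    stop("Both classes are required to train the SVM.", call. = FALSE)
  }
  X <- as.matrix(features[feature_cols()])
  # Positive (unplanned-purchase) class Task1 listed first so libsvm's
  # decision values are oriented positive-for-Task1.
  y <- factor(labels, levels = c("Task1", "Task2"))
  model <- e1071::svm(X, y, kernel = kernel, cost = cost, scale = FALSE)
  out <- list(model = model, levels = levels(y), kernel = kernel,
              cost = cost)
  if (kernel == "linear") {
    w <- drop(t(model$coefs) %*% model$SV)
    b <- -model$rho
    # libsvm orients d(x) positive toward the class it happened to see
    # first; flip so positive always favors Task1
    first_label <- model$levels[model$labels[1L]]
    if (!identical(first_label, "Task1")) {
      w <- -w
      b <- -b
    }
    out$w <- w
    out$b <- b
    out$margin <- 2 / sqrt(sum(w^2))
  }
  class(out) <- "upb_svm"
  out
}

#' @export
print.upb_svm <- function(x, ...) {
  cat("<upb_svm> kernel:", x$kernel, " C:", x$cost,
      " support vectors:", nrow(x$model$SV), "\n")
  if (!is.null(x$margin)) cat("  margin 2/||w||:", signif(x$margin, 4), "\n")
  invisible(x)
}

#' Decision values of an SVM on new feature rows
#'
#' Returns `d(x)` oriented so that larger values favor the positive
#' (Task 1 / unplanned-purchase) class.
#'
#' @param fit An `"upb_svm"`.
#' @param features Tibble with the six feature columns.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(fit, features) {
  X <- as.matrix(features[feature_cols()])
  pred <- stats::predict(fit$model, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm names the column "<first>/<second>"; positive favors <first>
  if (!startsWith(colnames(dv)[1L], "Task1")) dv <- -dv
  drop(dv)
}

#' Repeated cross-validation of the per-subject classifier
#'
#' The default scheme is 30 independent stratified shuffled splits holding
#' out 20% of each class (the 8-train / 2-test split of a 10-fold partition,
#' repeated 30 times to estimate accuracy variability). Per split, the
#' min-max rescaler is fitted on the training portion only and applied to
#' both portions, preventing train-to-test leakage; `rescale = "global"`
#' deliberately fits on all rows (the literal read of the rescaling
#' equation) for leakage comparisons. The alternative `scheme = "kfold"`
#' runs classic stratified 10-fold partitions repeated `ceiling(repeats/10)`
#' times.
#'
#' @param features An `"upb_features"` tibble (raw, un-rescaled).
#' @param repeats Number of held-out evaluations (default 30).
#' @param train_frac Training fraction for the shuffled scheme.
#' @param scheme `"shuffled"` (default) or `"kfold"`.
#' @param rescale `"per_split"` (default, leakage-free) or `"global"`.
#' @param cost,kernel Passed to [train_svm()].
#' @param seed Integer seed making the split sequence reproducible.
#' @return An `"upb_cv"`: list with `accuracy` (length-`repeats` vector),
#'   `mean`, `sd`, `sem = sd/sqrt(repeats)`, and `scores` (tibble
#'   `iteration`, `truth`, `score` of pooled held-out decision values).
#' @export
cross_validate <- function(features, repeats = 30, train_frac = 0.8,
                           scheme = c("shuffled", "kfold"),
                           rescale = c("per_split", "global"),
                           cost = 1, kernel = "linear", seed = 1L) {
  scheme <- match.arg(scheme)
  rescale <- match.arg(rescale)
  stopifnot(inherits(features, "upb_features") || is.data.frame(features))
  labels <- features$condition
  counts <- table(labels)
  if (length(counts) < 2L) {
    stop("Both classes are required for cross-validation.", call. = FALSE)
  }
  if (min(counts) < 10L) {
    stop("Fewer than 10 samples in a class (", min(counts), "); use the ",
         "per-(channel, trial) sample unit to obtain 75 samples per class.",
         call. = FALSE)
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)

  idx_by_class <- split(seq_along(labels), labels)
  splits <- list()
  if (scheme == "shuffled") {
    for (r in seq_len(repeats)) {
      train <- unlist(lapply(idx_by_class, function(ix) {
        sample(ix, floor(train_frac * length(ix)))
      }), use.names = FALSE)
      splits[[r]] <- list(train = train,
                          test = setdiff(seq_along(labels), train))
    }
  } else {
    k <- 10L
    while (length(splits) < repeats) {
      fold_of <- integer(length(labels))
      for (ix in idx_by_class) {
        fold_of[ix] <- sample(rep_len(seq_len(k), length(ix)))
      }
      for (f in seq_len(k)) {
        if (length(splits) >= repeats) break
        test <- which(fold_of == f)
        splits[[length(splits) + 1L]] <-
          list(train = setdiff(seq_along(labels), test), test = test)
      }
    }
  }

  global_scaler <- if (rescale == "global") fit_minmax(features) else NULL
  acc <- numeric(length(splits))
  scores <- vector("list", length(splits))
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    scaler <- if (rescale == "per_split") {
      fit_minmax(features, sp$train)
    } else global_scaler
    scaled <- suppressWarnings(apply_minmax(scaler, features))
    fit <- train_svm(scaled[sp$train, ], cost = cost, kernel = kernel)
    sc <- decision_values(fit, scaled[sp$test, ])
    pred <- ifelse(sc > 0, "Task1", "Task2")
    truth <- labels[sp$test]
    acc[r] <- mean(pred == truth)
    scores[[r]] <- tibble::tibble(iteration = r, truth = truth, score = sc)
  }
  structure(
    list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
         sem = stats::sd(acc) / sqrt(length(acc)),
         scores = purrr::list_rbind(scores),
         scheme = scheme, rescale = rescale, repeats = length(splits),
         seed = seed),
    class = "upb_cv"
  )
}

#' @export
print.upb_cv <- function(x, ...) {
  cat("<upb_cv> ", x$repeats, " x ", x$scheme, " splits: accuracy ",
      sprintf("%.4f +/- %.4f (SEM)", x$mean, x$sem), "\n", sep = "")
  invisible(x)
}

#' Per-subject accuracy report
#'
#' Aggregates each subject's repeated-CV accuracies into the per-subject
#' mean +/- SEM table plus the grand mean +/- SEM across subjects (the
#' "average" bar of a per-subject accuracy chart).
#'
#' @param cv_results Named or unnamed list of `"upb_cv"` objects, one per
#'   subject.
#' @return An `"upb_report"`: list with `subjects` (tibble `subject`,
#'   `accuracy_mean`, `accuracy_sd`, `accuracy_sem`, `n_iterations`) and
#'   `grand` (one-row tibble `accuracy_mean`, `accuracy_sd`,
#'   `accuracy_sem`, `n_subjects`).
#' @export
per_subject_report <- function(cv_results) {
  stopifnot(length(cv_results) >= 1L)
  ids <- names(cv_results)
  if (is.null(ids)) ids <- as.character(seq_along(cv_results))
  subjects <- purrr::map2(cv_results, ids, function(cv, id) {
    tibble::tibble(subject = id, accuracy_mean = cv$mean,
                   accuracy_sd = cv$sd, accuracy_sem = cv$sem,
                   n_iterations = cv$repeats)
  }) |> purrr::list_rbind()
  means <- subjects$accuracy_mean
  grand <- tibble::tibble(
    accuracy_mean = mean(means),
    accuracy_sd = if (length(means) > 1L) stats::sd(means) else 0,
    accuracy_sem = if (length(means) > 1L) {
      stats::sd(means) / sqrt(length(means))
    } else 0,
    n_subjects = length(means)
  )
  structure(list(subjects = subjects, grand = grand), class = "upb_report")
}

#' @export
print.upb_report <- function(x, ...) {
  cat("<upb_report> ", nrow(x$subjects), " subject(s); grand accuracy ",
      sprintf("%.2f%% +/- %.2f%% (SEM)", 100 * x$grand$accuracy_mean,
              100 * x$grand$accuracy_sem), "\n", sep = "")
  invisible(x)
}
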