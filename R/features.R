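#' Six time-domain features of one epoch
#'
#' Computes, from a single HbO epoch `x[n]` (n = 0..N-1) sampled at interval
#' `dt` seconds, the six time-domain descriptors used as classifier input:
#'
#' * `sm` — signal mean, `(1/N) * sum(x)` (micromolar);
#' * `sv` — signal variance, `sum((x - sm)^2) / (N - 1)` (micromolar^2);
#' * `kr` — signal kurtosis, the raw (non-excess) fourth standardized
#'   moment `mean(((x - sm)/s)^4)` with `s = sqrt(sv)`;
#' * `sk` — signal skewness, `mean(((x - sm)/s)^3)`;
#' * `ss` — signal slope: the mean of the per-sample slopes
#'   `(x[n] - x[n-1])/dt`, which telescopes to
#'   `(x[N-1] - x[0]) / ((N-1) * dt)` (micromolar/s);
#' * `sa` — signal area, the signed rectangle-rule sum `sum(x) * dt`
#'   (micromolar-seconds).
#'
#' A constant epoch (`sv == 0`) makes `kr` and `sk` undefined; both are set
#' to 0 and flagged via `degenerate = TRUE` rather than returned as NaN.
#'
#' @param x Numeric vector, one epoch's HbO samples over the analysis
#'   window, `length(x) >= 3`.
#' @param dt Sampling interval in seconds.
#' @param slope Either `"endpoint"` (mean of per-sample slopes; default) or
#'   `"lsq"` (ordinary least-squares slope of `x` on time).
#' @return A one-row tibble: `sm`, `sv`, `kr`, `sk`, `ss`, `sa`,
#'   `degenerate`.
#' @export
#' @examples
#' time_domain_features(c(0, 1, 2, 3), dt = 1)
time_domain_features <- function(x, dt, slope = c("endpoint", "lsq")) {
  slope <- match.arg(slope)
  n <- length(x)
  if (n < 3L) stop("Need at least 3 samples per epoch.", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive.", call. = FALSE)
  sm <- sum(x) / n
  sv <- sum((x - sm)^2) / (n - 1)
  degenerate <- sv == 0
  if (degenerate) {
    kr <- 0
    sk <- 0
  } else {
    z <- (x - sm) / sqrt(sv)
    kr <- mean(z^4)
    sk <- mean(z^3)
  }
  ss <- if (slope == "endpoint") {
    (x[n] - x[1L]) / ((n - 1) * dt)
  } else {
    t <- (seq_len(n) - 1) * dt
    stats::cov(t, x) / stats::var(t)
  }
  sa <- sum(x) * dt
  tibble::tibble(sm = sm, sv = sv, kr = kr, sk = sk, ss = ss, sa = sa,
                 degenerate = degenerate)
}

#' Build the per-subject feature matrix
#'
#' One sample (row) per (channel, trial) epoch: with the 15-channel montage
#' and 5 trials per task this gives 75 rows per condition and subject.
#' Features are computed on the baseline-corrected post-onset analysis
#' window (default 0..60 s).
#'
#' @param epochs Baseline-corrected `"upb_epochs"` from one subject,
#'   containing both conditions.
#' @param window Analysis window `c(from, to)` (s), inclusive.
#' @param slope Slope scalarization passed to [time_domain_features()].
#' @return An `"upb_features"` tibble: `channel`, `trial`, `condition`,
#'   `sm`, `sv`, `kr`, `sk`, `ss`, `sa`, `degenerate`, with attribute
#'   `rescaled = FALSE`.
#' @export
build_feature_matrix <- function(epochs, window = c(0, 60),
                                 slope = "endpoint") {
  stopifnot(inherits(epochs, "upb_epochs"))
  if (!isTRUE(attr(epochs, "baseline_corrected"))) {
    stop("Features are computed on baseline-corrected epochs.", call. = FALSE)
  }
  conds <- unique(epochs$condition)
  if (length(conds) < 2L) {
    stop("Both conditions are required to build a classifiable feature ",
         "matrix; got only ", paste(conds, collapse = ", "), ".",
         call. = FALSE)
  }
  dt <- 1 / attr(epochs, "sampling_rate")
  out <- tibble::as_tibble(epochs) |>
    dplyr::filter(.data$t >= window[1L], .data$t <= window[2L]) |>
    dplyr::group_by(.data$channel, .data$trial, .data$condition) |>
    dplyr::reframe(time_domain_features(.data$hbo, dt, slope)) |>
    dplyr::ungroup()
  structure(out,
            class = c("upb_features", class(tibble::tibble())),
            rescaled = FALSE)
}

feature_cols <- function() c("sm", "sv", "kr", "sk", "ss", "sa")

#' Min-max rescaling fitted on a training subset
#'
#' `fit_minmax()` learns per-feature minima and maxima over the given rows;
#' `apply_minmax()` maps each feature through
#' `(z - min) / (max - min)`. Rows the scaler was fitted on land in
#' \[0, 1\]; other rows may fall outside — that is the documented,
#' leakage-free behavior when fitting on training folds only. A constant
#' column is mapped to 0 with a warning instead of dividing by zero.
#'
#' @param features An `"upb_features"` tibble (or any tibble with the six
#'   feature columns).
#' @param rows Integer row indices to fit on; defaults to all rows.
#' @return `fit_minmax()`: an `"upb_minmax"` scaler. `apply_minmax()`: the
#'   rescaled tibble with attribute `rescaled = TRUE`.
#' @export
#' @examples
#' m <- tibble::tibble(sm = c(2, 4, 6), sv = 1:3, kr = 1:3, sk = 1:3,
#'                     ss = 1:3, sa = 1:3)
#' apply_minmax(fit_minmax(m), m)$sm
fit_minmax <- function(features, rows = seq_len(nrow(features))) {
  stopifnot(all(feature_cols() %in% names(features)))
  sub <- features[rows, feature_cols()]
  mins <- vapply(sub, min, numeric(1))
  maxs <- vapply(sub, max, numeric(1))
  structure(list(min = mins, max = maxs), class = "upb_minmax")
}

#' @rdname fit_minmax
#' @param scaler An `"upb_minmax"` from `fit_minmax()`.
#' @export
apply_minmax <- function(scaler, features) {
  stopifnot(inherits(scaler, "upb_minmax"),
            all(feature_cols() %in% names(features)))
  at <- attributes(features)
  for (col in feature_cols()) {
    rng <- scaler$max[[col]] - scaler$min[[col]]
    if (rng == 0) {
      warning("Feature `", col, "` is constant over the fitted rows; ",
              "rescaled to 0.", call. = FALSE)
      features[[col]] <- rep(0, nrow(features))
    } else {
      features[[col]] <- (features[[col]] - scaler$min[[col]]) / rng
    }
  }
  attr(features, "rescaled") <- TRUE
  if (!is.null(at$class)) class(features) <- at$class
  features
}
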