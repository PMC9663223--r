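# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles are written as naive loops on purpose: they must
# stay independent of the vectorized implementations they check.

zero_noise <- c(cardiac = 0, respiratory = 0, mayer = 0, drift = 0, white = 0)

# two trials per task keeps unit-test recordings short (~4 min of signal)
small_config <- function(...) {
  sim_config(n_subjects = 1, n_trials_per_task = 2, seed = 42, ...)
}

# zero programmed activation in both conditions = zero class contrast
null_amplitudes <- function() {
  amp <- c(DLPFC = 0, VLPFC_L = 0, VLPFC_R = 0, mPFC = 0, OFC = 0)
  list(Task1 = amp, Task2 = amp)
}

naive_features <- function(x, dt) {
  n <- length(x)
  sm <- 0
  for (v in x) sm <- sm + v
  sm <- sm / n
  sv <- 0
  for (v in x) sv <- sv + (v - sm)^2
  sv <- sv / (n - 1)
  s <- sqrt(sv)
  kr <- 0
  sk <- 0
  for (v in x) {
    kr <- kr + ((v - sm) / s)^4
    sk <- sk + ((v - sm) / s)^3
  }
  kr <- kr / n
  sk <- sk / n
  ss <- 0
  for (i in 2:n) ss <- ss + (x[i] - x[i - 1]) / dt
  ss <- ss / (n - 1)
  sa <- 0
  for (v in x) sa <- sa + v * dt
  c(sm = sm, sv = sv, kr = kr, sk = sk, ss = ss, sa = sa)
}

naive_minmax <- function(z) (z - min(z)) / (max(z) - min(z))

# pairwise-ranking (Mann-Whitney) probability P(s+ > s-) + 0.5 P(tie)
brute_auc <- function(scores, labels, positive = "Task1") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) {
    for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

brute_confusion <- function(truth, pred, positive = "Task1") {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == positive && pred[i] == positive) tp <- tp + 1L
    if (truth[i] != positive && pred[i] == positive) fp <- fp + 1L
    if (truth[i] != positive && pred[i] != positive) tn <- tn + 1L
    if (truth[i] == positive && pred[i] != positive) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# feature tibble helper for classifier tests: embeds 2-D points into the
# six feature columns (remaining columns zero)
points_as_features <- function(xy, labels) {
  tibble::tibble(sm = xy[, 1], sv = xy[, 2], kr = 0, sk = 0, ss = 0, sa = 0,
                 condition = labels)
}
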