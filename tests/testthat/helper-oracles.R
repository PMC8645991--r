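# Independent oracles used across the suite. Each recomputes a quantity by a
# route different from the package implementation (explicit loops, lm() fits,
# exhaustive enumeration) so agreement is evidence, not tautology.

# Pearson correlation as an explicit centered-inner-product loop
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- 0; dx <- 0; dy <- 0
  for (t in seq_along(x)) {
    num <- num + (x[t] - mx) * (y[t] - my)
    dx <- dx + (x[t] - mx)^2
    dy <- dy + (y[t] - my)^2
  }
  num / sqrt(dx * dy)
}

# per-node lasso objective at a weight matrix (row i regresses x_i on the rest)
oracle_sr_objective <- function(X, W, lam) {
  tot <- 0
  for (i in seq_len(ncol(X))) {
    r <- X[, i] - X %*% W[i, ]
    tot <- tot + sum(r^2) + lam * sum(abs(W[i, ]))
  }
  tot
}

# Granger statistic via lm() on explicitly built lagged frames
oracle_granger <- function(x, y, p) {
  T <- length(y)
  idx <- (p + 1):T
  dat <- data.frame(yt = y[idx])
  for (k in seq_len(p)) {
    dat[[paste0("yl", k)]] <- y[idx - k]
    dat[[paste0("xl", k)]] <- x[idx - k]
  }
  fr <- stats::lm(stats::reformulate(paste0("yl", 1:p), "yt"), dat)
  fu <- stats::lm(stats::reformulate(c(paste0("yl", 1:p), paste0("xl", 1:p)), "yt"), dat)
  n <- length(idx)
  max(log((sum(stats::resid(fr)^2) / n) / (sum(stats::resid(fu)^2) / n)), 0)
}

# AUC by exhaustive positive-negative pair counting, ties 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == -1]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# small, quick planted cohort for protocol tests
tiny_cohort <- function(seed, n_per_group = 20, n_rois = 20, t = 140,
                        effect = 0.15, cov_edges = 6, lag_edges = 6) {
  simulate_cohort(cohort_spec(
    n_per_group = n_per_group, n_rois = n_rois, n_timepoints = t,
    n_diff_edges_cov = cov_edges, n_diff_edges_lag = lag_edges,
    effect_size = effect, seed = seed))
}

rand_subject <- function(seed, t = 60, n = 5, id = "s1") {
  set.seed(seed)
  subject_ts(id, matrix(rnorm(t * n), t, n))
}
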