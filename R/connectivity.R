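#' Construct a subject time-series object
#'
#' Container for one subject's T x N ROI signal matrix (rows are time
#' points, columns are ROI series).
#'
#' @param subject_id character id.
#' @param signal numeric T x N matrix.
#' @param roi_labels optional character vector of N ROI names; defaults to
#'   the signal's column names or `ROI_1..ROI_N`.
#' @return an object of class `subject_ts`.
#' @export
subject_ts <- function(subject_id, signal, roi_labels = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (nrow(signal) < 3L)
    stop_mcpc("subject time series needs at least 3 time points")
  if (any(!is.finite(signal)))
    stop_mcpc(sprintf("subject '%s' has non-finite signal entries", subject_id))
  if (is.null(roi_labels))
    roi_labels <- colnames(signal) %||% paste0("ROI_", seq_len(ncol(signal)))
  if (length(roi_labels) != ncol(signal))
    stop_mcpc("roi_labels length must match the number of signal columns")
  dimnames(signal) <- NULL
  structure(list(subject_id = as.character(subject_id), signal = signal,
                 roi_labels = as.character(roi_labels)),
            class = "subject_ts")
}

conn_matrix <- function(weights, pattern, directed, subject_id, params = list()) {
  structure(list(weights = weights, pattern = pattern, directed = directed,
                 subject_id = subject_id, params = params),
            class = "conn_matrix")
}

check_columns_nondegenerate <- function(ts) {
  v <- apply(ts$signal, 2, stats::var)
  bad <- which(v <= 0 | !is.finite(v))
  if (length(bad))
    stop_mcpc(sprintf("degenerate (zero-variance) ROI series: %s",
                      paste(ts$roi_labels[bad], collapse = ", ")))
  invisible(TRUE)
}

#' Pearson correlation of two series
#'
#' Centered inner product normalized by the centered norms:
#' `sum((x - mean(x)) * (y - mean(y))) / sqrt(sum((x-mean(x))^2) * sum((y-mean(y))^2))`.
#'
#' @param x,y numeric series of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_edge <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_mcpc("series must have equal length >= 3")
  cx <- x - mean(x); cy <- y - mean(y)
  nx <- sum(cx^2); ny <- sum(cy^2)
  if (nx <= 0 || ny <= 0)
    stop_mcpc("degenerate input: a series has zero variance")
  r <- sum(cx * cy) / sqrt(nx * ny)
  min(1, max(-1, r))
}

#' Pearson-correlation connectivity matrix
#'
#' Symmetric N x N matrix of pairwise Pearson correlations between ROI
#' series, with a zero diagonal (self-connections carry no edge
#' information).
#'
#' @param ts a [subject_ts()].
#' @return a `conn_matrix` with `pattern = "PC"`.
#' @export
pearson_network <- function(ts) {
  stopifnot(inherits(ts, "subject_ts"))
  check_columns_nondegenerate(ts)
  W <- stats::cor(ts$signal)
  W[W > 1] <- 1; W[W < -1] <- -1
  diag(W) <- 0
  conn_matrix(W, "PC", directed = FALSE, subject_id = ts$subject_id)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# coordinate descent for min_w ||y - D w||^2 + lam * sum(|w|)
lasso_cd <- function(D, y, lam, tol = 1e-6, max_iter = 10000L) {
  p <- ncol(D)
  d2 <- colSums(D^2)
  if (any(d2 <= 0)) stop_mcpc("lasso design has a zero column")
  w <- numeric(p)
  r <- y
  obj <- sum(r^2)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(p)) {
      wj <- w[j]
      rho <- sum(D[, j] * r) + d2[j] * wj
      wn <- soft_threshold(rho, lam / 2) / d2[j]
      if (wn != wj) {
        r <- r + D[, j] * (wj - wn)
        w[j] <- wn
      }
    }
    obj_new <- sum(r^2) + lam * sum(abs(w))
    if (obj - obj_new < tol) {
      return(list(w = w, converged = TRUE, iterations = it, objective = obj_new))
    }
    obj <- obj_new
  }
  list(w = w, converged = FALSE, iterations = max_iter, objective = obj,
       gap = obj - obj_new)
}

#' Sparse-representation (lasso partial-correlation) connectivity matrix
#'
#' Each row i of W solves the per-node lasso
#' `min_w ||x_i - sum_{j != i} w_j x_j||^2 + lambda * sum |w_j|`
#' by coordinate descent; the diagonal is fixed at zero. Columns are
#' centered and, by default, z-scored before fitting so the penalty grid
#' `2^-5 .. 2^5` spans useful sparsity regardless of signal amplitude;
#' coefficients are returned on the standardized scale.
#'
#' @param ts a [subject_ts()].
#' @param lam nonnegative l1 penalty (the protocol default is `2^3`).
#' @param scale column scaling before fitting: `"sd"` (z-score, default),
#'   `"l2"` (unit Euclidean norm) or `"none"` (center only).
#' @param symmetrize if TRUE, return `(W + t(W)) / 2`; the raw asymmetric
#'   matrix is kept in `$params$raw`.
#' @param tol,max_iter coordinate-descent stopping rule: objective decrease
#'   per sweep below `tol`, iteration cap.
#' @return a `conn_matrix` with `pattern = "SR"`.
#' @export
sr_network <- function(ts, lam, scale = c("sd", "l2", "none"),
                       symmetrize = FALSE, tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(ts, "subject_ts"))
  if (!is.finite(lam) || lam < 0) stop_mcpc("'lam' must be nonnegative")
  scale <- match.arg(scale)
  check_columns_nondegenerate(ts)
  X <- sweep(ts$signal, 2, colMeans(ts$signal))
  if (scale == "sd") X <- sweep(X, 2, apply(X, 2, stats::sd), "/")
  if (scale == "l2") X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  N <- ncol(X)
  W <- matrix(0, N, N)
  for (i in seq_len(N)) {
    fit <- lasso_cd(X[, -i, drop = FALSE], X[, i], lam,
                    tol = tol, max_iter = max_iter)
    if (!fit$converged)
      stop_mcpc(sprintf(
        "sr_network did not converge for ROI %s (objective gap %.3g)",
        ts$roi_labels[i], fit$gap))
    W[i, -i] <- fit$w
  }
  raw <- W
  if (symmetrize) W <- (W + t(W)) / 2
  conn_matrix(W, "SR", directed = !symmetrize, subject_id = ts$subject_id,
              params = list(lam = lam, scale = scale, symmetrize = symmetrize,
                            raw = if (symmetrize) raw else NULL))
}

# objective of the per-node lasso system at a given weight matrix
sr_objective <- function(ts, W, lam, scale = c("sd", "l2", "none")) {
  scale <- match.arg(scale)
  X <- sweep(ts$signal, 2, colMeans(ts$signal))
  if (scale == "sd") X <- sweep(X, 2, apply(X, 2, stats::sd), "/")
  if (scale == "l2") X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  R <- X - X %*% t(W)   # column i of t(W) holds row i of W
  sum(R^2) + lam * sum(abs(W))
}

#' Bivariate Granger causality of x on y
#'
#' Compares the restricted autoregression of `y` on its own `p` lags with
#' the unrestricted regression adding `p` lags of `x`; the statistic is the
#' log ratio of the residual variances, `ln(var(restricted) /
#' var(unrestricted))`, nonnegative for nested least-squares fits (tiny
#' negative values from finite precision are clipped to 0).
#'
#' @param x,y numeric series of equal length.
#' @param p lag order (default 1).
#' @return a list with `restricted_residual_variance`,
#'   `unrestricted_residual_variance`, `f_value` and `lag_order`.
#' @export
granger_pair <- function(x, y, p = 1L) {
  p <- check_scalar_int(p, "p")
  T <- length(y)
  if (length(x) != T) stop_mcpc("series must have equal length")
  if (T <= 2 * p + 2) stop_mcpc("series too short for the requested lag order")
  if (stats::var(x) <= 0 || stats::var(y) <= 0)
    stop_mcpc("degenerate input: a series has zero variance")
  idx <- (p + 1):T
  Y <- y[idx]
  lags <- function(v) vapply(seq_len(p), function(k) v[idx - k], numeric(length(idx)))
  Zr <- cbind(1, lags(y))
  Zu <- cbind(Zr, lags(x))
  rss <- function(Z) {
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) stop_mcpc("degenerate design matrix in Granger regression")
    sum(qr.resid(qrz, Y)^2)
  }
  n_obs <- length(Y)
  var_r <- rss(Zr) / n_obs
  var_u <- rss(Zu) / n_obs
  f <- log(var_r / var_u)
  if (is.nan(f)) stop_mcpc("degenerate residuals in Granger regression")
  list(restricted_residual_variance = var_r,
       unrestricted_residual_variance = var_u,
       f_value = max(f, 0), lag_order = p)
}

#' Granger causality mapping of a subject
#'
#' Directed N x N matrix with `W[i, j]` the Granger statistic of ROI i on
#' ROI j ([granger_pair()] with `x = x_i`, `y = x_j`); asymmetric in
#' general, zero diagonal. For `p = 1` all pairwise regressions are solved
#' in closed form from the lag-0/lag-1 cross-moment matrices; higher orders
#' fall back to per-pair fits.
#'
#' @param ts a [subject_ts()].
#' @param p lag order (default 1).
#' @return a `conn_matrix` with `pattern = "GCM"`, `directed = TRUE`.
#' @export
gcm_network <- function(ts, p = 1L) {
  stopifnot(inherits(ts, "subject_ts"))
  p <- check_scalar_int(p, "p")
  check_columns_nondegenerate(ts)
  X <- ts$signal
  T <- nrow(X); N <- ncol(X)
  if (T <= 2 * p + 2) stop_mcpc("series too short for the requested lag order")
  W <- matrix(0, N, N)
  if (p == 1L) {
    Y <- X[2:T, , drop = FALSE]
    L <- X[1:(T - 1), , drop = FALSE]
    Yc <- sweep(Y, 2, colMeans(Y))
    Lc <- sweep(L, 2, colMeans(L))
    Syy <- colSums(Yc^2)
    Cyl <- crossprod(Yc, Lc)   # Cyl[j, i] = <Y_j, L_i>
    Cll <- crossprod(Lc)
    for (j in seq_len(N)) {
      a <- Cll[j, j]
      if (a <= 0) stop_mcpc(sprintf("degenerate design for ROI %s", ts$roi_labels[j]))
      rss_r <- Syy[j] - Cyl[j, j]^2 / a
      for (i in seq_len(N)) {
        if (i == j) next
        d <- Cll[i, i]; bc <- Cll[j, i]
        det <- a * d - bc^2
        if (det <= 1e-12 * a * d)
          stop_mcpc(sprintf("degenerate design matrix for ROI pair %s -> %s",
                            ts$roi_labels[i], ts$roi_labels[j]))
        s1 <- Cyl[j, j]; s2 <- Cyl[j, i]
        b1 <- (d * s1 - bc * s2) / det
        b2 <- (a * s2 - bc * s1) / det
        rss_u <- Syy[j] - (b1 * s1 + b2 * s2)
        W[i, j] <- max(log(rss_r / rss_u), 0)
      }
    }
  } else {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (i == j) next
      W[i, j] <- granger_pair(X[, i], X[, j], p)$f_value
    }
  }
  conn_matrix(W, "GCM", directed = TRUE, subject_id = ts$subject_id,
              params = list(lag_order = p))
}
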