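#' Edge-feature index for an N-node pattern
#'
#' Deterministic column ordering of the feature map: symmetric patterns use
#' the strict upper triangle in row-major (i < j) order; directed patterns
#' use all off-diagonal entries in (row, column) order.
#'
#' @param n number of nodes.
#' @param directed logical.
#' @return data.frame with columns `i`, `j`, `directed`.
#' @export
edge_feature_index <- function(n, directed) {
  if (directed) {
    m <- which(diag(n) == 0, arr.ind = TRUE)
  } else {
    m <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  }
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(i = m[, 1], j = m[, 2], directed = directed)
}

#' Vectorize a connectivity matrix into an edge-feature row
#'
#' @param cm a `conn_matrix` (or plain square matrix, with `directed`
#'   supplied).
#' @param directed overrides the matrix's directedness flag.
#' @return numeric feature vector ordered per [edge_feature_index()].
#' @export
vectorize_cm <- function(cm, directed = NULL) {
  W <- if (inherits(cm, "conn_matrix")) cm$weights else as.matrix(cm)
  if (is.null(directed))
    directed <- if (inherits(cm, "conn_matrix")) cm$directed else
      stop_mcpc("supply 'directed' for a plain matrix")
  idx <- edge_feature_index(nrow(W), directed)
  v <- W[cbind(idx$i, idx$j)]
  if (any(!is.finite(v))) {
    k <- which(!is.finite(v))[1]
    stop_mcpc(sprintf("non-finite weight at edge (%d, %d)", idx$i[k], idx$j[k]))
  }
  v
}

#' Scatter a feature row back into a square matrix
#'
#' Inverse of [vectorize_cm()]; symmetric patterns are mirrored across the
#' diagonal.
#'
#' @param v feature vector.
#' @param n number of nodes.
#' @param directed logical.
#' @return an n x n matrix with zero diagonal.
#' @export
scatter_cm <- function(v, n, directed) {
  idx <- edge_feature_index(n, directed)
  if (length(v) != nrow(idx)) stop_mcpc("feature length does not match n/directedness")
  W <- matrix(0, n, n)
  W[cbind(idx$i, idx$j)] <- v
  if (!directed) W[cbind(idx$j, idx$i)] <- v
  W
}

#' Stack per-subject connectivity matrices into a feature matrix
#'
#' @param cms list of `conn_matrix` objects sharing pattern and size.
#' @return list with `pattern`, `matrix` (n_subjects x d) and
#'   `feature_index`.
#' @export
pattern_features <- function(cms) {
  pats <- unique(vapply(cms, function(m) m$pattern, ""))
  if (length(pats) != 1) stop_mcpc("all matrices must share one pattern")
  dirs <- unique(vapply(cms, function(m) m$directed, TRUE))
  if (length(dirs) != 1) stop_mcpc("all matrices must share directedness")
  M <- t(vapply(cms, vectorize_cm, numeric(length(vectorize_cm(cms[[1]])))))
  list(pattern = pats, matrix = M,
       feature_index = edge_feature_index(nrow(cms[[1]]$weights), dirs))
}

#' Linear kernel Gram matrix, trace-normalized
#'
#' Inner products of feature rows divided by `trace/n`, putting every
#' pattern's kernel on a common scale before the weighted combination.
#'
#' @param features n x d numeric matrix.
#' @return n x n Gram matrix with attribute `"scale"` (the divisor applied).
#' @export
linear_kernel <- function(features) {
  features <- as.matrix(features)
  G <- tcrossprod(features)
  tr <- sum(diag(G))
  if (tr <= 0) stop_mcpc("degenerate kernel: features are identically zero")
  sc <- tr / nrow(G)
  G <- G / sc
  attr(G, "scale") <- sc
  G
}

#' Cross-kernel rows between test and training features
#'
#' @param test_features n_test x d matrix.
#' @param train_features n_train x d matrix.
#' @param scale normalization constant from the training-set
#'   [linear_kernel()] (its `"scale"` attribute).
#' @return n_test x n_train matrix of kernel evaluations.
#' @export
cross_kernel <- function(test_features, train_features, scale) {
  tcrossprod(as.matrix(test_features), as.matrix(train_features)) / scale
}

#' Bundle per-pattern Gram matrices with labels
#'
#' @param grams list of n x n Gram matrices (one per connection pattern).
#' @param labels length-n vector in `{+1, -1}`.
#' @param pattern_names names for the kernels.
#' @param check_psd verify symmetry and positive semidefiniteness (within
#'   1e-8).
#' @return an object of class `kernel_set`.
#' @export
kernel_set <- function(grams, labels, pattern_names = names(grams),
                       check_psd = TRUE) {
  if (length(grams) < 1) stop_mcpc("need at least one Gram matrix")
  n <- nrow(grams[[1]])
  labels <- as.numeric(labels)
  if (length(labels) != n || !all(labels %in% c(-1, 1)))
    stop_mcpc("labels must be +1/-1 and match the Gram dimension")
  for (G in grams) {
    if (!is.matrix(G) || nrow(G) != n || ncol(G) != n)
      stop_mcpc("all Gram matrices must be n x n with a common n")
    if (check_psd) {
      if (max(abs(G - t(G))) > 1e-8) stop_mcpc("Gram matrix is not symmetric")
      ev <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) stop_mcpc("Gram matrix is not positive semidefinite")
    }
  }
  if (is.null(pattern_names)) pattern_names <- paste0("K", seq_along(grams))
  structure(list(grams = grams, pattern_names = pattern_names, labels = labels),
            class = "kernel_set")
}
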