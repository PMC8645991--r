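#' Train a multi-kernel soft-margin SVM with learned simplex weights
#'
#' Solves the multi-kernel SVM whose decision function is
#' `f(x) = sum_i y_i alpha_i sum_m beta_m k_m(x_i, x) + b` with kernel
#' weights `beta` on the probability simplex. Optimization alternates an
#' exact SVM dual solve (SMO) on the beta-combined kernel with a
#' reduced-gradient descent step on the simplex using golden-section line
#' search (the SimpleMKL scheme); the dual objective is monotone
#' non-increasing across outer iterations. With a single kernel this is the
#' ordinary soft-margin kernel SVM and `beta = 1`.
#'
#' @param ks a [kernel_set()].
#' @param C positive box constraint on the dual coefficients.
#' @param outer_tol convergence tolerance on the max-norm change of beta.
#' @param max_outer cap on outer (beta) iterations.
#' @param svm_eps KKT tolerance of the inner SVM solve.
#' @param beta_init optional starting weights (defaults to uniform).
#' @return an object of class `mkl_model` with dual coefficients `alpha`,
#'   bias `b`, kernel weights `beta`, `support_index`, cached
#'   `training_labels` and the outer objective trace.
#' @export
train_mkl <- function(ks, C, outer_tol = 1e-4, max_outer = 100L,
                      svm_eps = 1e-6, beta_init = NULL) {
  stopifnot(inherits(ks, "kernel_set"))
  if (!is.finite(C) || C <= 0) stop_mcpc("'C' must be positive")
  y <- ks$labels
  if (length(unique(y)) < 2) stop_mcpc("training labels contain a single class")
  M <- length(ks$grams)
  n <- length(y)
  cube <- array(unlist(ks$grams), dim = c(n, n, M))
  fit <- .simplemkl_cpp(cube, y, C, outer_tol, as.integer(max_outer), svm_eps,
                        beta_init)
  if (!fit$svm_converged)
    stop_mcpc(sprintf(
      "inner SVM solve did not converge (objective trace: %s)",
      paste(signif(fit$objective_trace, 6), collapse = ", ")))
  sv <- which(fit$alpha > 1e-8)
  if (length(sv) == 0) stop_mcpc("no support vectors at this C")
  structure(list(alpha = as.numeric(fit$alpha), b = fit$b,
                 beta = as.numeric(fit$beta), C = C,
                 support_index = sv, training_labels = y,
                 pattern_names = ks$pattern_names,
                 objective_trace = as.numeric(fit$objective_trace),
                 n_outer = fit$n_outer),
            class = "mkl_model")
}

#' Predict with a trained multi-kernel SVM
#'
#' @param model an `mkl_model` from [train_mkl()].
#' @param test_kernel_rows list of M matrices (n_test x n_train) of kernel
#'   evaluations between test and training subjects, in the model's pattern
#'   order.
#' @return list with `labels` (+1/-1; a decision value of exactly 0 maps to
#'   +1) and `decision_values`.
#' @export
predict_mkl <- function(model, test_kernel_rows) {
  stopifnot(inherits(model, "mkl_model"))
  if (!is.list(test_kernel_rows)) test_kernel_rows <- list(test_kernel_rows)
  M <- length(model$beta)
  if (length(test_kernel_rows) != M)
    stop_mcpc("expected one test-kernel matrix per pattern")
  n <- length(model$alpha)
  Kc <- 0
  for (m in seq_len(M)) {
    Km <- as.matrix(test_kernel_rows[[m]])
    if (ncol(Km) != n)
      stop_mcpc("test kernel columns must match the number of training subjects")
    Kc <- Kc + model$beta[m] * Km
  }
  f <- as.numeric(Kc %*% (model$alpha * model$training_labels)) + model$b
  list(labels = ifelse(f >= 0, 1, -1), decision_values = f)
}

#' Serialize an MKL model to JSON
#'
#' @param model an `mkl_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mkl_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an MKL model written by [write_mkl_model()]
#'
#' @param path JSON file.
#' @return an `mkl_model`.
#' @export
read_mkl_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$training_labels <- as.numeric(m$training_labels)
  structure(m, class = "mkl_model")
}
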